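#' Pairwise genetic distance between aligned sequences
#'
#' Maximum-likelihood corrected amino-acid distance from the observed
#' proportion of differing sites. Only comparable columns (non-gap in both
#' sequences) are counted. Models: `"poisson"`, d = -ln(1 - p), and
#' `"gamma"`, d = alpha * ((1 - p)^(-1/alpha) - 1), which accounts for
#' rate heterogeneity across sites and tends to the Poisson distance as
#' alpha grows. Near-saturated pairs (p >= `p_max`) return the bounded
#' sentinel `d_max` with a `saturated` attribute so downstream
#' correlations stay defined.
#'
#' @param seq_a,seq_b Aligned sequences (equal-length strings, gaps `-`).
#' @param model `"poisson"` or `"gamma"`.
#' @param alpha Gamma shape parameter (model `"gamma"`).
#' @param p_max Saturation threshold on the observed difference proportion.
#' @param d_max Distance assigned to saturated pairs.
#' @return Distance in substitutions per site.
#' @export
#' @examples
#' pairwise_distance("ARNDARNDAR", "ARNDARNDAK")  # p = 0.1
pairwise_distance <- function(seq_a, seq_b, model = c("poisson", "gamma"),
                              alpha = 1, p_max = 0.95, d_max = 10) {
  model <- match.arg(model)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  comp <- a != "-" & b != "-"
  if (!any(comp)) stop("no comparable (non-gap in both) columns")
  p <- sum(a[comp] != b[comp]) / sum(comp)
  if (p >= p_max) {
    d <- d_max
    attr(d, "saturated") <- TRUE
    return(d)
  }
  if (model == "poisson") -log(1 - p) else alpha * ((1 - p)^(-1 / alpha) - 1)
}

#' Genetic distance matrix of an orthologue family
#'
#' All pairwise corrected distances between the sequences of an alignment,
#' symmetric with a zero diagonal.
#'
#' @param x A [msa()] object (>= 3 sequences).
#' @inheritParams pairwise_distance
#' @return `dist_matrix`: symmetric numeric matrix with species labels.
#' @export
distance_matrix <- function(x, model = c("poisson", "gamma"), alpha = 1,
                            p_max = 0.95, d_max = 10) {
  stopifnot(inherits(x, "coat_msa"))
  model <- match.arg(model)
  seqs <- apply(x$mat, 1, paste, collapse = "")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(x$species, x$species))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- tryCatch(
      pairwise_distance(seqs[i], seqs[j], model, alpha, p_max, d_max),
      error = function(e) stop("pair ", x$species[i], " / ", x$species[j],
                               ": ", conditionMessage(e)))
    d[i, j] <- d[j, i] <- as.numeric(dij)
  }
  class(d) <- c("dist_matrix", "matrix", "array")
  d
}

check_dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must carry species labels")
  if (!isTRUE(all.equal(unname(m), unname(t(m))))) stop("matrix not symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  invisible(m)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining (via ape); negative branch lengths are
#' clamped to zero and flagged in the `clamped` attribute.
#'
#' @param m Symmetric distance matrix with species labels (n >= 3).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(m) {
  check_dist_matrix(m)
  if (nrow(m) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(m))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Mirror-tree correlation between two distance matrices
#'
#' Pearson correlation between the upper-triangle entries of two genetic
#' distance matrices restricted to their common species (species order
#' aligned first) -- the correlated-evolution signal between two families.
#'
#' @param a,b Distance matrices with species labels.
#' @param min_species Minimum common species for a valid correlation.
#' @return List `r`, `n_common`, `species`.
#' @export
matrix_correlation <- function(a, b, min_species = 4L) {
  check_dist_matrix(a); check_dist_matrix(b)
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < min_species)
    stop("need at least ", min_species, " common species, got ", length(common))
  ua <- a[common, common][upper.tri(diag(length(common)))]
  ub <- b[common, common][upper.tri(diag(length(common)))]
  list(r = cor(ua, ub), n_common = length(common), species = common)
}

#' Permutation significance of a mirror-tree correlation
#'
#' One-sided permutation test (positive co-evolution is the hypothesis):
#' the species labels of `b` are permuted jointly over rows and columns,
#' the correlation recomputed, and
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @inheritParams matrix_correlation
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed RNG seed.
#' @return List `r`, `p_value`, `n_perm`, `n_common`.
#' @export
correlation_significance <- function(a, b, n_perm = 9999L, seed = 1L,
                                     min_species = 4L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  obs <- matrix_correlation(a, b, min_species)
  common <- obs$species
  ua <- a[common, common][upper.tri(diag(length(common)))]
  bb <- b[common, common]
  set.seed(seed)
  n <- length(common)
  rperm <- replicate(n_perm, {
    p <- sample.int(n)
    cor(ua, bb[p, p][upper.tri(diag(n))])
  })
  list(r = obs$r,
       p_value = (1 + sum(rperm >= obs$r)) / (1 + n_perm),
       n_perm = n_perm, n_common = obs$n_common)
}

#' Batch mirror-tree table over family pairs
#'
#' Computes r (and optionally permutation p) for a list of family pairs,
#' including designated unrelated baseline pairs, producing the per-pair
#' correlation table used to contrast interacting against unrelated
#' components.
#'
#' @param matrices Named list of distance matrices.
#' @param pairs data.frame with columns `a`, `b` and optionally `role`
#'   (e.g. `"interacting"` / `"baseline"`).
#' @param n_perm Permutations per pair; 0 skips the test.
#' @param seed Base RNG seed (incremented per pair).
#' @return data.frame `a`, `b`, `role`, `n_common`, `r`, `p_value`.
#' @export
mirror_batch <- function(matrices, pairs, n_perm = 0L, seed = 1L) {
  stopifnot(all(c("a", "b") %in% names(pairs)))
  role <- if ("role" %in% names(pairs)) pairs$role else NA_character_
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ma <- matrices[[pairs$a[k]]]; mb <- matrices[[pairs$b[k]]]
    if (is.null(ma) || is.null(mb)) stop("unknown family in pair ", k)
    if (n_perm > 0) {
      res <- correlation_significance(ma, mb, n_perm, seed + k - 1L)
      p <- res$p_value
    } else {
      res <- matrix_correlation(ma, mb)
      p <- NA_real_
    }
    data.frame(a = pairs$a[k], b = pairs$b[k], role = role[k],
               n_common = res$n_common, r = res$r, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write PHYLIP square distance matrices and Newick trees
#'
#' Thin wrappers over phangorn and ape for the standard interchange
#' formats, including the import path for externally computed distance
#' matrices and trees.
#' @param path File path.
#' @param m Distance matrix.
#' @param tree A `phylo` tree.
#' @export
read_dist_phylip <- function(path) {
  d <- phangorn::readDist(path)
  m <- as.matrix(d)
  class(m) <- c("dist_matrix", "matrix", "array")
  check_dist_matrix(m)
}

#' @rdname read_dist_phylip
#' @export
write_dist_phylip <- function(m, path) {
  check_dist_matrix(m)
  phangorn::writeDist(as.dist(m), path, format = "phylip")
  invisible(path)
}

#' @rdname read_dist_phylip
#' @export
read_tree_newick <- function(path) ape::read.tree(path)

#' @rdname read_dist_phylip
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
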