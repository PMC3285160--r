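#' Multiple sequence alignment container
#'
#' @description Builds an `coat_msa` from aligned sequences (equal length,
#' gaps as `-`), with unique species labels and a designated target
#' sequence that maps onto a structure chain.
#'
#' @param sequences Named character vector of aligned sequences.
#' @param target Name of the target sequence (default: first).
#' @return `coat_msa`: list with `mat` (sequence x column character matrix),
#'   `species`, `target`.
#' @export
msa <- function(sequences, target = names(sequences)[1]) {
  stopifnot(is.character(sequences), length(sequences) >= 3)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique species labels")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("aligned sequences must have equal lengths")
  if (!target %in% names(sequences)) stop("target not in alignment: ", target)
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  structure(list(mat = mat, species = names(sequences), target = target),
            class = "coat_msa")
}

#' @export
print.coat_msa <- function(x, ...) {
  cat(sprintf("<coat_msa> %d sequences x %d columns, target %s\n",
              nrow(x$mat), ncol(x$mat), x$target))
  invisible(x)
}

#' Read an alignment from FASTA or Clustal
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param target Target sequence name (default first).
#' @return A [msa()] object.
#' @export
read_msa <- function(path, format = c("fasta", "clustal"), target = NULL) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format)
  seqs <- setNames(toupper(unlist(aln$seq)), aln$nam)
  msa(seqs, target = if (is.null(target)) aln$nam[1] else target)
}

#' Write an alignment as FASTA
#' @param x A `coat_msa`.
#' @param path Output file.
#' @export
write_msa <- function(x, path) {
  seqs <- apply(x$mat, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Filter homologue hits by identity and coverage
#'
#' Keeps hits with strictly more than `min_identity` percent sequence
#' identity to the query and strictly more than `min_coverage` percent
#' coverage of the query length -- the orthologue-selection rule applied to
#' sequence-search output before alignment. Identity is identical aligned
#' pairs over aligned columns excluding gap-gap pairs; coverage is the
#' number of query residues inside the aligned span (first to last column
#' where the hit is non-gap) over the full query length.
#'
#' @param query Ungapped query sequence (string).
#' @param candidates Named list; each element either a list with elements
#'   `query_aln` and `hit_aln` (equal-length aligned strings, gaps `-`), or
#'   a plain hit sequence string, aligned internally by global alignment
#'   when `align = TRUE`.
#' @param min_identity,min_coverage Percent thresholds (strict).
#' @param align Allow internal pairwise alignment of unaligned candidates
#'   (requires Biostrings).
#' @return data.frame with per-candidate `identity`, `coverage`, `kept`.
#' @export
filter_homologs <- function(query, candidates, min_identity = 30,
                            min_coverage = 70, align = TRUE) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  qlen <- nchar(gsub("-", "", query))
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    if (is.character(cand) && length(cand) == 1) {
      if (!align) stop("candidate '", nm, "' has no alignment and internal ",
                       "alignment is disabled")
      cand <- align_pair(gsub("-", "", query), cand)
    }
    q <- strsplit(toupper(cand$query_aln), "")[[1]]
    h <- strsplit(toupper(cand$hit_aln), "")[[1]]
    if (length(q) != length(h)) stop("misaligned candidate: ", nm)
    not_gg <- !(q == "-" & h == "-")
    ident <- 100 * sum(q == h & q != "-" & not_gg) / sum(not_gg)
    span <- range(which(h != "-"))
    cov <- 100 * sum(q[span[1]:span[2]] != "-") / qlen
    data.frame(name = nm, identity = ident, coverage = cov,
               kept = ident > min_identity & cov > min_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

align_pair <- function(query, hit) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings required for internal alignment")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(hit),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global-local")
  list(query_aln = as.character(Biostrings::alignedPattern(al)),
       hit_aln = as.character(Biostrings::alignedSubject(al)))
}

#' Per-position conservation scores
#'
#' Surrogate conservation score with the same convention as Bayesian
#' conservation servers: the lowest score marks the most conserved
#' position. The raw score of a column is its sequence-weighted Shannon
#' entropy (position-based Henikoff-Henikoff weights; gaps excluded from
#' the frequencies), z-normalised across the scored columns so scores are
#' a relative measure within one protein. If every scored column is
#' identical the profile is all zeros by convention. Columns with more
#' than 50% gaps are scored but flagged, and flagged positions are
#' excluded from downstream group means. Scores are reported per target
#' position (columns where the target is non-gap).
#'
#' @param x A [msa()] object.
#' @return `conservation_profile`: data.frame with `position` (1-based
#'   target position), `column` (alignment column), `score` (z-normalised,
#'   comparable within one protein), `raw` (unnormalised weighted entropy,
#'   comparable across proteins scored with the same convention), `n_eff`
#'   (non-gap sequences in the column), `gap_flag`.
#' @export
conservation_scores <- function(x) {
  stopifnot(inherits(x, "coat_msa"))
  mat <- x$mat
  w <- henikoff_weights(mat)
  tgt <- mat[x$target, ]
  cols <- which(tgt != "-")
  raw <- numeric(length(cols))
  n_eff <- integer(length(cols))
  gap_flag <- logical(length(cols))
  for (k in seq_along(cols)) {
    col <- mat[, cols[k]]
    ng <- col != "-"
    n_eff[k] <- sum(ng)
    gap_flag[k] <- mean(!ng) > 0.5
    f <- tapply(w[ng], col[ng], sum)
    f <- f / sum(f)
    raw[k] <- -sum(f * log(f))
  }
  s <- sd(raw)
  score <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  structure(data.frame(position = seq_along(cols), column = cols,
                       score = score, raw = raw, n_eff = n_eff,
                       gap_flag = gap_flag),
            class = c("conservation_profile", "data.frame"))
}

# position-based sequence weights; the gap counts as a 21st symbol
henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w / sum(w)
}

#' Partition chain residues into interface / surface / buried
#'
#' Classifies every residue of one chain: residues in the interface set are
#' class `"interface"` regardless of accessibility; of the rest, residues
#' with isolated-form relative accessibility strictly above `exposed`
#' percent are `"surface"` (non-interface surface-exposed) and the
#' remainder `"buried"`. The partition is exhaustive and disjoint.
#'
#' @param profile `sasa_profile` of the isolated chain (all-atom probe).
#' @param interface An `interface_set` covering the same chain.
#' @param exposed Percent exposure threshold (strict).
#' @return data.frame `chain`, `resno`, `insert`, `res_type`, `position`
#'   (1-based residue order), `class`.
#' @export
classify_surface <- function(profile, interface, exposed = 10) {
  ch <- unique(profile$chain)
  if (length(ch) != 1) stop("profile must cover exactly one chain")
  ifc <- interface[interface$chain == ch, , drop = FALSE]
  if (nrow(interface) > 0 && nrow(ifc) == 0 && !ch %in% unique(interface$chain))
    stop("interface set does not cover chain ", ch)
  in_ifc <- res_key(profile$chain, profile$resno, profile$insert) %in%
    res_key(ifc$chain, ifc$resno, ifc$insert)
  cls <- ifelse(in_ifc, "interface",
                ifelse(!is.na(profile$rel_acc) & profile$rel_acc > exposed,
                       "surface", "buried"))
  data.frame(chain = profile$chain, resno = profile$resno,
             insert = profile$insert, res_type = profile$res_type,
             position = seq_len(nrow(profile)), class = cls,
             stringsAsFactors = FALSE)
}

#' Compare conservation of interface vs surface residues
#'
#' Averages conservation scores over interface residues and over
#' non-interface surface-exposed residues of the same chain, reporting the
#' difference (interface minus surface; negative means the interface is
#' more conserved) with a bootstrap confidence interval. Gap-flagged
#' positions are excluded.
#'
#' @param profile A `conservation_profile`; positions must map one-to-one
#'   onto the chain residues of `partition` via `position`.
#' @param partition Output of [classify_surface()].
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with `mean_interface`, `mean_surface`, `difference`,
#'   `ci` (length-2), `n_interface`, `n_surface`.
#' @export
compare_interface_conservation <- function(profile, partition,
                                           n_boot = 10000L, seed = 1L,
                                           conf = 0.95) {
  m <- match(partition$position, profile$position)
  sc <- profile$score[m]
  keep <- !is.na(sc) & !profile$gap_flag[m]
  gi <- sc[keep & partition$class == "interface"]
  gs <- sc[keep & partition$class == "surface"]
  if (length(gi) == 0 || length(gs) == 0)
    stop("both groups must be non-empty")
  if (length(gi) < 2 || length(gs) < 2)
    warning("group of size 1: bootstrap interval is degenerate-wide")
  diff_obs <- mean(gi) - mean(gs)
  set.seed(seed)
  boot <- replicate(n_boot, {
    mean(sample(gi, replace = TRUE)) - mean(sample(gs, replace = TRUE))
  })
  alpha <- (1 - conf) / 2
  list(mean_interface = mean(gi), mean_surface = mean(gs),
       difference = diff_obs,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       n_interface = length(gi), n_surface = length(gs))
}
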