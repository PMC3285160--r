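#' @name coat_structure
#' @title Structure container
#'
#' @description
#' A `coat_structure` is a light wrapper around an atom table, the form all
#' SASA and interface operations consume. Fields:
#'
#' * `atom`: data.frame with columns `chain` (chain id), `resno` (author
#'   residue number), `insert` (insertion code, `""` if none), `resid`
#'   (three-letter residue name), `res_type` (one-letter code, `"X"` for
#'   non-standard), `elety` (atom name), `element`, `x`, `y`, `z`
#'   (Angstrom), `radius` (van der Waals, Angstrom).
#' * `chains`: data.frame with `chain_id` and `calpha_only` (TRUE when every
#'   residue of the chain consists of a single CA atom). The flag is per
#'   chain, so mixed-resolution models are handled.
#' * `source_id`: free-text provenance (e.g. a PDB id).
#'
#' Residue identity is always author numbering plus insertion code; residues
#' are never renumbered.
NULL

res_key <- function(chain, resno, insert) {
  if (length(chain) == 0) return(character(0))
  paste0(chain, ":", resno, insert)
}

new_structure <- function(atom, source_id = "") {
  stopifnot(is.data.frame(atom), nrow(atom) > 0)
  atom$insert[is.na(atom$insert)] <- ""
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)))
    stop("non-finite atom coordinates")
  if (any(!is.finite(atom$radius) | atom$radius <= 0))
    stop("all atoms must carry a positive radius")
  chains <- unique(atom$chain)
  calpha_only <- vapply(chains, function(ch) {
    a <- atom[atom$chain == ch, ]
    all(a$elety == "CA") &&
      !anyDuplicated(res_key(a$chain, a$resno, a$insert))
  }, logical(1))
  structure(
    list(atom = atom,
         chains = data.frame(chain_id = chains, calpha_only = calpha_only,
                             stringsAsFactors = FALSE),
         source_id = source_id),
    class = "coat_structure")
}

#' @export
print.coat_structure <- function(x, ...) {
  cat(sprintf("<coat_structure> %s: %d chains, %d residues, %d atoms\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$chains),
              length(unique(res_key(x$atom$chain, x$atom$resno, x$atom$insert))),
              nrow(x$atom)))
  ca <- x$chains$chain_id[x$chains$calpha_only]
  if (length(ca)) cat("  C-alpha-only chains:", paste(ca, collapse = ""), "\n")
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses a PDB file (via bio3d) into a [coat_structure]. HETATM records and
#' waters are excluded (selenomethionine MSE is retained and read as MET);
#' alternate locations are resolved by keeping the highest-occupancy
#' conformer, first in file on ties. Van der Waals radii are assigned per
#' element from `radii`; CA atoms of C-alpha-only chains receive the
#' united-residue `calpha_radius`.
#'
#' @param path PDB file.
#' @param model_index 1-based model to read from multi-model files.
#' @param radii Named element-to-radius vector, see [vdw_radii()].
#' @param calpha_radius Radius for CA beads of C-alpha-only chains.
#' @param unknown_radius Fallback radius for elements absent from `radii`;
#'   `NULL` makes an unknown element an error naming the atom.
#' @return A [coat_structure].
#' @export
read_structure <- function(path, model_index = 1L, radii = vdw_radii(),
                           calpha_radius = calpha_bead_radius(),
                           unknown_radius = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" | toupper(at$resid) == "MSE"
  keep <- keep & !(toupper(at$resid) %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no ATOM records in ", path)

  xyz <- pdb$xyz
  if (is.matrix(xyz)) {
    if (model_index > nrow(xyz)) stop("model_index ", model_index,
                                      " out of range (", nrow(xyz), " models)")
    xyz <- xyz[model_index, ]
  } else if (model_index != 1L) stop("model_index out of range (1 model)")
  idx <- which(keep)
  at$x <- xyz[3 * (idx - 1) + 1]
  at$y <- xyz[3 * (idx - 1) + 2]
  at$z <- xyz[3 * (idx - 1) + 3]

  # altloc: keep highest occupancy, first in file on ties
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  rkeys <- paste(at$chain, at$resno, at$insert, sep = "\r")
  file_order <- unique(rkeys)  # author order, before any sorting
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       file_order), at$eleno), , drop = FALSE]

  element <- toupper(trimws(at$elesy))
  noel <- !nzchar(element) | is.na(element)
  element[noel] <- gsub("[^A-Z]", "", toupper(substr(trimws(at$elety[noel]), 1, 1)))
  element[toupper(at$resid) == "MSE" & at$elety == "SE"] <- "SE"

  radius <- unname(radii[element])
  if (anyNA(radius)) {
    if (is.null(unknown_radius)) {
      bad <- which(is.na(radius))[1]
      stop("no van der Waals radius for element '", element[bad],
           "' (atom ", at$elety[bad], " of ", at$resid[bad], " ",
           at$chain[bad], at$resno[bad], ")")
    }
    radius[is.na(radius)] <- unknown_radius
  }

  atom <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                     insert = at$insert, resid = toupper(at$resid),
                     res_type = aa_three_to_one(at$resid),
                     elety = trimws(at$elety), element = element,
                     x = at$x, y = at$y, z = at$z, radius = radius,
                     stringsAsFactors = FALSE)
  s <- new_structure(atom, source_id = sub("\\.pdb$", "", basename(path)))
  # CA beads of C-alpha-only chains are united residues: wider radius
  ca_chains <- s$chains$chain_id[s$chains$calpha_only]
  s$atom$radius[s$atom$chain %in% ca_chains] <- calpha_radius
  s
}

#' Write a structure to a PDB file
#'
#' @param structure A [coat_structure].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atom
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(nzchar(a$insert), a$insert, ""),
                   elety = a$elety, elesy = a$element,
                   eleno = seq_len(nrow(a)))
  invisible(path)
}

#' Extract one chain as a structure
#'
#' Coordinates are unchanged; only atoms of `chain_id` are kept.
#' @param structure A [coat_structure].
#' @param chain_id Chain to extract.
#' @export
extract_chain <- function(structure, chain_id) {
  if (!chain_id %in% structure$chains$chain_id)
    stop("no such chain: ", chain_id)
  sub_structure(structure, chain_id)
}

sub_structure <- function(structure, chain_ids) {
  atom <- structure$atom[structure$atom$chain %in% chain_ids, , drop = FALSE]
  new_structure(atom, source_id = structure$source_id)
}

#' Reduce a structure to its C-alpha trace
#'
#' Keeps only CA atoms (coordinates unchanged) and assigns the
#' united-residue bead radius, producing the rendition the low-resolution
#' (3.5 Angstrom probe) regime operates on.
#'
#' @param structure A [coat_structure].
#' @param calpha_radius Bead radius in Angstrom.
#' @return A [coat_structure] whose chains are all C-alpha-only.
#' @export
make_calpha <- function(structure, calpha_radius = calpha_bead_radius()) {
  atom <- structure$atom[structure$atom$elety == "CA", , drop = FALSE]
  if (nrow(atom) == 0) stop("structure has no CA atoms")
  atom$radius <- calpha_radius
  new_structure(atom, source_id = structure$source_id)
}

chain_ca_coords <- function(structure, chain_id) {
  a <- structure$atom
  a <- a[a$chain == chain_id & a$elety == "CA", , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", chain_id, " has no CA atoms")
  as.matrix(a[, c("x", "y", "z")])
}

#' Near-neighbour adjacency between chains
#'
#' Two chains are near neighbours when their closest inter-chain
#' C-alpha-to-C-alpha distance is less than or equal to `cutoff`
#' (inclusive boundary). All CA atoms of each chain are used.
#'
#' @param structure A [coat_structure]; every chain must have CA atoms.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return Symmetric logical matrix over chain ids, `FALSE` diagonal.
#' @export
near_neighbors <- function(structure, cutoff = 5.0) {
  ids <- structure$chains$chain_id
  ca <- lapply(ids, function(ch) chain_ca_coords(structure, ch))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n < 2) return(adj)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- min_sq_dist(ca[[i]], ca[[j]])
    adj[i, j] <- adj[j, i] <- d2 <= cut2
  }
  adj
}

min_sq_dist <- function(a, b) {
  # pairwise squared distances between two coordinate matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

#' Decompose an assembly into per-chain subcomplexes
#'
#' Large assemblies are analysed chain by chain: each chain's subcomplex is
#' the chain itself plus every chain sharing at least one near-neighbour
#' contact with it, and is treated as an independent structure downstream.
#' Member order is deterministic: focal chain first, then file order.
#'
#' @inheritParams near_neighbors
#' @return Named list (by focal chain) of `coat_subcomplex` objects with
#'   fields `focal` and `members`.
#' @export
build_subcomplexes <- function(structure, cutoff = 5.0) {
  adj <- near_neighbors(structure, cutoff)
  ids <- structure$chains$chain_id
  out <- lapply(ids, function(ch) {
    members <- c(ch, ids[adj[ch, ]])
    structure(list(focal = ch, members = members), class = "coat_subcomplex")
  })
  names(out) <- ids
  out
}

#' @export
print.coat_subcomplex <- function(x, ...) {
  cat(sprintf("%s\t%s\n", x$focal, paste(x$members, collapse = "")))
  invisible(x)
}

#' Materialise a subcomplex as a structure
#'
#' @param structure The parent [coat_structure].
#' @param subcomplex A subcomplex from [build_subcomplexes()].
#' @export
subcomplex_structure <- function(structure, subcomplex) {
  sub_structure(structure, subcomplex$members)
}
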