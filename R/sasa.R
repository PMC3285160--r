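#' Deterministic unit-sphere quadrature points
#'
#' Golden-spiral (Fibonacci) point set in a fixed orientation, so that SASA
#' values are reproducible bit-for-bit at a given `n_points`.
#'
#' @param n_points Number of points (>= 92).
#' @return `n_points` x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n_points = 960L) {
  n_points <- as.integer(n_points)
  if (n_points < 92L) stop("n_points must be at least 92")
  i <- seq_len(n_points) - 1L
  z <- 1 - 2 * (i + 0.5) / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the atom spheres by point quadrature: each
#' atom's probe-centre sphere (radius = atom radius + probe) is sampled at a
#' deterministic golden-spiral point set and a point counts as accessible
#' when it lies outside every other atom's probe-centre sphere. Residue ASA
#' is the sum over the residue's atoms. The probe radius selects the regime:
#' 1.4 Angstrom for all-atom structures, 3.5 Angstrom for C-alpha-only
#' models, whose beads present a smoother, coarser surface.
#'
#' @param structure A [coat_structure].
#' @param probe_radius Probe radius in Angstrom (> 0).
#' @param n_points Quadrature points per atom (default 960).
#' @param reference Named vector of per-residue-type maximal ASA used for
#'   relative accessibility, a set name for [reference_max_asa()], or `NULL`
#'   to skip relative values.
#' @return A `sasa_profile`: data.frame with columns `chain`, `resno`,
#'   `insert`, `res_type`, `abs_asa` (Angstrom^2) and `rel_acc` (percent,
#'   `NA` where no reference value exists), with attributes `probe_radius`,
#'   `n_points` and `calpha` (TRUE when every chain is C-alpha-only).
#' @export
#' @examples
#' s <- generate_complex(complex_scenario(seed = 1))$all_atom
#' head(compute_sasa(s, probe_radius = 1.4, n_points = 240))
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                         reference = "synthetic") {
  stopifnot(inherits(structure, "coat_structure"))
  if (probe_radius <= 0) stop("probe_radius must be positive")
  sphere <- golden_spiral_points(n_points)
  a <- structure$atom
  asa <- .sasa_kernel(as.matrix(a[, c("x", "y", "z")]), a$radius,
                      probe_radius, sphere)
  key <- res_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  prof <- data.frame(chain = a$chain[first], resno = a$resno[first],
                     insert = a$insert[first], res_type = a$res_type[first],
                     abs_asa = as.numeric(tapply(asa, factor(key, levels = key[first]), sum)),
                     stringsAsFactors = FALSE)
  if (is.character(reference) && length(reference) == 1 && is.null(names(reference)))
    reference <- reference_max_asa(reference, n_points = n_points)
  prof$rel_acc <- if (is.null(reference)) NA_real_ else
    100 * prof$abs_asa / unname(reference[prof$res_type])
  attr(prof, "probe_radius") <- probe_radius
  attr(prof, "n_points") <- n_points
  attr(prof, "calpha") <- all(structure$chains$calpha_only)
  class(prof) <- c("sasa_profile", "data.frame")
  prof
}

#' SASA of one chain extracted from its complex
#'
#' Computes the profile of the chain in isolation (all other chains removed,
#' coordinates unchanged) -- the "isolated form" of the interface criterion.
#'
#' @inheritParams compute_sasa
#' @param chain_id Chain to isolate.
#' @export
isolated_chain_sasa <- function(structure, chain_id, probe_radius = 1.4,
                                n_points = 960L, reference = "synthetic") {
  compute_sasa(extract_chain(structure, chain_id), probe_radius,
               n_points, reference)
}

#' Per-chain isolated profiles for a whole structure
#'
#' @inheritParams compute_sasa
#' @return Named list of `sasa_profile`, one per chain.
#' @export
isolated_profiles <- function(structure, probe_radius = 1.4, n_points = 960L,
                              reference = "synthetic") {
  ids <- structure$chains$chain_id
  setNames(lapply(ids, function(ch)
    isolated_chain_sasa(structure, ch, probe_radius, n_points, reference)),
    ids)
}
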