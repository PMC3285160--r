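#' Van der Waals radii tables
#'
#' Element-keyed radii (Angstrom) used when loading structures. The default
#' set is a standard united-atom protein set (Chothia-type values); hydrogens
#' are assigned a nominal radius but are normally absent from the structures
#' analysed. C-alpha atoms of C-alpha-only chains are treated as
#' united-residue beads with their own configurable radius.
#'
#' @param set Radii set name. Only `"chothia"` is shipped.
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function(set = "chothia") {
  set <- match.arg(set)
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00,
    SE = 1.90, FE = 1.47, ZN = 1.39, MG = 1.18, CA = 1.74)
}

#' Default united-residue radius for C-alpha beads
#'
#' Radius assigned to CA atoms of C-alpha-only chains, where one sphere
#' stands in for the whole residue.
#' @return Radius in Angstrom.
#' @export
calpha_bead_radius <- function() 1.87

# 20 standard amino acids, one- and three-letter codes
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","V","W","Y")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","VAL","TRP","TYR")

aa_three_to_one <- function(res3) {
  res3 <- toupper(res3)
  res3[res3 == "MSE"] <- "MET"  # selenomethionine read as methionine
  out <- AA1[match(res3, AA3)]
  out[is.na(out)] <- "X"
  out
}

#' Reference maximal accessible surface areas
#'
#' Per-residue-type maximal ASA (Angstrom^2) used to convert absolute ASA to
#' relative accessibility (percent). Two sets are shipped:
#'
#' * `"tien2013"`: published theoretical Gly-X-Gly tripeptide maxima for
#'   all-atom structures at probe 1.4 Angstrom (Tien et al. 2013, PLOS ONE
#'   8:e80635). Use for real PDB structures.
#' * `"synthetic"`: maxima computed once from the package's own extended
#'   Gly-X-Gly tripeptides built with the simplified residue geometry of
#'   [generate_complex()], at probe 1.4 Angstrom. Use for synthetic
#'   benchmark complexes so that relative accessibilities are
#'   self-consistent with the generator.
#'
#' In the C-alpha 3.5 Angstrom regime classification uses absolute cutoffs
#' (see [calibrate_calpha_cutoffs()]); relative values there are
#' informational only.
#'
#' @param set `"tien2013"` or `"synthetic"`.
#' @param n_points Quadrature points used when computing the synthetic set.
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
#' @examples
#' reference_max_asa("tien2013")[["G"]]
reference_max_asa <- function(set = c("tien2013", "synthetic"), n_points = 960) {
  set <- match.arg(set)
  if (set == "tien2013") {
    return(c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, V = 174, W = 285, Y = 263))
  }
  synthetic_reference_max_asa(n_points)
}

# Maximal ASA of the central residue of an extended Gly-X-Gly tripeptide
# built with the synthetic residue templates. Memoised per n_points.
.synth_ref_cache <- new.env(parent = emptyenv())

synthetic_reference_max_asa <- function(n_points = 960) {
  key <- as.character(n_points)
  if (!is.null(.synth_ref_cache[[key]])) return(.synth_ref_cache[[key]])
  vals <- vapply(AA1, function(aa) {
    s <- build_tripeptide(aa)
    prof <- compute_sasa(s, probe_radius = 1.4, n_points = n_points,
                         reference = NULL)
    prof$abs_asa[prof$resno == 2L]
  }, numeric(1))
  .synth_ref_cache[[key]] <- vals
  vals
}
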