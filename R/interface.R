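#' All-atom interface detection
#'
#' A residue is an interface residue when it is buried in the complex
#' (relative accessibility strictly below `buried`, default 7%) and exposed
#' in the isolated chain (strictly above `exposed`, default 10%). Both
#' profiles must come from the same structure at the all-atom probe.
#' Residues lacking a reference area (and hence relative accessibility) are
#' excluded from classification and reported in the `excluded` attribute,
#' with a warning.
#'
#' @param complex_profile `sasa_profile` of the full complex.
#' @param isolated Named list of per-chain `sasa_profile`s of the isolated
#'   chains (see [isolated_profiles()]).
#' @param buried,exposed Percent thresholds; inequalities are strict.
#' @return An `interface_set`: data.frame with columns `chain`, `resno`,
#'   `insert`, `res_type`, `complex_value`, `isolated_value` (percent
#'   accessibilities), attribute `regime = "all-atom"`.
#' @export
detect_interface_allatom <- function(complex_profile, isolated,
                                     buried = 7, exposed = 10) {
  joined <- join_profiles(complex_profile, isolated)
  usable <- !is.na(joined$complex_value) & !is.na(joined$isolated_value)
  if (any(!usable)) {
    warning(sum(!usable), " residue(s) without reference accessibility ",
            "excluded from interface classification")
  }
  hit <- usable & joined$complex_value < buried & joined$isolated_value > exposed
  out <- joined[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regime") <- "all-atom"
  attr(out, "excluded") <- joined[!usable, c("chain", "resno", "insert", "res_type")]
  class(out) <- c("interface_set", "data.frame")
  out
}

# align complex and isolated profiles residue-by-residue
join_profiles <- function(complex_profile, isolated, value = "rel_acc") {
  stopifnot(is.list(isolated), !is.null(names(isolated)))
  ck <- res_key(complex_profile$chain, complex_profile$resno, complex_profile$insert)
  iso <- do.call(rbind, lapply(isolated, function(p)
    data.frame(key = res_key(p$chain, p$resno, p$insert),
               isolated_value = p[[value]], stringsAsFactors = FALSE)))
  m <- match(ck, iso$key)
  if (anyNA(m)) stop("residue missing from isolated profiles: ",
                     ck[which(is.na(m))[1]])
  data.frame(chain = complex_profile$chain, resno = complex_profile$resno,
             insert = complex_profile$insert, res_type = complex_profile$res_type,
             complex_value = complex_profile[[value]],
             isolated_value = iso$isolated_value[m],
             stringsAsFactors = FALSE)
}

#' Calibrate residue-type-dependent C-alpha ASA cutoffs
#'
#' Low-resolution models give only C-alpha positions, so the percent-based
#' burial criterion cannot be applied directly. Instead, absolute C-alpha
#' ASA cutoffs corresponding to the 7% and 10% relative-accessibility
#' thresholds are calibrated from all-atom training structures: every
#' residue contributes a pair (all-atom relative accessibility at the
#' high-resolution probe, C-alpha ASA at the low-resolution probe with the
#' same structural context reduced to its CA trace); per residue type an
#' isotonic (monotone increasing) regression maps relative accessibility to
#' expected C-alpha ASA, and the cutoffs are the fitted values at `buried`
#' and `exposed` percent. Pairs are pooled from each training complex and
#' from each of its chains in isolation, so both buried and exposed
#' contexts are represented.
#'
#' Types with fewer than `min_per_type` training residues fall back to a
#' pooled all-type fit and are flagged. After evaluation the strict
#' ordering buried < exposed is enforced (a flat fit between the two
#' percentages lifts the exposed cutoff by an epsilon and flags the row
#' "degenerate").
#'
#' @param training List of all-atom [coat_structure]s.
#' @param probe_lowres,probe_hires Probe radii (Angstrom) of the two
#'   regimes.
#' @param buried,exposed Percent accessibilities at which cutoffs are read.
#' @param min_per_type Minimum training residues per residue type.
#' @param n_points Quadrature points.
#' @param reference Reference max-ASA set for relative accessibility.
#' @param pairs Optional precomputed training pairs (data.frame with
#'   columns `res_type`, `rel_acc`, `ca_asa`), bypassing the SASA runs;
#'   used for calibration from externally tabulated data.
#' @return A `cutoff_table`: data.frame with columns `res_type`,
#'   `buried_cutoff`, `exposed_cutoff` (Angstrom^2), `n_train`, `fallback`.
#' @export
calibrate_calpha_cutoffs <- function(training, probe_lowres = 3.5,
                                     probe_hires = 1.4, buried = 7,
                                     exposed = 10, min_per_type = 50L,
                                     n_points = 960L, reference = "synthetic",
                                     pairs = NULL) {
  if (is.null(pairs)) {
    if (length(training) == 0) stop("empty training list")
    pairs <- do.call(rbind, lapply(training, function(s)
      calibration_pairs(s, probe_lowres, probe_hires, n_points, reference)))
  }
  pairs <- pairs[!is.na(pairs$rel_acc) & pairs$res_type %in% AA1, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no usable calibration pairs")

  eval_fit <- function(x, y) {
    fit <- isoreg(x, y)
    xs <- sort(x)
    vapply(c(buried, exposed), function(at)
      approx(xs, fit$yf, xout = at, rule = 2, ties = "ordered")$y, numeric(1))
  }
  pooled <- eval_fit(pairs$rel_acc, pairs$ca_asa)

  rows <- lapply(AA1, function(aa) {
    sel <- pairs$res_type == aa
    n <- sum(sel)
    if (n >= min_per_type) {
      v <- eval_fit(pairs$rel_acc[sel], pairs$ca_asa[sel])
      fb <- "none"
    } else {
      v <- pooled
      fb <- "pooled"
    }
    if (v[2] <= v[1]) {  # flat monotone fit between the two percentages
      v[2] <- v[1] + 1e-6
      fb <- if (fb == "none") "degenerate" else paste(fb, "degenerate", sep = "+")
    }
    data.frame(res_type = aa, buried_cutoff = v[1], exposed_cutoff = v[2],
               n_train = n, fallback = fb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- c(buried = buried, exposed = exposed)
  attr(out, "probe_lowres") <- probe_lowres
  attr(out, "probe_hires") <- probe_hires
  class(out) <- c("cutoff_table", "data.frame")
  out
}

# (relative accessibility all-atom, CA ASA of the CA-trace rendition) pairs,
# pooled over the complex and each isolated chain
calibration_pairs <- function(structure, probe_lowres, probe_hires,
                              n_points, reference) {
  if (any(structure$chains$calpha_only))
    stop("calibration requires all-atom training structures")
  forms <- c(list(structure),
             lapply(structure$chains$chain_id, function(ch)
               extract_chain(structure, ch)))
  do.call(rbind, lapply(forms, function(s) {
    aa <- compute_sasa(s, probe_hires, n_points, reference)
    ca <- compute_sasa(make_calpha(s), probe_lowres, n_points, reference = NULL)
    stopifnot(identical(res_key(aa$chain, aa$resno, aa$insert),
                        res_key(ca$chain, ca$resno, ca$insert)))
    data.frame(res_type = aa$res_type, rel_acc = aa$rel_acc,
               ca_asa = ca$abs_asa, stringsAsFactors = FALSE)
  }))
}

#' Read / write a cutoff table
#'
#' Tab-separated with columns `res_type`, `buried_cutoff`, `exposed_cutoff`,
#' `n_train`, `fallback`.
#' @param x A `cutoff_table`.
#' @param path File path.
#' @export
write_cutoff_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cutoff_table
#' @export
read_cutoff_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("res_type", "buried_cutoff", "exposed_cutoff")
  if (!all(need %in% names(out))) stop("not a cutoff table: ", path)
  if (any(out$buried_cutoff >= out$exposed_cutoff))
    stop("invalid cutoff table: buried_cutoff must be < exposed_cutoff")
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' C-alpha-regime interface detection
#'
#' Applies the calibrated absolute cutoffs to C-alpha ASA profiles computed
#' at the low-resolution probe: a residue is an interface residue when its
#' C-alpha ASA in the complex is strictly below its type's buried cutoff
#' and strictly above the exposed cutoff in isolation.
#'
#' @param complex_profile `sasa_profile` of the C-alpha-only complex at the
#'   3.5 Angstrom probe.
#' @param isolated Named list of per-chain isolated `sasa_profile`s.
#' @param cutoffs A `cutoff_table` from [calibrate_calpha_cutoffs()] or
#'   [read_cutoff_table()].
#' @return An `interface_set` with `regime = "calpha"`; `complex_value` and
#'   `isolated_value` are absolute C-alpha ASA (Angstrom^2).
#' @export
detect_interface_calpha <- function(complex_profile, isolated, cutoffs) {
  if (!isTRUE(attr(complex_profile, "calpha")))
    stop("C-alpha regime requires a profile of a C-alpha-only structure ",
         "(see make_calpha)")
  stopifnot(inherits(cutoffs, "cutoff_table"))
  joined <- join_profiles(complex_profile, isolated, value = "abs_asa")
  m <- match(joined$res_type, cutoffs$res_type)
  usable <- !is.na(m)
  if (any(!usable))
    warning(sum(!usable), " residue(s) of types absent from the cutoff ",
            "table excluded from classification")
  bc <- cutoffs$buried_cutoff[m]
  ec <- cutoffs$exposed_cutoff[m]
  hit <- usable & joined$complex_value < bc & joined$isolated_value > ec
  hit[is.na(hit)] <- FALSE
  out <- joined[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regime") <- "calpha"
  attr(out, "excluded") <- joined[!usable, c("chain", "resno", "insert", "res_type")]
  class(out) <- c("interface_set", "data.frame")
  out
}

#' Interface detection for a whole assembly via subcomplexes
#'
#' Runs detection per subcomplex (each chain plus its near neighbours,
#' treated as an independent structure) and takes each chain's interface
#' from its own subcomplex. This keeps the SASA problem small for large
#' cages while every relevant occluder is present.
#'
#' @param structure A [coat_structure].
#' @param cutoff Near-neighbour cutoff in Angstrom.
#' @param regime `"all-atom"` or `"calpha"`.
#' @param cutoffs `cutoff_table`, required for the C-alpha regime.
#' @param probe_radius Probe; default 1.4 (all-atom) or 3.5 (C-alpha).
#' @inheritParams compute_sasa
#' @return A combined `interface_set` over all chains.
#' @export
detect_interface_assembly <- function(structure, cutoff = 5.0,
                                      regime = c("all-atom", "calpha"),
                                      cutoffs = NULL, probe_radius = NULL,
                                      n_points = 960L, reference = "synthetic") {
  regime <- match.arg(regime)
  if (is.null(probe_radius)) probe_radius <- if (regime == "calpha") 3.5 else 1.4
  if (regime == "calpha" && is.null(cutoffs))
    stop("the C-alpha regime requires a cutoff table")
  subs <- build_subcomplexes(structure, cutoff)
  parts <- lapply(subs, function(sc) {
    s <- subcomplex_structure(structure, sc)
    cp <- compute_sasa(s, probe_radius, n_points, reference)
    iso <- isolated_chain_sasa(s, sc$focal, probe_radius, n_points, reference)
    iso <- setNames(list(iso), sc$focal)
    cp <- cp[cp$chain == sc$focal, , drop = FALSE]
    if (regime == "calpha") detect_interface_calpha(cp, iso, cutoffs)
    else detect_interface_allatom(cp, iso)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "regime") <- regime
  class(out) <- c("interface_set", "data.frame")
  out
}

#' Compare two interface sets
#'
#' Per-chain set arithmetic on residue identifiers (author numbering plus
#' insertion code): shared residues, residues unique to each set, and the
#' Jaccard index.
#'
#' @param a,b `interface_set` objects with intersecting chain ids.
#' @return data.frame with one row per common chain: `chain`, `n_shared`,
#'   `n_only_a`, `n_only_b`, `jaccard`, plus comma-separated id columns
#'   `shared`, `only_a`, `only_b`.
#' @export
compare_interfaces <- function(a, b) {
  chains <- intersect(unique(a$chain), unique(b$chain))
  if (length(chains) == 0) stop("interface sets share no chain ids")
  rid <- function(x) paste0(x$res_type, x$resno, x$insert)
  do.call(rbind, lapply(chains, function(ch) {
    ra <- rid(a[a$chain == ch, ]); rb <- rid(b[b$chain == ch, ])
    sh <- intersect(ra, rb)
    un <- union(ra, rb)
    data.frame(chain = ch, n_shared = length(sh),
               n_only_a = length(setdiff(ra, rb)),
               n_only_b = length(setdiff(rb, ra)),
               jaccard = if (length(un)) length(sh) / length(un) else NA_real_,
               shared = paste(sh, collapse = ","),
               only_a = paste(setdiff(ra, rb), collapse = ","),
               only_b = paste(setdiff(rb, ra), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
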