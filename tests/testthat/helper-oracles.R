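# shared helpers: residue keys, an independently coded brute-force
# interface oracle, and small structure builders

rkey <- function(chain, resno, insert = "") {
  if (length(chain) == 0) return(character(0))
  paste0(chain, ":", resno, insert)
}

# brute-force re-implementation of the dual accessibility rule, sharing no
# detection code with detect_interface_allatom: it builds the single-chain
# structures itself, converts absolute areas to percentages from the raw
# reference table, and applies the two comparisons in a plain loop
brute_force_interface <- function(structure, n_points = 480L,
                                  probe = 1.4, buried = 7, exposed = 10) {
  ref <- reference_max_asa("synthetic", n_points = n_points)
  cp <- compute_sasa(structure, probe, n_points, reference = NULL)
  hits <- character(0)
  for (ch in structure$chains$chain_id) {
    lone <- structure
    lone$atom <- lone$atom[lone$atom$chain == ch, , drop = FALSE]
    lone <- coatmap:::new_structure(lone$atom, lone$source_id)
    ip <- compute_sasa(lone, probe, n_points, reference = NULL)
    for (r in seq_len(nrow(ip))) {
      i <- which(cp$chain == ch & cp$resno == ip$resno[r] &
                   cp$insert == ip$insert[r])
      mx <- ref[[ip$res_type[r]]]
      if (is.null(mx) || is.na(mx)) next
      acc_complex <- 100 * cp$abs_asa[i] / mx
      acc_isolated <- 100 * ip$abs_asa[r] / mx
      if (acc_complex < buried && acc_isolated > exposed)
        hits <- c(hits, rkey(ch, ip$resno[r], ip$insert[r]))
    }
  }
  sort(hits)
}

interface_keys <- function(ifc) sort(rkey(ifc$chain, ifc$resno, ifc$insert))

# structure from bare atom coordinates (one single-atom residue per row)
atoms_structure <- function(xyz, radius = 1.87, chain = "A",
                            res_type = "A") {
  n <- nrow(xyz)
  coatmap:::new_structure(data.frame(
    chain = rep_len(chain, n), resno = seq_len(n), insert = "",
    resid = "ALA", res_type = rep_len(res_type, n), elety = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n), stringsAsFactors = FALSE), "test")
}

# C-alpha-only two-chain structure with a given closest inter-chain
# CA-CA distance
two_chain_ca <- function(min_dist) {
  a <- cbind(seq(0, 19) * 3.8, 0, 0)
  b <- cbind(seq(0, 19) * 3.8, min_dist, 0)
  at <- rbind(
    data.frame(chain = "A", resno = 1:20, x = a[, 1], y = a[, 2], z = a[, 3]),
    data.frame(chain = "B", resno = 1:20, x = b[, 1], y = b[, 2], z = b[, 3]))
  coatmap:::new_structure(data.frame(
    chain = at$chain, resno = at$resno, insert = "", resid = "GLY",
    res_type = "G", elety = "CA", element = "C",
    x = at$x, y = at$y, z = at$z, radius = 1.87,
    stringsAsFactors = FALSE), "two-chain")
}

# minimal sasa_profile for rule-level interface tests
fake_profile <- function(chain, resno, res_type, value, calpha = FALSE,
                         column = c("rel_acc", "abs_asa")) {
  column <- match.arg(column)
  prof <- data.frame(chain = chain, resno = resno, insert = "",
                     res_type = res_type, abs_asa = NA_real_,
                     rel_acc = NA_real_, stringsAsFactors = FALSE)
  prof[[column]] <- value
  attr(prof, "calpha") <- calpha
  class(prof) <- c("sasa_profile", "data.frame")
  prof
}

per_chain_f1 <- function(reference, predicted, chains) {
  vapply(chains, function(ch) {
    rk <- rkey(reference$chain, reference$resno,
               reference$insert)[reference$chain == ch]
    pk <- rkey(predicted$chain, predicted$resno,
               predicted$insert)[predicted$chain == ch]
    tp <- length(intersect(rk, pk))
    if (length(rk) + length(pk) == 0) return(NA_real_)
    2 * tp / (length(rk) + length(pk))
  }, numeric(1))
}
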