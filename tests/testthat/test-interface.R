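test_that("the dual accessibility rule uses strict thresholds", {
  cp <- fake_profile("A", 1:5, "L", c(5, 8, 5, 6.999, 7.0))
  iso <- list(A = fake_profile("A", 1:5, "L", c(15, 15, 9, 10.001, 15)))
  ifc <- detect_interface_allatom(cp, iso)
  # buried & exposed; not buried; core (not exposed); boundary cases
  expect_identical(ifc$resno, c(1L, 4L))
})

test_that("residues without reference accessibility are reported, not dropped silently", {
  cp <- fake_profile("A", 1:2, c("L", "X"), c(5, NA))
  iso <- list(A = fake_profile("A", 1:2, c("L", "X"), c(15, NA)))
  expect_warning(ifc <- detect_interface_allatom(cp, iso),
                 "without reference")
  expect_identical(ifc$resno, 1L)
  expect_identical(attr(ifc, "excluded")$resno, 2L)
})

test_that("all-atom detection equals the brute-force oracle on generated complexes", {
  scns <- list(complex_scenario(n_chains = 2, length = 20, seed = 21),
               complex_scenario(n_chains = 3, length = 20, seed = 22),
               complex_scenario(geometry = "bead-lattice", seed = 23))
  for (scn in scns) {
    gc <- generate_complex(scn)
    cp <- compute_sasa(gc$all_atom, 1.4, 480)
    iso <- isolated_profiles(gc$all_atom, 1.4, 480)
    ifc <- suppressWarnings(detect_interface_allatom(cp, iso))
    expect_identical(interface_keys(ifc),
                     brute_force_interface(gc$all_atom, 480))
  }
})

test_that("a chain out of occlusion range yields an empty interface", {
  gc <- generate_complex(complex_scenario(length = 15, packing = 40, seed = 5),
                         repack = FALSE)
  cp <- compute_sasa(gc$all_atom, 1.4, 240)
  iso <- isolated_profiles(gc$all_atom, 1.4, 240)
  expect_identical(nrow(detect_interface_allatom(cp, iso)), 0L)
  ct <- calibrate_calpha_cutoffs(NULL, pairs = data.frame(
    res_type = rep(coatmap:::AA1, each = 4),
    rel_acc = rep(c(0, 30, 60, 100), 20),
    ca_asa = rep(c(0, 30, 60, 100), 20)), min_per_type = 3)
  cpc <- compute_sasa(gc$calpha, 3.5, 240, reference = NULL)
  isoc <- isolated_profiles(gc$calpha, 3.5, 240, reference = NULL)
  expect_identical(nrow(detect_interface_calpha(cpc, isoc, ct)), 0L)
})

test_that("calibration recovers a known monotone generating function", {
  set.seed(1)
  # exact linear map per residue type: ca_asa = a + b * rel_acc
  ab <- data.frame(res_type = coatmap:::AA1,
                   a = seq(2, 12, length.out = 20),
                   b = seq(0.8, 2.2, length.out = 20))
  pairs <- do.call(rbind, lapply(seq_len(20), function(i) {
    x <- runif(200, 0, 60)
    data.frame(res_type = ab$res_type[i], rel_acc = x,
               ca_asa = ab$a[i] + ab$b[i] * x)
  }))
  ct <- calibrate_calpha_cutoffs(NULL, pairs = pairs)
  for (i in seq_len(20)) {
    row <- ct[ct$res_type == ab$res_type[i], ]
    expect_equal(row$buried_cutoff, ab$a[i] + ab$b[i] * 7, tolerance = 0.02)
    expect_equal(row$exposed_cutoff, ab$a[i] + ab$b[i] * 10, tolerance = 0.02)
    expect_identical(row$fallback, "none")
  }
})

test_that("types missing from training fall back to the pooled fit, flagged", {
  set.seed(2)
  x <- runif(300, 0, 60)
  pairs <- data.frame(res_type = sample(setdiff(coatmap:::AA1, "W"), 300,
                                        replace = TRUE),
                      rel_acc = x, ca_asa = 3 + 1.5 * x)
  ct <- calibrate_calpha_cutoffs(NULL, pairs = pairs, min_per_type = 5)
  expect_match(ct$fallback[ct$res_type == "W"], "pooled")
  expect_equal(ct$buried_cutoff[ct$res_type == "W"], 3 + 1.5 * 7,
               tolerance = 0.05)
  expect_error(calibrate_calpha_cutoffs(list()), "empty training")
})

test_that("calibrated cutoffs are strictly ordered for every residue type", {
  train <- lapply(1:4, function(i) generate_complex(
    complex_scenario(n_chains = 3, length = 30, seed = 400 + i))$all_atom)
  ct <- calibrate_calpha_cutoffs(train, n_points = 240, min_per_type = 30)
  expect_true(all(ct$buried_cutoff < ct$exposed_cutoff))
  expect_true(all(ct$buried_cutoff >= 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cutoff_table(ct, f)
  ct2 <- read_cutoff_table(f)
  expect_equal(ct2$buried_cutoff, ct$buried_cutoff, tolerance = 1e-9)
})

test_that("the C-alpha rule applies per-type absolute cutoffs strictly", {
  ct <- structure(data.frame(res_type = "L", buried_cutoff = 30,
                             exposed_cutoff = 45, n_train = 100,
                             fallback = "none", stringsAsFactors = FALSE),
                  class = c("cutoff_table", "data.frame"))
  cp <- fake_profile("A", 1:3, "L", c(12, 12, 30), calpha = TRUE,
                     column = "abs_asa")
  iso <- list(A = fake_profile("A", 1:3, "L", c(85, 40, 85), calpha = TRUE,
                               column = "abs_asa"))
  ifc <- detect_interface_calpha(cp, iso, ct)
  expect_identical(ifc$resno, 1L)  # 12/85 in; 12/40 fails exposure; 30 not buried
  # regime guard: an all-atom profile is rejected
  cp_aa <- fake_profile("A", 1, "L", 12, calpha = FALSE, column = "abs_asa")
  expect_error(detect_interface_calpha(cp_aa, iso, ct), "C-alpha regime")
})

test_that("interface comparison reports shared residues and Jaccard overlap", {
  mk <- function(resno, types) structure(
    data.frame(chain = "G", resno = resno, insert = "", res_type = types,
               complex_value = 1, isolated_value = 20,
               stringsAsFactors = FALSE),
    class = c("interface_set", "data.frame"))
  a <- mk(c(845L, 849L, 852L), c("L", "V", "R"))
  b <- mk(c(845L, 852L, 861L), c("L", "R", "W"))
  cmp <- compare_interfaces(a, b)
  expect_identical(cmp$n_shared, 2L)
  expect_setequal(strsplit(cmp$shared, ",")[[1]], c("L845", "R852"))
  expect_equal(cmp$jaccard, 0.5)
  expect_equal(compare_interfaces(a, a)$jaccard, 1.0)
  b2 <- mk(c(1L, 2L), c("A", "A"))
  expect_equal(compare_interfaces(a, b2)$jaccard, 0.0)
  b3 <- b; b3$chain <- "Z"
  expect_error(compare_interfaces(a, b3), "no chain ids")
})
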