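test_that("homolog filter applies strict identity and coverage thresholds", {
  # query of 100 residues, alignments built column by column
  q <- strrep("A", 100)
  mk_hit <- function(n_ident, span) {
    h <- rep("-", 100)
    h[span[1]:span[2]] <- "V"
    h[span[1]:(span[1] + n_ident - 1)] <- "A"
    list(query_aln = q, hit_aln = paste(h, collapse = ""))
  }
  cands <- list(good = mk_hit(35, c(11, 90)),     # 35% id, 80% coverage
                border = mk_hit(30, c(6, 95)),    # exactly 30% id
                short = mk_hit(50, c(18, 82)))    # 50% id, 65% coverage
  res <- filter_homologs(q, cands)
  expect_identical(res$kept, c(TRUE, FALSE, FALSE))
  expect_equal(res$identity, c(35, 30, 50))
  expect_equal(res$coverage, c(80, 90, 65))

  # monotone in both thresholds; idempotent on the kept subset
  res2 <- filter_homologs(q, cands, min_identity = 40)
  expect_true(all(res2$kept <= res$kept))
  res3 <- filter_homologs(q, cands[res$kept], 30, 70)
  expect_true(all(res3$kept))
  expect_error(filter_homologs(q, list(x = "AVAVAV"), align = FALSE),
               "no alignment")
})

test_that("conserved columns score strictly lower than diverse columns", {
  seqs <- c(s1 = "AAAC", s2 = "ARAC", s3 = "ANAC", s4 = "ADAC")
  prof <- conservation_scores(msa(seqs))
  # columns 1 and 3 identical, column 2 maximally diverse
  expect_lt(prof$score[1], prof$score[2])
  expect_lt(prof$score[3], prof$score[2])
  expect_equal(mean(prof$score), 0, tolerance = 1e-12)
  expect_equal(sd(prof$score), 1, tolerance = 1e-12)
})

test_that("an alignment of identical sequences scores zero everywhere", {
  seqs <- setNames(rep("ARNDK", 4), paste0("s", 1:4))
  prof <- conservation_scores(msa(seqs))
  expect_identical(prof$score, rep(0, 5))
})

test_that("scores ignore sequence order and renormalise under duplication", {
  scn <- evolution_scenario(n_taxa = 8, n_sites = 60, seed = 13)
  m <- simulate_family(scn)
  p1 <- conservation_scores(m)
  seqs <- apply(m$mat, 1, paste, collapse = "")
  m2 <- msa(seqs[rev(names(seqs))], target = m$target)
  expect_equal(conservation_scores(m2)$score, p1$score, tolerance = 1e-12)
  dup <- c(seqs, setNames(seqs, paste0(names(seqs), "_dup")))
  p3 <- conservation_scores(msa(dup, target = m$target))
  expect_equal(p3$score, p1$score, tolerance = 1e-12)
})

test_that("heavily gapped columns are flagged and excluded from group means", {
  seqs <- c(t = "ARND", a = "-RND", b = "-RQD", c = "-RED", d = "-RWD")
  prof <- conservation_scores(msa(seqs, target = "t"))
  expect_true(prof$gap_flag[1])
  expect_false(any(prof$gap_flag[-1]))
})

test_that("slow sites score as more conserved than fast sites", {
  wins <- 0L
  for (sd in 1:20) {
    m <- simulate_family(evolution_scenario(n_taxa = 16, n_sites = 300,
                                            seed = sd))
    prof <- conservation_scores(m)
    cls <- attr(m, "site_class")
    wins <- wins + (mean(prof$score[cls == "interface"]) <
                      mean(prof$score[cls == "surface"]))
  }
  expect_gte(wins, 18L)
})

test_that("surface classification is exhaustive, disjoint, interface-first", {
  prof <- fake_profile("A", 1:4, "L", c(50, 25, 4, 2))
  prof$abs_asa <- prof$rel_acc
  ifc <- structure(data.frame(chain = "A", resno = 4L, insert = "",
                              res_type = "L", complex_value = 1,
                              isolated_value = 20, stringsAsFactors = FALSE),
                   class = c("interface_set", "data.frame"))
  part <- classify_surface(prof, ifc)
  expect_identical(part$class, c("surface", "surface", "buried", "interface"))
  expect_identical(part$position, 1:4)
})

test_that("interface vs surface comparison separates constructed groups", {
  prof <- structure(data.frame(position = 1:40, column = 1:40,
                               score = c(rep(-1.2, 10), rep(0.4, 30)),
                               raw = 0, n_eff = 8, gap_flag = FALSE),
                    class = c("conservation_profile", "data.frame"))
  part <- data.frame(chain = "A", resno = 1:40, insert = "", res_type = "L",
                     position = 1:40,
                     class = c(rep("interface", 10), rep("surface", 30)))
  cmp <- compare_interface_conservation(prof, part, n_boot = 500, seed = 1)
  expect_lt(cmp$difference, 0)
  expect_lt(cmp$ci[2], 0)  # interval excludes zero
  expect_identical(c(cmp$n_interface, cmp$n_surface), c(10L, 30L))

  # both groups from one distribution: interval usually brackets zero
  set.seed(99)
  covers <- 0L
  for (k in 1:10) {
    prof$score <- rnorm(40)
    cmp0 <- compare_interface_conservation(prof, part, n_boot = 500, seed = k)
    covers <- covers + (cmp0$ci[1] <= 0 && cmp0$ci[2] >= 0)
  }
  expect_gte(covers, 8L)

  part1 <- part; part1$class[2:10] <- "surface"
  expect_warning(
    compare_interface_conservation(prof, part1, n_boot = 200, seed = 1),
    "size 1")
  part2 <- part; part2$class <- "surface"
  expect_error(compare_interface_conservation(prof, part2, n_boot = 200),
               "non-empty")
})

test_that("alignments round-trip through FASTA", {
  m <- simulate_family(evolution_scenario(n_taxa = 6, n_sites = 30, seed = 2))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, f)
  m2 <- read_msa(f, target = m$target)
  expect_identical(m2$mat, m$mat)
})
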