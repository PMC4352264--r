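test_that("all generators are pure functions of their seed", {
  expect_identical(gen_proteome(c(1, 2, 3), seed = 5),
                   gen_proteome(c(1, 2, 3), seed = 5))
  expect_identical(gen_codon_pair(50, 0.5, 0.1, seed = 5),
                   gen_codon_pair(50, 0.5, 0.1, seed = 5))
  expect_identical(gen_locus_table(seed = 5), gen_locus_table(seed = 5))
  plant <- tibble::tibble(promoter_id = "p", motif = "ABRE", count = 2L)
  expect_identical(gen_promoters(plant, seed = 5), gen_promoters(plant, seed = 5))
  expect_identical(gen_expression(seed = 5), gen_expression(seed = 5))
  qplan <- tibble::tibble(gene = "g", treatment = "cold", timepoint = 24, fold = 4)
  expect_identical(gen_qpcr(qplan, seed = 5), gen_qpcr(qplan, seed = 5))
  expect_identical(gen_alignment(c(2, 3), seed = 5), gen_alignment(c(2, 3), seed = 5))
  # different seeds differ
  expect_false(identical(gen_proteome(c(1, 2, 3), seed = 5)$records$sequence,
                         gen_proteome(c(1, 2, 3), seed = 6)$records$sequence))
  # and the caller's RNG stream is untouched
  withr::local_seed(1)
  before <- runif(1)
  withr::local_seed(1)
  invisible(gen_proteome(c(1), seed = 99))
  expect_equal(runif(1), before)
})

test_that("gen_proteome plants exactly the requested motifs", {
  g <- gen_proteome(c(0, 1, 4), seed = 2)
  expect_equal(nrow(g$records), 3)
  expect_equal(nrow(g$truth), 5)
  hits <- scan_ccch(g$records, scan_params(overlap_policy = "all_matches"))
  cols <- c("protein_id", "start", "end", "i", "j")
  expect_equal(as.data.frame(dplyr::arrange(hits[, cols], protein_id, start)),
               as.data.frame(dplyr::arrange(g$truth[, cols], protein_id, start)))
  # zero planting in a C/H-free background scans clean
  empty <- gen_proteome(c(0, 0), seed = 3)
  expect_equal(nrow(scan_ccch(empty$records,
                              scan_params(overlap_policy = "all_matches"))), 0)
  # pattern table is honored
  pt <- tibble::tibble(i = c(8L, 17L), j = c(5L, 4L), count = c(2L, 1L))
  g2 <- gen_proteome(c(2, 1), pattern_table = pt, seed = 4)
  expect_equal(sort(table(g2$truth$pattern)),
               sort(table(c(rep("C-X8-C-X5-C-X3-H", 2), "C-X17-C-X4-C-X3-H"))),
               ignore_attr = TRUE)
})

test_that("gen_codon_pair controls realized substitution counts", {
  g0 <- gen_codon_pair(100, omega = 1, ks_target = 0, seed = 1)
  expect_equal(g0$seq_a, g0$seq_b)
  k0 <- kaks(g0$seq_a, g0$seq_b)
  expect_equal(c(k0$Ka, k0$Ks), c(0, 0))

  # realized truth counts vs the estimator's fractional Sd, Nd
  for (s in 1:5) {
    g <- gen_codon_pair(100, omega = 0.5, ks_target = 0.1, seed = s)
    k <- kaks(g$seq_a, g$seq_b)
    expect_lt(abs(k$Sd - g$truth$n_syn), 0.5)
    expect_lt(abs(k$Nd - g$truth$n_nonsyn), 0.5)
  }
  expect_error(gen_codon_pair(100, omega = 1, ks_target = 3), "saturation")

  # neutral simulation: estimator centers on omega = 1
  est <- vapply(1:10, function(s) {
    g <- gen_codon_pair(300, omega = 1, ks_target = 0.2, seed = s)
    kaks(g$seq_a, g$seq_b)$ratio
  }, numeric(1))
  expect_gt(mean(est), 0.8)
  expect_lt(mean(est), 1.2)
})

test_that("gen_locus_table plants recoverable duplication types", {
  gl <- gen_locus_table(n_tandem = 3, n_homeologous = 15, n_paralogous = 1,
                        seed = 8)
  out <- classify_duplication(gl$loci, gl$truth[, c("gene_a", "gene_b")])
  expect_equal(out$dup_type, gl$truth$dup_type)
  expect_equal(sum(out$dup_type == "homeologous"), 15)
  # a pair planted with five intervening loci is paralogous (strict boundary)
  gb <- gen_locus_table(n_tandem = 1, n_homeologous = 1, n_paralogous = 0,
                        tandem_intervening = 5, seed = 9)
  outb <- classify_duplication(gb$loci, gb$truth[, c("gene_a", "gene_b")])
  expect_equal(outb$dup_type[gb$truth$dup_type == "tandem"], "paralogous")
})

test_that("gen_expression realizes planted pair correlations", {
  plan <- tibble::tibble(gene_a = "a", gene_b = "b", r = 1)
  ge <- gen_expression(n_background = 4, pairs_plan = plan, seed = 10)
  ps <- pair_expression_similarity(ge$expr, plan)
  expect_equal(ps$r, 1, tolerance = 1e-6)
})
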