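test_that("chromosome-pair and locus-based duplication classification", {
  expect_equal(classify_chromosome_pair("Chr5a", "Chr5b"), "homeologous")
  expect_equal(classify_chromosome_pair("Chr3a", "Chr6b"), "paralogous")
  expect_equal(classify_chromosome_pair("Chr1a", "Chr1a"), "same_chromosome")
  expect_equal(classify_chromosome_pair("unknown", "Chr1a"), "unknown")
  expect_error(classify_chromosome_pair("5a", "Chr1a"), "malformed")

  loci <- tibble::tibble(
    gene_id = c("t1", "t2", "far", "h1", "h2", "u1"),
    chromosome = c("Chr1a", "Chr1a", "Chr1a", "Chr5a", "Chr5b", "unknown"),
    ordinal = c(12L, 13L, 30L, 1L, 1L, 1L),
    start = 1, end = 10, strand = "+")
  pairs <- tibble::tibble(gene_a = c("t1", "t1", "h1", "t1"),
                          gene_b = c("t2", "far", "h2", "u1"))
  out <- classify_duplication(loci, pairs)
  expect_equal(out$dup_type, c("tandem", "paralogous", "homeologous", "unknown"))

  # boundary: exactly five intervening loci is not tandem
  loci2 <- tibble::tibble(gene_id = c("a", "b"), chromosome = "Chr2a",
                          ordinal = c(1L, 7L), start = 1, end = 10, strand = "+")
  out2 <- classify_duplication(loci2, tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_equal(out2$dup_type, "paralogous")
  # four intervening loci is tandem
  loci2$ordinal <- c(1L, 6L)
  out3 <- classify_duplication(loci2, tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_equal(out3$dup_type, "tandem")
})

test_that("ng86_sites matches enumeration of all single-nucleotide mutants", {
  expect_equal(ng86_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_sites("GGG"), c(s = 1, n = 2))
  expect_equal(ng86_sites("ATG"), c(s = 0, n = 3))
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("QQQ"), "not a codon")
  # s + n = 3 for every sense codon, under both stop policies
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cod in sense) {
    expect_equal(sum(ng86_sites(cod)), 3)
    expect_equal(sum(ng86_sites(cod, "nonsynonymous")), 3)
  }
})

test_that("kaks reproduces hand-enumerated NG86/JC values and is symmetric", {
  same <- kaks("TTTGGGGGG", "TTTGGGGGG")
  expect_equal(c(same$Ka, same$Ks), c(0, 0))
  expect_true(is.na(same$ratio))
  expect_equal(same$selection, "neutral")

  k <- kaks("TTTGGGGGG", "TTCGGGGGG")
  expect_equal(k$S, 7 / 3)
  expect_equal(c(k$Sd, k$Nd), c(1, 0))
  expect_equal(k$Ks, -(3 / 4) * log(1 - (4 / 3) * (3 / 7)))
  expect_equal(k$Ka, 0)
  expect_equal(k$S + k$N, 3 * k$n_codons)

  withr::local_seed(17)
  for (r in 1:5) {
    g <- gen_codon_pair(60, omega = 0.8, ks_target = 0.15, seed = r)
    fwd <- kaks(g$seq_a, g$seq_b)
    rev <- kaks(g$seq_b, g$seq_a)
    expect_equal(fwd$Ks, rev$Ks)
    expect_equal(fwd$Ka, rev$Ka)
    # JC correction dominates the raw proportion
    expect_gte(fwd$Ks, fwd$ps)
    expect_gte(fwd$Ka, fwd$pn)
  }

  # saturation guard
  expect_error(kaks(strrep("GGG", 30), strrep("CCC", 30)), "saturation")
})

test_that("codons with gaps or ambiguity are skipped pairwise", {
  k <- kaks("TTT---GGGAAA", "TTCNNNGGGAAA")
  expect_equal(k$n_codons, 3)
  expect_equal(k$Sd, 1)
  expect_equal(k$S, 1 / 3 + 1 + 1 / 3)
})

test_that("classify_selection follows the published rule including Ks = 0", {
  expect_equal(classify_selection(0.052, 0.039), "diversifying")
  expect_equal(classify_selection(0.019, 0.041), "purifying")
  expect_equal(classify_selection(0.041, 0), "diversifying")
  expect_equal(classify_selection(0, 0), "neutral")
  expect_equal(classify_selection(0.05, 0.05), "neutral")
})

test_that("divergence_time applies the grass molecular clock", {
  expect_equal(round(divergence_time(0.163), 1), 12.5)
  expect_equal(round(divergence_time(0.237), 1), 18.2)
  expect_true(is.na(divergence_time(0)))
  expect_equal(divergence_time(0, na_for_zero = FALSE), 0)
  # linear and increasing
  ks <- seq(0, 1, by = 0.1)
  t <- divergence_time(ks, na_for_zero = FALSE)
  expect_equal(t, ks / (2 * 6.5e-9) * 1e-6)
  expect_true(all(diff(t) > 0))
})

test_that("the packaged selection table is internally consistent", {
  tab <- pvc3h_selection_table()
  expect_equal(nrow(tab), 19)
  expect_equal(sum(is.na(tab$ks) | tab$ks == 0), 3)
  # our classifier reproduces the printed selection calls
  calls <- classify_selection(tab$ka, tab$ks)
  expect_equal(calls, tolower(tab$selection))
})
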