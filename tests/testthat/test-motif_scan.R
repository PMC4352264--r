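test_that("scan_ccch finds exact template hits and nothing in anchor-free sequences", {
  rec <- tibble::tibble(id = "p1", sequence = paste0(
    "C", strrep("A", 8), "C", strrep("A", 5), "C", "AAA", "H"))
  hits <- scan_ccch(rec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pattern, "C-X8-C-X5-C-X3-H")
  expect_equal(c(hits$start, hits$end), c(1L, 20L))

  expect_equal(nrow(scan_ccch(tibble::tibble(id = "q", sequence = "MKHHHAAA"))), 0)
})

test_that("all_matches mode equals the brute-force anchor enumeration", {
  withr::local_seed(11)
  params <- scan_params(overlap_policy = "all_matches")
  for (r in 1:30) {
    seq <- random_seq(200, AA_ALL)
    hits <- scan_ccch(tibble::tibble(id = "s", sequence = seq), params)
    oracle <- brute_force_ccch(seq)
    got <- dplyr::arrange(hits[, c("start", "end", "i", "j", "k")], start, i, j)
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("overlap policies respect the expected set and disjointness relations", {
  withr::local_seed(3)
  all_p <- scan_params(overlap_policy = "all_matches")
  for (r in 1:20) {
    rec <- tibble::tibble(id = "s", sequence = random_seq(300, c("C", "H", "A", "G")))
    a <- scan_ccch(rec, all_p)
    nv <- scan_ccch(rec)
    # subset relation
    key <- function(h) paste(h$start, h$i, h$j)
    expect_true(all(key(nv) %in% key(a)))
    # nonoverlapping hits are pairwise disjoint, in order
    if (nrow(nv) > 1) {
      expect_true(all(nv$start[-1] > nv$end[-nrow(nv)]))
    }
    # every hit satisfies the anchors and span equation
    for (h in seq_len(nrow(a))) {
      expect_equal(a$end[h] - a$start[h] + 1, a$i[h] + a$j[h] + a$k[h] + 4)
      ch <- strsplit(rec$sequence, "")[[1]]
      expect_equal(ch[a$start[h]], "C")
      expect_equal(ch[a$start[h] + a$i[h] + 1], "C")
      expect_equal(ch[a$start[h] + a$i[h] + a$j[h] + 2], "C")
      expect_equal(ch[a$end[h]], "H")
    }
  }
})

test_that("tally_motifs counts patterns, proteins, and totals consistently", {
  recs <- tibble::tibble(id = c("a", "b", "c"), sequence = "X")
  hits <- tibble::tibble(
    protein_id = c("a", "b", "b", "c", "c", "c"),
    start = 1L, end = 20L, i = 8L, j = 5L, k = 3L,
    pattern = "C-X8-C-X5-C-X3-H")
  tl <- tally_motifs(hits, recs)
  expect_equal(tl$totals$n_proteins, 3)
  expect_equal(tl$totals$n_motifs, 6)
  expect_equal(tl$motifs_per_protein$n_proteins, c(1L, 1L, 1L))
  expect_equal(sum(tl$per_pattern$n), sum(tl$per_protein$n_motifs))

  empty <- tally_motifs(hits[0, ], recs)
  expect_equal(empty$totals$n_motifs, 0)
  expect_equal(nrow(empty$motifs_per_protein), 0)
})

test_that("position_profile reproduces planted column distributions and IC bounds", {
  # all-C column: IC = log2(20); uniform column: IC = 0
  withr::local_seed(5)
  n_inst <- 40
  col_uniform <- rep(AA_ALL, 2)  # exactly uniform over 20 residues
  seqs <- vapply(seq_len(n_inst), function(ii) {
    spacer1 <- paste0(col_uniform[(ii - 1) %% 20 + 1],
                      random_seq(3, setdiff(AA_ALL, c("C", "H"))))
    paste0("C", spacer1, "C", random_seq(4, "A"), "C", "AAA", "H")
  }, character(1))
  recs <- tibble::tibble(id = sprintf("p%02d", 1:n_inst), sequence = seqs)
  hits <- scan_ccch(recs)
  prof <- position_profile(hits, recs)
  p1 <- dplyr::filter(prof, position == 1)
  expect_equal(p1$freq[p1$residue == "C"], 1)
  expect_equal(p1$ic[1], log2(20))
  p2 <- dplyr::filter(prof, position == 2)   # cycles uniformly over all 20
  expect_equal(p2$freq, rep(1 / 20, 20))
  expect_equal(p2$ic[1], 0)
  expect_true(all(prof$ic >= 0 & prof$ic <= log2(20) + 1e-12))
  # frequencies sum to 1 per column
  sums <- tapply(prof$freq, prof$position, sum)
  expect_equal(as.vector(sums), rep(1, max(prof$position)))

  mixed <- dplyr::bind_rows(hits, dplyr::mutate(hits[1, ], i = 5L,
                                                pattern = "C-X5-C-X4-C-X3-H"))
  expect_error(position_profile(mixed, recs), "mix")
})

test_that("protein_stats computes MW and a zero-charge isoelectric point", {
  g <- protein_stats(tibble::tibble(id = "g", sequence = "G"))
  expect_equal(g$mw_kda * 1000, 75.07, tolerance = 1e-4)

  withr::local_seed(9)
  recs <- tibble::tibble(id = sprintf("r%d", 1:10),
                         sequence = vapply(rep(80, 10), random_seq,
                                           character(1), alphabet = AA_ALL))
  st <- protein_stats(recs)
  # defining property: net charge at the reported pI is ~0
  for (r in seq_len(nrow(recs))) {
    counts <- table(factor(strsplit(recs$sequence[r], "")[[1]],
                           levels = AA_ALL))
    cnt <- setNames(as.numeric(counts[c("H", "K", "R", "D", "E", "C", "Y")]),
                    c("H", "K", "R", "D", "E", "C", "Y"))
    expect_lt(abs(ccchfam:::protein_net_charge(cnt, st$pi[r])), 1e-4)
  }

  acidic <- protein_stats(tibble::tibble(id = "a", sequence = "DDDD"))$pi
  basic <- protein_stats(tibble::tibble(id = "b", sequence = "KKKK"))$pi
  expect_lt(acidic, basic)
  expect_error(protein_stats(tibble::tibble(id = "e", sequence = "")), "empty")
})
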