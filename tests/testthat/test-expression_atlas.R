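test_that("normalize_log2 centers rows on the log2 scale", {
  ex <- tibble::tibble(gene_id = c("const", "dyadic"),
                       s1 = c(5, 0), s2 = c(5, 1), s3 = c(5, 3))
  out <- normalize_log2(ex)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(0, 0, 0))
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(-1, 0, 1))

  withr::local_seed(2)
  m <- tibble::tibble(gene_id = sprintf("g%d", 1:20))
  for (s in 1:8) m[[paste0("s", s)]] <- runif(20, 0, 100)
  norm <- normalize_log2(m)
  expect_true(all(abs(rowSums(as.matrix(norm[, -1]))) < 1e-9))
  # scaling every sample of a row equally leaves the centered output unchanged
  doubled <- m
  scols <- setdiff(names(m), "gene_id")
  doubled[3, scols] <- as.list((as.numeric(m[3, scols]) + 1) * 2 - 1)
  norm2 <- normalize_log2(doubled)
  expect_equal(as.numeric(norm2[3, scols]), as.numeric(norm[3, scols]))

  m$s1[1] <- -1
  expect_error(normalize_log2(m), "negative")
})

test_that("hcluster matches a brute-force average-linkage oracle", {
  withr::local_seed(8)
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:12))
  for (s in 1:6) expr[[paste0("s", s)]] <- rnorm(12)
  hc <- hcluster(expr, "genes")
  oracle_heights <- brute_force_average_linkage(as.matrix(expr[, -1]))
  expect_equal(sort(hc$hclust$height), oracle_heights, tolerance = 1e-9)

  # identical rows merge first at height 0
  expr2 <- expr
  expr2[2, -1] <- expr2[1, -1]
  hc2 <- hcluster(expr2, "genes")
  expect_equal(min(hc2$hclust$height), 0)
  expect_setequal(abs(hc2$hclust$merge[1, ]), c(1, 2))

  # permutation invariance (same merge heights)
  perm <- sample(12)
  hc3 <- hcluster(expr[perm, ], "genes")
  expect_equal(sort(hc3$hclust$height), sort(hc$hclust$height))

  expect_error(hcluster(expr[1, ], "genes"), "at least 2")
})

test_that("pair_expression_similarity scores identical, opposite, and planted pairs", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(1, 1, 8), s2 = c(2, 2, 4), s3 = c(8, 8, 1),
                         s4 = c(4, 4, 2))
  ps <- pair_expression_similarity(expr, tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_equal(ps$r, 1)
  expect_true(ps$similar)
  neg <- pair_expression_similarity(expr, tibble::tibble(gene_a = "a", gene_b = "c"),
                                    pseudocount = 0)
  expect_equal(neg$r, -1)
  expect_false(neg$similar)
  expect_error(
    pair_expression_similarity(expr, tibble::tibble(gene_a = "a", gene_b = "zz")),
    "zz")

  # planted correlations 0.95 vs 0.0: recovery and classification accuracy
  plan <- dplyr::bind_rows(
    tibble::tibble(gene_a = sprintf("H%02d", 1:50), gene_b = sprintf("h%02d", 1:50),
                   r = 0.95, selection = "purifying"),
    tibble::tibble(gene_a = sprintf("L%02d", 1:50), gene_b = sprintf("l%02d", 1:50),
                   r = 0, selection = "diversifying"))
  ge <- gen_expression(n_background = 5, n_samples = 21, pairs_plan = plan, seed = 14)
  ps <- pair_expression_similarity(ge$expr, plan, threshold = 0.8)
  expect_lt(abs(mean(ps$r[plan$r == 0.95]) - 0.95), 0.1)
  expect_lt(abs(mean(ps$r[plan$r == 0])), 0.1)
  correct <- mean(c(ps$similar[plan$r == 0.95], !ps$similar[plan$r == 0]))
  expect_gte(correct, 0.9)
  sm <- attr(ps, "summary")
  expect_equal(sort(sm$selection), c("diversifying", "purifying"))
  expect_gt(sm$frac_similar[sm$selection == "purifying"],
            sm$frac_similar[sm$selection == "diversifying"])
})

test_that("cluster_atlas separates planted co-expression blocks", {
  ge <- gen_expression(n_background = 24, n_clusters = 3, n_samples = 10,
                       noise_sd = 0.1, seed = 5)
  ca <- cluster_atlas(ge$expr)
  expect_s3_class(ca, "clustered_heatmap")
  # cutting the gene tree at 3 recovers the planted blocks
  cut <- stats::cutree(ca$genes$hclust, k = 3)
  truth <- ge$clusters$cluster[match(names(cut), ge$clusters$gene_id)]
  tab <- table(cut, truth)
  expect_equal(sum(apply(tab, 1, max)), 24)   # pure clusters
  expect_equal(sort(ca$samples$order), sort(sprintf("S%02d", 1:10)))
})
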