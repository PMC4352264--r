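test_that("p_distance matches site-by-site enumeration under both gap policies", {
  aln <- tibble::tibble(id = c("a", "b"), sequence = c("AAAA", "AAAA"))
  expect_equal(p_distance(aln)["a", "b"], 0)

  aln$sequence <- c("AAAA", "AAAT")
  expect_equal(p_distance(aln)["a", "b"], 0.25)

  aln3 <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c("A-CD", "ABCD", "ABCD"))
  expect_equal(p_distance(aln3, "pairwise_deletion")["a", "b"], 0)
  # complete deletion drops the gapped column for every pair
  expect_equal(p_distance(aln3, "complete_deletion")["b", "c"], 0)

  bad <- tibble::tibble(id = c("x", "y"), sequence = c("--AA", "AA--"))
  expect_error(p_distance(bad), "no comparable sites.*x.*y")
})

test_that("neighbor_joining solves the three-taxon case exactly", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("neighbor_joining recovers random additive trees exactly", {
  withr::local_seed(23)
  for (r in 1:10) {
    n <- sample(6:10, 1)
    true <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.05, 1)))
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(est, true), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), rownames(D)] - D)),
              1e-9)
  }
})

test_that("equidistant taxa give zero-length internal branches", {
  n <- 6
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  tr <- neighbor_joining(dm)
  internal <- tr$edge[, 2] > n
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("total branch length is invariant under taxon permutation", {
  withr::local_seed(31)
  aln <- gen_alignment(c(3, 4), n_singletons = 1, seed = 8)$alignment
  dm <- p_distance(aln)
  base <- sum(neighbor_joining(dm)$edge.length)
  for (r in 1:5) {
    perm <- sample(nrow(dm))
    expect_equal(sum(neighbor_joining(dm[perm, perm])$edge.length), base,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap supports behave on uniform signals and are seed-reproducible", {
  # two groups differing at every site: resampling cannot change the signal
  aln <- tibble::tibble(id = sprintf("t%d", 1:6),
                        sequence = c(rep(strrep("A", 40), 3),
                                     rep(strrep("K", 40), 3)))
  bt <- bootstrap_support(aln, replicates = 50, seed = 2)
  expect_true(all(bt$supports$support == 100))

  aln2 <- gen_alignment(c(3, 3), seed = 4)$alignment
  b1 <- bootstrap_support(aln2, replicates = 100, seed = 7)
  b2 <- bootstrap_support(aln2, replicates = 100, seed = 7)
  expect_equal(b1$supports$support, b2$supports$support)
  b3 <- bootstrap_support(aln2, replicates = 100, seed = 8)
  expect_equal(b1$supports$key, b3$supports$key)  # topology is seed-free
  expect_true(all(b1$supports$support >= 0 & b1$supports$support <= 100))
})

test_that("extract_clades applies the strict support threshold", {
  aln <- gen_alignment(c(3, 3), seed = 4)$alignment
  bt <- bootstrap_support(aln, replicates = 100, seed = 7)
  high <- extract_clades(bt, threshold = 50)
  expect_true(all(high$clades$support > 50))
  none <- extract_clades(bt, threshold = 100)
  expect_equal(nrow(none$clades), 0)
  expect_equal(sort(none$singletons), sort(aln$id))
})

test_that("the planted 21-clade family design is recovered from its tree", {
  sizes <- clade_design_sizes()        # 21 groups, 94 members
  expect_equal(sum(sizes), 94L)
  ga <- gen_alignment(sizes, n_singletons = 9, seed = 27)
  bt <- bootstrap_support(ga$alignment, replicates = 100, seed = 127)
  cl <- extract_clades(bt, threshold = 50)
  expect_equal(nrow(cl$clades), 21)
  expect_equal(sum(cl$clades$n_members), 94)
  expect_equal(length(cl$singletons), 9)
  truth <- split(ga$truth$gene_id[!is.na(ga$truth$group)],
                 ga$truth$group[!is.na(ga$truth$group)])
  found <- lapply(cl$clades$members, sort)
  for (g in names(truth)) {
    expect_true(any(vapply(found, identical, logical(1), sort(truth[[g]]))))
  }
})

test_that("trees round-trip through Newick with supports attached", {
  ga <- gen_alignment(c(3, 3), seed = 4)
  bt <- bootstrap_support(ga$alignment, replicates = 20, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, ga$alignment$id)
  expect_equal(sum(back$edge.length), sum(bt$tree$edge.length), tolerance = 1e-6)
})
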