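# Distance phylogenetics: p-distance matrices from aligned protein
# sequences, Saitou-Nei neighbor-joining (authored here; ape is used only
# for Newick interchange and as an independent oracle in the tests),
# column-resampling bootstrap supports, and clade calling at a support
# threshold.

aln_matrix <- function(alignment) {
  stopifnot(all(c("id", "sequence") %in% names(alignment)))
  if (nrow(alignment) < 2) abort("need at least 2 aligned sequences")
  L <- nchar(alignment$sequence)
  if (length(unique(L)) != 1) abort("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(alignment$sequence, ""))
  rownames(m) <- alignment$id
  m
}

#' Pairwise p-distance matrix from an alignment
#'
#' The p-distance between two aligned sequences is the proportion of
#' differing sites among comparable sites: under `pairwise_deletion` a site is
#' comparable for a pair when neither sequence has a gap (`-` or `.`); under
#' `complete_deletion` only sites where no taxon has a gap are used at all.
#'
#' @param alignment Tibble with `id` and (equal-length, aligned) `sequence`.
#' @param gap_policy `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance <- function(alignment,
                       gap_policy = c("pairwise_deletion", "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  p_distance_matrix(aln_matrix(alignment), gap_policy)
}

p_distance_matrix <- function(m, gap_policy = "pairwise_deletion") {
  gap <- m == "-" | m == "."
  if (gap_policy == "complete_deletion") {
    keep <- colSums(gap) == 0
    if (!any(keep)) abort("no gap-free columns under complete deletion")
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(m)
  # indicator algebra: diff counts via per-letter outer products
  ok <- !gap
  comp <- ok %*% t(ok)                       # comparable sites per pair
  same <- matrix(0, n, n)
  for (letter in unique(as.vector(m[ok]))) {
    ind <- (m == letter) & ok
    same <- same + ind %*% t(ind)
  }
  if (any(comp[upper.tri(comp)] == 0)) {
    idx <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)[1, ]
    abort(paste0("no comparable sites for pair ", rownames(m)[idx[1]], " / ",
                 rownames(m)[idx[2]]))
  }
  d <- (comp - same) / comp
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(a,b) = (n-2) d(a,b) - sum_k d(a,k) - sum_k d(b,k)`, with branch lengths
#' from the standard three-point formulas. Ties in `Q` are broken by smallest
#' `(row, column)` index in the current matrix order, so the output is
#' bit-reproducible. On an additive distance matrix the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @param clamp_negative If `TRUE`, negative branch lengths are clamped to
#'   zero (MEGA-style presentation); default `FALSE` keeps the classical
#'   estimates.
#' @return An unrooted tree of class `phylo` (ape-compatible; the "root" is
#'   the trifurcating center node).
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  n <- nrow(dm)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(dm, t(dm))), !is.null(rownames(dm)))
  taxa <- rownames(dm)
  D <- unname(dm)
  # node ids: tips 1..n, internals n+1 ...
  active <- seq_len(n)
  next_id <- n + 1L
  children <- list()  # children[[id - n]] = list of (child, length)
  while (length(active) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest (row, col), col-major scan transposed for row-major order
    best <- which(t(Q) == min(Q), arr.ind = TRUE)
    ij <- c(best[1, 2], best[1, 1])
    a <- min(ij); b <- max(ij)
    la <- D[a, b] / 2 + (r[a] - r[b]) / (2 * (m - 2))
    lb <- D[a, b] - la
    children[[next_id - n]] <- list(c(active[a], la), c(active[b], lb))
    dk <- (D[a, ] + D[b, ] - D[a, b]) / 2
    keep <- setdiff(seq_len(m), c(a, b))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    active <- c(active[keep], next_id)
    D <- D2
    next_id <- next_id + 1L
  }
  # join the final three around the center
  ab <- D[1, 2]; ac <- D[1, 3]; bc <- D[2, 3]
  ls <- c((ab + ac - bc) / 2, (ab + bc - ac) / 2, (ac + bc - ab) / 2)
  children[[next_id - n]] <- list(c(active[1], ls[1]), c(active[2], ls[2]),
                                  c(active[3], ls[3]))
  center <- next_id
  # renumber internals in preorder from the center (ape convention: root n+1)
  n_int <- center - n
  newid <- integer(center)
  newid[seq_len(n)] <- seq_len(n)
  cursor <- n
  edges <- matrix(0L, 0, 2)
  lens <- numeric()
  stack <- center
  order_children <- function(id) children[[id - n]]
  # iterative preorder
  assign_next <- function(old) {
    cursor <<- cursor + 1L
    newid[old] <<- cursor
  }
  assign_next(center)
  walk <- function(old) {
    for (ch in order_children(old)) {
      cid <- as.integer(ch[1]); clen <- ch[2]
      if (cid > n) assign_next(cid)
      edges <<- rbind(edges, c(newid[old], newid[cid]))
      lens <<- c(lens, clen)
      if (cid > n) walk(cid)
    }
  }
  walk(center)
  if (clamp_negative) lens <- pmax(lens, 0)
  tree <- list(edge = edges, edge.length = lens, tip.label = taxa,
               Nnode = n_int)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

# For each internal edge: the tip set below its child node, as sorted labels.
# Canonical bipartition key: the side NOT containing the first taxon label.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  # postorder: edges reversed from cladewise preorder
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ref <- tree$tip.label[1]
  keys <- character(); nodes <- integer(); sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next                    # trivial bipartition
    side <- below[[ch]]
    key_side <- if (ref %in% side) setdiff(tree$tip.label, side) else side
    keys <- c(keys, paste(sort(key_side), collapse = "|"))
    nodes <- c(nodes, ch)
    sides[[length(sides) + 1L]] <- sort(side)
  }
  tibble(node = nodes, key = keys, members = sides,
         n_members = lengths(sides))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then for each
#' replicate resamples alignment columns with replacement, rebuilds the tree
#' and records its bipartitions. The support of a reference internal edge is
#' the percentage of replicates containing its bipartition. The reference
#' topology does not depend on the seed; the supports are reproducible for a
#' fixed seed.
#'
#' @param alignment Tibble with `id`, `sequence` (>= 4 taxa).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for column resampling.
#' @param gap_policy Passed to [p_distance()].
#' @return A list of class `ccch_tree`: `tree` (`phylo`, with `node.label`
#'   holding supports), `supports` tibble (`node`, `support`, `members`),
#'   `replicates`, `seed`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000, seed = 1,
                              gap_policy = "pairwise_deletion") {
  if (nrow(alignment) < 4) abort("bootstrap needs at least 4 taxa")
  ref_tree <- neighbor_joining(p_distance(alignment, gap_policy))
  bip <- tree_bipartitions(ref_tree)
  hits <- setNames(numeric(nrow(bip)), bip$key)
  m <- aln_matrix(alignment)
  L <- ncol(m)
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      dm_r <- p_distance_matrix(m[, cols, drop = FALSE], gap_policy)
      keys_r <- tree_bipartitions(neighbor_joining(dm_r))$key
      found <- bip$key %in% keys_r
      hits[found] <- hits[found] + 1
    }
  })
  support <- 100 * hits / replicates
  n <- length(ref_tree$tip.label)
  node_label <- rep(NA_character_, ref_tree$Nnode)
  node_label[bip$node - n] <- formatC(support, format = "f", digits = 1)
  ref_tree$node.label <- node_label
  structure(list(tree = ref_tree,
                 supports = mutate(bip, support = unname(support)),
                 replicates = replicates, seed = seed),
            class = "ccch_tree")
}

#' @export
print.ccch_tree <- function(x, ...) {
  cat(sprintf("<ccch_tree> %d taxa, %d bootstrap replicates (seed %s)\n",
              length(x$tree$tip.label), x$replicates, format(x$seed)))
  invisible(x)
}

#' Extract supported clades from a bootstrapped tree
#'
#' Every internal edge with support strictly above `threshold` defines a
#' candidate clade -- the smaller side of its bipartition (ties broken to the
#' side not containing the first taxon), the natural unrooted reading of a
#' "supported subtree". Maximal candidates (not nested inside another
#' supported candidate) are reported. Taxa in no supported clade are
#' singletons.
#'
#' @param x A `ccch_tree` from [bootstrap_support()].
#' @param threshold Support threshold, strict `>` (default 50).
#' @return A list of class `clade_set`: `clades` tibble (`clade_id`,
#'   `support`, `n_members`, `members` list-column), `membership` tibble
#'   (`gene_id`, `clade_id` with `NA` for singletons), `singletons` character
#'   vector.
#' @export
extract_clades <- function(x, threshold = 50) {
  stopifnot(inherits(x, "ccch_tree"))
  taxa <- x$tree$tip.label
  sup <- x$supports |>
    filter(.data$support > threshold) |>
    mutate(members = purrr::map(.data$members, function(side) {
      other <- setdiff(taxa, side)
      if (length(other) < length(side)) sort(other)
      else if (length(side) < length(other)) side
      else if (taxa[1] %in% side) sort(other) else side
    }),
    n_members = lengths(.data$members))
  # drop candidates nested inside another supported candidate
  keep <- rep(TRUE, nrow(sup))
  if (nrow(sup) > 1) {
    for (a in seq_len(nrow(sup))) {
      for (b in seq_len(nrow(sup))) {
        if (a != b && keep[a] &&
            all(sup$members[[a]] %in% sup$members[[b]]) &&
            sup$n_members[a] < sup$n_members[b]) {
          keep[a] <- FALSE
          break
        }
      }
    }
  }
  sup <- sup[keep, ]
  sup <- sup |> arrange(dplyr::desc(.data$n_members))
  clades <- tibble(
    clade_id = if (nrow(sup)) paste0("C", seq_len(nrow(sup))) else character(),
    support = sup$support, n_members = sup$n_members, members = sup$members)
  membership <- tibble(gene_id = x$tree$tip.label) |>
    left_join(
      tidyr::unnest(select(clades, "clade_id", "members"),
                    "members") |> rename(gene_id = "members") |>
        distinct(.data$gene_id, .keep_all = TRUE),
      by = "gene_id")
  singletons <- membership$gene_id[is.na(membership$clade_id)]
  structure(list(clades = clades, membership = membership,
                 singletons = singletons, threshold = threshold),
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat(sprintf("<clade_set> %d clades (support > %s) covering %d taxa; %d singletons\n",
              nrow(x$clades), format(x$threshold),
              sum(x$clades$n_members), length(x$singletons)))
  invisible(x)
}

#' Write a tree (with supports, if present) to Newick
#'
#' @param x A `phylo` or `ccch_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  tree <- if (inherits(x, "ccch_tree")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @method tidy ccch_tree
#' @export
tidy.ccch_tree <- function(x, ...) {
  select(x$supports, "node", "support", "n_members", "members")
}

#' @method glance ccch_tree
#' @export
glance.ccch_tree <- function(x, ...) {
  tibble(n_taxa = length(x$tree$tip.label),
         total_branch_length = sum(x$tree$edge.length),
         replicates = x$replicates, seed = x$seed)
}
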