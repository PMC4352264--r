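# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the implementation it checks.

# Brute-force CCCH enumeration: vectorized anchor test over every
# (start, i, j) offset combination (the scanner chains C positions instead).
brute_force_ccch <- function(seq, i_range = 4:17, j_range = 4:6, k = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- list()
  for (i in i_range) {
    for (j in j_range) {
      w <- i + j + k + 4
      if (w > n) next
      s <- seq_len(n - w + 1)
      hit <- ch[s] == "C" & ch[s + i + 1] == "C" & ch[s + i + j + 2] == "C" &
        ch[s + i + j + k + 3] == "H"
      if (any(hit)) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = s[hit], end = s[hit] + w - 1, i = i, j = j, k = k)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          i = integer(), j = integer(), k = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), start, i, j)
}

# Brute-force average-linkage agglomeration: recompute all pairwise cluster
# distances from scratch at each step (the implementation uses stats::hclust).
brute_force_average_linkage <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric()
  cluster_dist <- function(a, b) {
    mean(as.matrix(stats::dist(m))[a, b])
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          d <- cluster_dist(clusters[[a]], clusters[[b]])
          if (d < bestd - 1e-12) { bestd <- d; best <- c(a, b) }
        }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# random sequences over a given alphabet
random_seq <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                          collapse = "")

AA_ALL <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
            "T","V","W","Y")

# the 21-group / 94-member / 9-singleton planted clade design
clade_design_sizes <- function() c(rep(4L, 13), rep(5L, 6), rep(6L, 2))
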