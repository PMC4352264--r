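# Degenerate CCCH zinc-finger motif detection. The family's defining motif is
# C-X(i)-C-X(j)-C-X(k)-H with variable spacers; the scanner finds every
# placement of the four anchor residues with spacers inside the configured
# ranges, either exhaustively or with non-overlapping shortest-first
# semantics.

#' Scanner parameters for the CCCH motif
#'
#' @param i_min,i_max Bounds on the first spacer (C..C), defaults 4 and 17.
#' @param j_min,j_max Bounds on the second spacer (C..C), defaults 4 and 6.
#' @param k Third spacer length (C..H), default 3; the C-X3-4-H variant can be
#'   scanned by calling twice with `k = 3` and `k = 4`.
#' @param overlap_policy `"nonoverlapping_shortest_first"` (default): scan
#'   left to right, at each position admit the match with smallest `i` then
#'   smallest `j`, and resume after the matched H; or `"all_matches"`: report
#'   every `(start, i, j)` combination whose anchors hold.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(i_min = 4L, i_max = 17L, j_min = 4L, j_max = 6L,
                        k = 3L,
                        overlap_policy = c("nonoverlapping_shortest_first",
                                           "all_matches")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(i_min > 0, i_min <= i_max, j_min > 0, j_min <= j_max, k >= 1)
  structure(list(i_min = as.integer(i_min), i_max = as.integer(i_max),
                 j_min = as.integer(j_min), j_max = as.integer(j_max),
                 k = as.integer(k), overlap_policy = overlap_policy),
            class = "scan_params")
}

pattern_label <- function(i, j, k) sprintf("C-X%d-C-X%d-C-X%d-H", i, j, k)

# all (start, i, j) anchor placements in one sequence; start/end 1-based closed
scan_one_all <- function(seq, params) {
  ch <- strsplit(seq, "")[[1]]
  cpos <- which(ch == "C")
  hset <- ch == "H"
  out <- list()
  n <- length(ch)
  for (c1 in cpos) {
    for (i in params$i_min:params$i_max) {
      c2 <- c1 + i + 1L
      if (c2 > n || ch[c2] != "C") next
      for (j in params$j_min:params$j_max) {
        c3 <- c2 + j + 1L
        h <- c3 + params$k + 1L
        if (h > n || ch[c3] != "C" || !hset[h]) next
        out[[length(out) + 1L]] <- c(c1, h, i, j)
      }
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), i = integer(),
                  j = integer(), k = integer(), pattern = character()))
  }
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2], i = m[, 3], j = m[, 4],
         k = params$k, pattern = pattern_label(m[, 3], m[, 4], params$k))
}

#' Scan protein sequences for CCCH motifs
#'
#' @param records Tibble with `id` and `sequence` columns (protein records).
#' @param params A [scan_params()] object.
#' @return A tibble of hits: `protein_id`, `start`, `end` (1-based inclusive
#'   span of the full C..H match, so `end - start + 1 = i + j + k + 4`),
#'   spacer lengths `i`, `j`, `k`, and a `pattern` label like `C-X8-C-X5-C-X3-H`.
#' @examples
#' rec <- tibble::tibble(id = "p1",
#'   sequence = paste0("C", strrep("A", 8), "C", strrep("A", 5), "C", "AAA", "H"))
#' scan_ccch(rec)
#' @export
scan_ccch <- function(records, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    hits <- scan_one_all(seq, params)
    if (params$overlap_policy == "nonoverlapping_shortest_first" && nrow(hits)) {
      hits <- hits |> arrange(.data$start, .data$i, .data$j)
      keep <- integer()
      pos <- 1L
      r <- 1L
      while (r <= nrow(hits)) {
        if (hits$start[r] >= pos) {
          keep <- c(keep, r)
          pos <- hits$end[r] + 1L
        }
        r <- r + 1L
      }
      hits <- hits[keep, ]
    }
    if (nrow(hits)) dplyr::bind_cols(tibble(protein_id = id), hits) else
      tibble(protein_id = character(), start = integer(), end = integer(),
             i = integer(), j = integer(), k = integer(), pattern = character())
  })
}

#' Tally CCCH motifs per pattern and per protein
#'
#' @param hits Hit tibble from [scan_ccch()], all from one scan.
#' @param records Optional record tibble; proteins with zero hits then appear
#'   in the per-protein histogram's accounting of family size.
#' @param family Family label stored in the result.
#' @return A list of class `motif_tally` with tibbles `per_pattern`
#'   (`pattern`, `n`), `per_protein` (`protein_id`, `n_motifs`),
#'   `motifs_per_protein` histogram (`n_motifs`, `n_proteins`), and `totals`
#'   (`n_proteins`, `n_motif_proteins`, `n_motifs`).
#' @export
tally_motifs <- function(hits, records = NULL, family = "CCCH") {
  per_pattern <- hits |> count(.data$pattern, name = "n") |> arrange(.data$pattern)
  per_protein <- hits |> count(.data$protein_id, name = "n_motifs")
  if (!is.null(records)) {
    per_protein <- tibble(protein_id = records$id) |>
      left_join(per_protein, by = "protein_id") |>
      mutate(n_motifs = dplyr::coalesce(.data$n_motifs, 0L))
  }
  hist <- per_protein |>
    filter(.data$n_motifs > 0) |>
    count(.data$n_motifs, name = "n_proteins") |>
    arrange(.data$n_motifs)
  totals <- tibble(
    family = family,
    n_proteins = if (is.null(records)) dplyr::n_distinct(hits$protein_id) else nrow(records),
    n_motif_proteins = dplyr::n_distinct(hits$protein_id),
    n_motifs = nrow(hits)
  )
  structure(list(per_pattern = per_pattern, per_protein = per_protein,
                 motifs_per_protein = hist, totals = totals),
            class = "motif_tally")
}

#' @export
print.motif_tally <- function(x, ...) {
  cat(sprintf("<motif_tally> %s: %d motifs in %d of %d proteins\n",
              x$totals$family, x$totals$n_motifs, x$totals$n_motif_proteins,
              x$totals$n_proteins))
  print(x$per_pattern, n = 10)
  invisible(x)
}

#' Position frequency profile (sequence-logo statistics) of one motif pattern
#'
#' All hits must share one `(i, j, k)` spacer signature so motif instances
#' align without gaps. Per-column information content is
#' `log2(20) - H(column)` with `H` the Shannon entropy in bits over the
#' 20-residue alphabet (no small-sample correction).
#'
#' @param hits Hit tibble (one pattern) from [scan_ccch()].
#' @param records Record tibble the hits were scanned from.
#' @return A tibble with columns `position` (1..motif width), `residue`,
#'   `freq`, and `ic` (the column's information content in bits, repeated
#'   across its residues).
#' @export
position_profile <- function(hits, records) {
  if (nrow(hits) == 0) abort("no hits supplied")
  if (dplyr::n_distinct(hits$pattern) != 1) {
    abort("hits mix patterns; profile requires a single (i, j, k) signature")
  }
  seqs <- setNames(records$sequence, records$id)
  inst <- substring(seqs[hits$protein_id], hits$start, hits$end)
  width <- hits$i[1] + hits$j[1] + hits$k[1] + 4L
  stopifnot(all(nchar(inst) == width))
  mat <- do.call(rbind, strsplit(inst, ""))
  purrr::map_dfr(seq_len(width), function(pos) {
    col <- mat[, pos]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    freq <- as.numeric(cnt) / sum(cnt)
    p <- freq[freq > 0]
    ic <- log2(20) + sum(p * log2(p))
    tibble(position = pos, residue = AA20, freq = freq, ic = ic)
  })
}

# EMBOSS pKa values; any consistent table satisfies the zero-net-charge
# property that defines the reported pI.
PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# average residue (amino acid minus water) masses, Da
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

protein_net_charge <- function(counts, pH) {
  pos <- c(Nterm = 1, counts[c("H", "K", "R")])
  pka_pos <- PKA_EMBOSS[c("Nterm", "H", "K", "R")]
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  pka_neg <- PKA_EMBOSS[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - pka_pos))) - sum(neg / (1 + 10^(pH - pka_neg)) * 10^(pH - pka_neg))
}

#' Molecular weight and isoelectric point of protein records
#'
#' Molecular weight is the sum of average residue masses plus one water mass
#' (an `X` contributes the mean of the 20 residue masses). The isoelectric
#' point is found by bisection on the Henderson-Hasselbalch net charge over
#' the termini and D, E, C, Y, H, K, R side chains (EMBOSS pKa table) to
#' `|charge| < 1e-4`; `X` carries no charge.
#'
#' @param records Tibble with `id` and `sequence`.
#' @return A tibble: `id`, `length`, `mw_kda`, `pi`.
#' @export
protein_stats <- function(records) {
  if (any(!nzchar(records$sequence))) abort("empty sequence")
  purrr::map2_dfr(records$id, records$sequence, function(id, seq) {
    ch <- strsplit(seq, "")[[1]]
    counts <- table(factor(ch, levels = c(AA20, "X")))
    mw <- sum(counts[AA20] * RESIDUE_MASS[AA20]) +
      counts[["X"]] * mean(RESIDUE_MASS) + WATER_MASS
    cnt <- setNames(as.numeric(counts[c("H", "K", "R", "D", "E", "C", "Y")]),
                    c("H", "K", "R", "D", "E", "C", "Y"))
    lo <- 0; hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- protein_net_charge(cnt, mid)
      if (abs(q) < 1e-4 || hi - lo < 1e-12) break
      if (q > 0) lo <- mid else hi <- mid
    }
    tibble(id = id, length = length(ch), mw_kda = mw / 1000, pi = mid)
  })
}
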