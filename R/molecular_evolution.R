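# Duplicate-pair classification and Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor multiple-hit correction, plus selection-mode calling and
# molecular-clock divergence dating. The Ka/Ks estimator is authored here
# (proportional site counting, pathway averaging with stop exclusion); it is
# the NG86/JC method that DnaSP applies by default, so exact numeric parity
# with other programs is method-level, not implementation-level.

GENETIC_CODE_STD <- Biostrings::GENETIC_CODE

parse_chrom <- function(chromosome) {
  if (chromosome == "unknown") return(list(number = NA, sub = NA))
  if (!grepl("^Chr[0-9]+[ab]?$", chromosome)) {
    abort(paste0("malformed chromosome label: ", chromosome))
  }
  list(number = sub("^Chr([0-9]+)[ab]?$", "\\1", chromosome),
       sub = sub("^Chr[0-9]+", "", chromosome))
}

#' Classify a duplicate pair from chromosome labels alone
#'
#' Chromosome labels carry a number and an optional subgenome letter (`a`/`b`)
#' of the allotetraploid. Identical labels give `"same_chromosome"` (tandem
#' candidates -- confirming tandem status needs gene ordinals, see
#' [classify_duplication()]); same number but different subgenome letter gives
#' `"homeologous"`; anything else with both labels known is `"paralogous"`.
#'
#' @param chr_a,chr_b Chromosome labels (vectorized).
#' @return Character vector in
#'   `{"same_chromosome", "homeologous", "paralogous", "unknown"}`.
#' @export
classify_chromosome_pair <- function(chr_a, chr_b) {
  purrr::map2_chr(chr_a, chr_b, function(a, b) {
    pa <- parse_chrom(a); pb <- parse_chrom(b)
    if (is.na(pa$number) || is.na(pb$number)) return("unknown")
    if (a == b) return("same_chromosome")
    if (pa$number == pb$number && pa$sub != pb$sub &&
        all(c(pa$sub, pb$sub) %in% c("a", "b"))) return("homeologous")
    "paralogous"
  })
}

#' Classify the duplication type of a gene pair from its loci
#'
#' Tandem duplicates are paralogs on the same chromosome separated by fewer
#' than five gene loci (`|ordinal difference| - 1 <= max_intervening`,
#' default 4). Pairs on homeologous chromosomes (same number, subgenome `a`
#' vs `b`) arose from the allotetraploidization; remaining pairs with known
#' locations are plain paralogs; a pair involving an unknown chromosome is
#' `"unknown"`.
#'
#' @param loci Locus tibble (see [read_locus_table()]).
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param max_intervening Maximum intervening gene loci for a tandem call
#'   (default 4, i.e. "fewer than five genes in between").
#' @return `pairs` with added columns `chr_a`, `chr_b`, `dup_type`.
#' @export
classify_duplication <- function(loci, pairs, max_intervening = 4) {
  loci <- validate_locus_table(loci)
  idx <- setNames(seq_len(nrow(loci)), loci$gene_id)
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), loci$gene_id)
  if (length(missing)) abort(paste0("gene(s) absent from locus table: ",
                                    paste(missing, collapse = ", ")))
  if (any(pairs$gene_a == pairs$gene_b)) abort("a pair must join two distinct genes")
  la <- loci[idx[pairs$gene_a], ]
  lb <- loci[idx[pairs$gene_b], ]
  base <- classify_chromosome_pair(la$chromosome, lb$chromosome)
  dup_type <- dplyr::case_when(
    base == "same_chromosome" &
      abs(la$ordinal - lb$ordinal) - 1 <= max_intervening ~ "tandem",
    base == "same_chromosome" ~ "paralogous",
    TRUE ~ base
  )
  mutate(pairs, chr_a = la$chromosome, chr_b = lb$chromosome,
         dup_type = dup_type)
}

codon_split <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

is_stop <- function(codon) !is.na(GENETIC_CODE_STD[codon]) & GENETIC_CODE_STD[codon] == "*"

#' Synonymous and nonsynonymous site counts of one codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the number of
#' the three single-nucleotide changes that preserve the encoded amino acid,
#' divided by the number of counted changes; changes creating a stop codon
#' are excluded from both numerator and denominator (`stop_policy =
#' "exclude"`, the standard practice) or counted as nonsynonymous
#' (`"nonsynonymous"`).
#'
#' @param codon A sense codon string, e.g. `"TTT"`.
#' @param stop_policy `"exclude"` or `"nonsynonymous"`.
#' @return Named numeric `c(s = ..., n = ...)` with `s + n = 3`.
#' @export
ng86_sites <- function(codon, stop_policy = c("exclude", "nonsynonymous")) {
  stop_policy <- match.arg(stop_policy)
  aa <- GENETIC_CODE_STD[codon]
  if (is.na(aa)) abort(paste0("not a codon: ", codon))
  if (aa == "*") abort(paste0("stop codon: ", codon))
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; counted <- 0
    for (b in setdiff(bases, ch[pos])) {
      mut <- ch; mut[pos] <- b
      maa <- GENETIC_CODE_STD[paste(mut, collapse = "")]
      if (maa == "*") {
        if (stop_policy == "nonsynonymous") counted <- counted + 1
        next
      }
      counted <- counted + 1
      if (maa == aa) syn <- syn + 1
    }
    if (counted > 0) s <- s + syn / counted
  }
  c(s = s, n = 3 - s)
}

# average fractional (syn, nonsyn) difference counts between two codons,
# over all substitution orderings; pathways through stop codons are dropped
# and the remaining pathways reweighted (or, if all pass through a stop, all
# pathways are used).
codon_path_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd_tot <- length(pos)
  if (nd_tot == 0) return(c(sd = 0, nd = 0))
  perms <- switch(nd_tot, list(1L), list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  a_ch <- strsplit(ca, "")[[1]]; b_ch <- strsplit(cb, "")[[1]]
  path_counts <- list()
  for (perm in perms) {
    cur <- a_ch; sd <- 0; nd <- 0; ok <- TRUE
    for (p in pos[perm]) {
      nxt <- cur; nxt[p] <- b_ch[p]
      aa1 <- GENETIC_CODE_STD[paste(cur, collapse = "")]
      aa2 <- GENETIC_CODE_STD[paste(nxt, collapse = "")]
      if (aa2 == "*" || aa1 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1L]] <-
      c(sd = sd, nd = nd, ok = as.numeric(ok))
  }
  pm <- do.call(rbind, path_counts)
  use <- pm[, "ok"] == 1
  if (!any(use)) use <- rep(TRUE, nrow(pm))  # degenerate: keep all pathways
  c(sd = mean(pm[use, "sd"]), nd = mean(pm[use, "nd"]))
}

jc_correct <- function(p) {
  if (p >= 3 / 4) abort("saturation: JC correction undefined")
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction for one codon pair
#'
#' Site counts `S`, `N` are averaged over the two sequences
#' (`S + N = 3 x` compared codons). Codon pairs differing at one position are
#' classified directly; at two or three positions the fractional synonymous /
#' nonsynonymous difference counts are averaged over all substitution
#' pathways, excluding pathways through stop codons (renormalizing over the
#' rest). Proportions `ps = Sd/S`, `pn = Nd/N` are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - (4/3) p)`. Codons containing gaps, ambiguity codes, or
#' a stop in either sequence are skipped pairwise.
#'
#' @param seq_a,seq_b In-frame aligned coding sequences of equal length
#'   divisible by 3.
#' @param lambda_rate Synonymous substitution rate per site per year used for
#'   dating (default `6.5e-9`, the grass rate).
#' @param stop_policy Passed to [ng86_sites()].
#' @return One-row tibble: `n_codons`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `Ks`, `Ka`, `ratio` (`NA` when `Ks = 0`), `selection`, `T_mya` (`NA`
#'   when `Ks = 0`).
#' @export
kaks <- function(seq_a, seq_b, lambda_rate = 6.5e-9,
                 stop_policy = "exclude") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must have equal length")
  if (nchar(seq_a) %% 3 != 0) abort("length must be divisible by 3")
  ca <- codon_split(seq_a); cb <- codon_split(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !is_stop(ca) & !is_stop(cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) abort("no comparable codons")
  sa <- vapply(ca, function(x) ng86_sites(x, stop_policy)["s"], numeric(1))
  sb <- vapply(cb, function(x) ng86_sites(x, stop_policy)["s"], numeric(1))
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * length(ca) - S
  diffs <- purrr::map2(ca, cb, codon_path_diffs)
  Sd <- sum(vapply(diffs, `[[`, numeric(1), "sd"))
  Nd <- sum(vapply(diffs, `[[`, numeric(1), "nd"))
  ps <- Sd / S; pn <- Nd / N
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  ratio <- if (Ks > 0) Ka / Ks else NA_real_
  tibble(n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
         ps = ps, pn = pn, Ks = Ks, Ka = Ka, ratio = ratio,
         selection = classify_selection(Ka, Ks),
         T_mya = divergence_time(Ks, lambda_rate))
}

#' Selection mode from Ka and Ks
#'
#' `Ka/Ks > 1` indicates diversifying (positive) selection, `< 1` purifying
#' selection, `= 1` neutral evolution. When `Ks = 0` with `Ka > 0` the ratio
#' is undefined but every nonsynonymous change is unmatched by silent change,
#' so the pair is called diversifying; `Ka = Ks = 0` is neutral.
#'
#' @param Ka,Ks Nonsynonymous / synonymous substitution rates (vectorized).
#' @return Character vector in `{"purifying", "diversifying", "neutral"}`.
#' @export
classify_selection <- function(Ka, Ks) {
  purrr::map2_chr(Ka, Ks, function(ka, ks) {
    if (ks == 0) {
      if (ka > 0) "diversifying" else "neutral"
    } else if (ka / ks > 1) "diversifying"
    else if (ka / ks < 1) "purifying"
    else "neutral"
  })
}

#' Molecular-clock divergence time from Ks
#'
#' `T = Ks / (2 * lambda) * 1e-6` million years, with `lambda` the synonymous
#' substitution rate per site per year (`6.5e-9` for grasses). When `Ks = 0`
#' the estimate carries no information and `NA` is returned by default (the
#' raw `0` is available with `na_for_zero = FALSE`).
#'
#' @param Ks Synonymous substitution rate(s) per site.
#' @param lambda_rate Substitution rate per site per year.
#' @param na_for_zero Report `NA` for `Ks = 0` (default `TRUE`).
#' @return Numeric vector of times in Mya (not rounded; round to one decimal
#'   for report parity).
#' @export
divergence_time <- function(Ks, lambda_rate = 6.5e-9, na_for_zero = TRUE) {
  t <- Ks / (2 * lambda_rate) * 1e-6
  if (na_for_zero) t[Ks == 0] <- NA_real_
  t
}

#' Ka/Ks over a table of coding-sequence pairs
#'
#' @param cds Tibble of nucleotide records (`id`, `sequence`).
#' @param pairs Tibble with `gene_a`, `gene_b` naming records in `cds`.
#' @param ... Passed to [kaks()].
#' @return `pairs` with the [kaks()] columns bound on.
#' @export
kaks_pairs <- function(cds, pairs, ...) {
  seqs <- setNames(cds$sequence, cds$id)
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), names(seqs))
  if (length(missing)) abort(paste0("CDS missing for: ",
                                    paste(missing, collapse = ", ")))
  res <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b,
                         function(a, b) kaks(seqs[[a]], seqs[[b]], ...))
  dplyr::bind_cols(pairs, res)
}

#' The published selection table of the switchgrass C3H family
#'
#' A transcription of the 19 duplicated PvC3H pairs with their chromosome
#' locations, printed Ks, Ka, Ka/Ks, selection call, duplication type and
#' divergence time, shipped as a package fixture for parity checks.
#'
#' @return A tibble with columns `pair`, `chr_a`, `chr_b`, `ks`, `ka`,
#'   `ratio`, `selection`, `dup_type`, `t_mya` (`NA` where printed "N/A").
#' @export
pvc3h_selection_table <- function() {
  path <- system.file("extdata", "pvc3h_selection_table.tsv",
                      package = "ccchfam", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    pair = readr::col_character(), chr_a = readr::col_character(),
    chr_b = readr::col_character(), ks = readr::col_double(),
    ka = readr::col_double(), ratio = readr::col_double(),
    selection = readr::col_character(), dup_type = readr::col_character(),
    t_mya = readr::col_double()))
}
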