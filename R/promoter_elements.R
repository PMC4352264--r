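# Strand-aware scanning of promoter sequences against a library of named
# IUPAC consensus cis-elements (PLACE-style semantics: every overlapping
# match on either strand is reported, with sense-strand coordinates).

#' Default cis-element library
#'
#' Documented PLACE-style consensi for the stress-related elements used in
#' C3H promoter analysis: the ABA-responsive element core (ABRE), the
#' dehydration-responsive element (DRE), the barley C-repeat binding factor
#' site (CBFHV) and the low-temperature-responsive element (LTRE). The exact
#' identifiers behind any given published figure are not recoverable, so the
#' library is plain data: override it with any tibble of `name`, `consensus`
#' (IUPAC DNA) or load one from TSV with [read_element_library()]. Note the
#' shared `CCGAC` core: a DRE instance also satisfies CBFHV and contains
#' LTRE, so counts for these elements overlap by construction.
#'
#' @return A tibble with columns `name`, `consensus`.
#' @export
default_element_library <- function() {
  tibble(name = c("ABRE", "DRE", "CBFHV", "LTRE"),
         consensus = c("ACGTG", "RCCGAC", "RYCGAC", "CCGAC"))
}

#' Read a cis-element library from TSV
#'
#' @param path TSV with columns `name`, `consensus`.
#' @return Validated library tibble.
#' @export
read_element_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), consensus = readr::col_character()))
  validate_element_library(lib)
}

validate_element_library <- function(library) {
  library <- as_tibble(library)
  stopifnot(all(c("name", "consensus") %in% names(library)))
  library$consensus <- toupper(library$consensus)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- vapply(strsplit(library$consensus, ""),
                function(ch) length(ch) == 0 || any(!ch %in% iupac), logical(1))
  if (any(bad)) abort(paste0("invalid IUPAC consensus for element(s): ",
                             paste(library$name[bad], collapse = ", ")))
  library
}

#' Scan promoters for cis-element matches on both strands
#'
#' Each consensus is matched against the sense strand and, via its reverse
#' complement, against the antisense strand; antisense hits are reported in
#' sense-strand coordinates. All overlapping matches are reported. Ambiguity
#' codes in the consensus are degenerate, but letters in the promoter are
#' literal, so an `N` in the promoter never matches a non-`N` consensus
#' position (no spurious hits from masked bases).
#'
#' @param promoters Tibble with `id` and `sequence` (DNA; by convention the
#'   -2000..-1 region 5'->3' on the coding strand).
#' @param library Element library tibble (`name`, `consensus`); defaults to
#'   [default_element_library()].
#' @return Tibble of hits: `promoter_id`, `motif`, `strand`
#'   (`"sense"`/`"antisense"`), `start`, `end` (1-based inclusive,
#'   sense-strand), `match` (sense-strand substring).
#' @examples
#' scan_promoter(tibble::tibble(id = "p", sequence = "TTACCGACT"))
#' @export
scan_promoter <- function(promoters, library = default_element_library()) {
  library <- validate_element_library(library)
  empty <- tibble(promoter_id = character(), motif = character(),
                  strand = character(), start = integer(), end = integer(),
                  match = character())
  if (nrow(library) == 0 || nrow(promoters) == 0) return(empty)
  out <- purrr::map2_dfr(promoters$id, toupper(promoters$sequence), function(id, seq) {
    subj <- Biostrings::DNAString(seq)
    purrr::pmap_dfr(library, function(name, consensus) {
      if (nchar(consensus) > nchar(seq)) return(empty)
      hit_tbl <- function(ranges, strand) {
        if (length(ranges) == 0) return(empty)
        tibble(promoter_id = id, motif = name, strand = strand,
               start = Biostrings::start(ranges), end = Biostrings::end(ranges),
               match = substring(seq, Biostrings::start(ranges), Biostrings::end(ranges)))
      }
      sense <- Biostrings::matchPattern(consensus, subj, fixed = "subject")
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
      anti <- Biostrings::matchPattern(rc, subj, fixed = "subject")
      bind_rows(hit_tbl(sense, "sense"), hit_tbl(anti, "antisense"))
    })
  })
  arrange(out, .data$promoter_id, .data$start, .data$motif)
}

#' Per-promoter, per-element hit counts
#'
#' @param hits Hit tibble from [scan_promoter()].
#' @param promoters Optional promoter tibble; promoters without hits then get
#'   explicit zero rows for every library element.
#' @param library Optional library tibble for the zero-fill grid.
#' @return Tibble `promoter_id`, `motif`, `n`, `multiple` (`n >= 2`).
#' @export
element_summary <- function(hits, promoters = NULL, library = NULL) {
  counts <- hits |> count(.data$promoter_id, .data$motif, name = "n")
  if (!is.null(promoters) && !is.null(library)) {
    grid <- tidyr::expand_grid(promoter_id = promoters$id, motif = library$name)
    counts <- grid |>
      left_join(counts, by = c("promoter_id", "motif")) |>
      mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  counts |> mutate(multiple = .data$n >= 2) |>
    arrange(.data$promoter_id, .data$motif)
}

#' Reverse-complement a DNA string
#'
#' @param seq DNA string (IUPAC letters).
#' @return The reverse complement, as character.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
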