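# Readers/writers and record-level validation for every external format the
# pipeline touches: FASTA (protein / CDS / promoter) and the TSV gene-locus
# table. Sequence collections are plain tibbles so they chain with dplyr.

#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are upper-cased and whitespace-stripped. The first whitespace
#' token of each header is the record `id`; the remainder (if any) is kept as
#' `description`. A `gene_group` column is derived from ids of the form
#' `gene.isoform` (text before the last `.`), and is `NA` where no dot is
#' present; it groups alternative-splicing isoforms of one gene for
#' [pick_longest_isoform()].
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`. Controls which letters are legal:
#'   the 20 amino acids plus `X` for proteins, `ACGTN` (and gap `-`) for DNA.
#' @param strict If `TRUE` (default) an illegal character is an error; if
#'   `FALSE` it is replaced by `X` (protein) or `N` (dna) with a warning.
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `gene_group`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MKC", ">b", "HH"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), strict = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(gsub("\\s", "", as.character(set))))
  if (any(duplicated(ids))) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  legal <- if (alphabet == "protein") c(AA20, "X") else c("A", "C", "G", "T", "N", "-")
  sub_char <- if (alphabet == "protein") "X" else "N"
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% legal), logical(1))
  if (any(bad)) {
    if (strict) {
      abort(paste0("illegal ", alphabet, " character(s) in record(s): ",
                   paste(ids[bad], collapse = ", ")))
    }
    warn(paste0("illegal characters replaced by ", sub_char, " in ",
                sum(bad), " record(s)"))
    pat <- paste0("[^", paste(legal, collapse = ""), "]")
    seqs <- gsub(pat, sub_char, seqs)
  }
  gene_group <- ifelse(grepl("\\.", ids), sub("\\.[^.]*$", "", ids), NA_character_)
  tibble(id = ids, description = desc, sequence = seqs, gene_group = gene_group)
}

#' Write a tibble of sequence records to FASTA
#'
#' Deterministic output: records in input order, one sequence line per record,
#' `\n` line endings.
#'
#' @param records Tibble with at least `id` and `sequence`; an optional
#'   non-empty `description` is appended to the header after a space.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc) | !nzchar(desc), "", paste0(" ", desc))
  lines <- as.vector(rbind(paste0(">", records$id, desc), records$sequence))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Keep the longest translated isoform per gene
#'
#' For genes annotated with several alternative-splicing isoforms only the
#' longest translated protein is carried into motif and phylogenetic analysis.
#' Ties are broken by the lexicographically smallest `id` so the choice is
#' deterministic.
#'
#' @param records Tibble of protein records; every row must have a non-missing
#'   `gene_group`.
#' @return A tibble with one row per `gene_group`, in order of first
#'   appearance.
#' @export
pick_longest_isoform <- function(records) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$gene_group))) {
    abort("every record must have a gene_group to pick isoforms")
  }
  records |>
    mutate(.len = nchar(.data$sequence), .ord = seq_len(nrow(records))) |>
    group_by(.data$gene_group) |>
    arrange(dplyr::desc(.data$.len), .data$id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".len", -".ord")
}

chrom_label_ok <- function(chromosome) {
  chromosome == "unknown" | grepl("^Chr[0-9]+[ab]?$", chromosome)
}

#' Read and validate a gene-locus table
#'
#' A TSV with header `gene_id, chromosome, ordinal, start, end, strand`.
#' `chromosome` labels look like `Chr5a` (number plus optional subgenome
#' letter `a`/`b` of the allotetraploid) or `"unknown"`; `ordinal` is the
#' 1-based rank of the gene along its chromosome; `start`/`end` are 1-based
#' inclusive coordinates with `end > start`.
#'
#' @param path Path to the TSV.
#' @return A validated tibble of loci.
#' @export
read_locus_table <- function(path) {
  loci <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chromosome = readr::col_character(),
    ordinal = readr::col_integer(),
    start = readr::col_double(),
    end = readr::col_double(),
    strand = readr::col_character()
  ))
  validate_locus_table(loci)
}

#' @rdname read_locus_table
#' @param loci A data frame shaped like the locus TSV (used when loci are
#'   built in code, e.g. by [gen_locus_table()]).
#' @export
validate_locus_table <- function(loci) {
  loci <- as_tibble(loci)
  need <- c("gene_id", "chromosome", "ordinal", "start", "end", "strand")
  missing <- setdiff(need, names(loci))
  if (length(missing)) abort(paste0("locus table lacks column(s): ",
                                    paste(missing, collapse = ", ")))
  if (any(!chrom_label_ok(loci$chromosome))) {
    abort(paste0("malformed chromosome label(s): ",
                 paste(unique(loci$chromosome[!chrom_label_ok(loci$chromosome)]),
                       collapse = ", ")))
  }
  if (any(loci$end <= loci$start)) {
    abort(paste0("end must exceed start for: ",
                 paste(loci$gene_id[loci$end <= loci$start], collapse = ", ")))
  }
  known <- loci[loci$chromosome != "unknown", ]
  key <- paste(known$chromosome, known$ordinal)
  if (any(duplicated(key))) {
    abort(paste0("duplicate (chromosome, ordinal): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (!all(loci$strand %in% c("+", "-", "unknown"))) {
    abort("strand must be one of '+', '-', 'unknown'")
  }
  loci
}

#' Write a gene-locus table
#'
#' @param loci Locus tibble as returned by [read_locus_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  readr::write_tsv(validate_locus_table(loci), path)
  invisible(path)
}
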