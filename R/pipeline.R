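# End-to-end orchestration of the family analysis: scan -> tally ->
# phylogeny + clades -> duplication + Ka/Ks + dating -> promoter elements ->
# expression atlas -> qPCR, with per-stage TSV outputs and a JSON summary of
# the headline quantities. Stages without inputs are skipped with a notice.

#' Configuration for [run_family_analysis()]
#'
#' Every input may be a file path (read with the package readers) or an
#' in-memory tibble of the same shape; `NULL` inputs skip their stage.
#' Thresholds default to the published analysis: bootstrap 1000, clade
#' support > 50, tandem spacing < 5 intervening loci, grass synonymous rate
#' `6.5e-9`, 2-fold qPCR cut-off, similarity `r >= 0.8`.
#'
#' @param proteome Protein FASTA path or record tibble (required).
#' @param alignment Aligned protein FASTA path or tibble.
#' @param cds CDS FASTA path or tibble (paired with `pairs`).
#' @param pairs Tibble or TSV with `gene_a`, `gene_b`.
#' @param loci Locus TSV path or tibble.
#' @param promoters Promoter FASTA path or tibble.
#' @param element_library Library TSV path or tibble; default library if `NULL`.
#' @param expression Expression TSV path (gene_id + samples) or tibble.
#' @param ct Ct TSV path or tibble.
#' @param qpcr_targets Character vector of qPCR target genes.
#' @param qpcr_references Reference genes, default `c("PvFTSH4", "Actin2")`.
#' @param scan [scan_params()].
#' @param bootstrap_replicates,support_threshold Tree parameters.
#' @param max_intervening Tandem spacing bound.
#' @param lambda_rate Synonymous substitution rate per year.
#' @param fold_cutoff,similarity_threshold Downstream thresholds.
#' @param pick_isoforms Collapse isoforms to the longest per gene first.
#' @param out_dir Output directory (created); `NULL` for no files.
#' @param seed Global seed (bootstrap resampling).
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, alignment = NULL, cds = NULL,
                            pairs = NULL, loci = NULL, promoters = NULL,
                            element_library = NULL, expression = NULL,
                            ct = NULL, qpcr_targets = NULL,
                            qpcr_references = c("PvFTSH4", "Actin2"),
                            scan = scan_params(),
                            bootstrap_replicates = 1000,
                            support_threshold = 50,
                            max_intervening = 4,
                            lambda_rate = 6.5e-9,
                            fold_cutoff = 2, similarity_threshold = 0.8,
                            pick_isoforms = FALSE,
                            out_dir = NULL, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

load_input <- function(x, reader) {
  if (is.null(x)) NULL
  else if (is.character(x) && length(x) == 1) reader(x)
  else as_tibble(x)
}

read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
}

read_ct_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), treatment = readr::col_character(),
    timepoint = readr::col_double(), replicate = readr::col_character(),
    ct = readr::col_double()))
}

read_pairs_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Run the full gene-family analysis
#'
#' Executes every stage whose inputs are present, writes per-stage TSVs (and
#' a Newick tree) under `out_dir` when set, and returns the per-stage results
#' plus a `summary` list of headline quantities (protein and motif counts,
#' clade count, selection-class counts, induced-gene counts). The run is
#' deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `family_analysis` with elements `records`,
#'   `hits`, `tally`, `tree`, `clades`, `duplication`, `kaks`,
#'   `element_hits`, `element_summary`, `atlas`, `pair_similarity`, `qpcr`,
#'   and `summary`.
#' @export
run_family_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notice <- function(...) message("[ccchfam] ", sprintf(...))
  res <- list()
  records <- load_input(config$proteome, function(p) read_fasta(p, "protein"))
  if (is.null(records)) abort("a proteome is required")
  if (config$pick_isoforms) records <- pick_longest_isoform(records)
  res$records <- records

  notice("scan: %d proteins", nrow(records))
  res$hits <- scan_ccch(records, config$scan)
  res$tally <- tally_motifs(res$hits, records)

  alignment <- load_input(config$alignment, function(p) read_fasta(p, "protein"))
  if (!is.null(alignment)) {
    notice("phylogeny: %d taxa, %d bootstrap replicates", nrow(alignment),
           config$bootstrap_replicates)
    res$tree <- bootstrap_support(alignment,
                                  replicates = config$bootstrap_replicates,
                                  seed = config$seed)
    res$clades <- extract_clades(res$tree, config$support_threshold)
  } else notice("phylogeny skipped (no alignment)")

  loci <- load_input(config$loci, read_locus_table)
  pairs <- load_input(config$pairs, read_pairs_tsv)
  if (!is.null(loci) && !is.null(pairs)) {
    notice("duplication typing: %d pairs", nrow(pairs))
    res$duplication <- classify_duplication(loci, pairs, config$max_intervening)
  } else notice("duplication typing skipped")

  cds <- load_input(config$cds, function(p) read_fasta(p, "dna"))
  if (!is.null(cds) && !is.null(pairs)) {
    notice("Ka/Ks: %d pairs", nrow(pairs))
    res$kaks <- kaks_pairs(cds, pairs, lambda_rate = config$lambda_rate)
    if (!is.null(res$duplication)) {
      res$kaks <- left_join(res$kaks,
                            select(res$duplication, "gene_a", "gene_b",
                                   "chr_a", "chr_b", "dup_type"),
                            by = c("gene_a", "gene_b"))
    }
  } else notice("Ka/Ks skipped")

  promoters <- load_input(config$promoters, function(p) read_fasta(p, "dna"))
  if (!is.null(promoters)) {
    library <- load_input(config$element_library, read_element_library) %||%
      default_element_library()
    notice("promoters: %d sequences x %d elements", nrow(promoters), nrow(library))
    res$element_hits <- scan_promoter(promoters, library)
    res$element_summary <- element_summary(res$element_hits, promoters, library)
  } else notice("promoter scan skipped")

  expr <- load_input(config$expression, read_expression_tsv)
  if (!is.null(expr)) {
    notice("atlas: %d genes x %d samples", nrow(expr), ncol(expr) - 1)
    res$atlas <- cluster_atlas(expr)
    sim_pairs <- res$kaks %||% pairs
    if (!is.null(sim_pairs) &&
        all(c(sim_pairs$gene_a, sim_pairs$gene_b) %in% expr$gene_id)) {
      res$pair_similarity <- pair_expression_similarity(
        expr, sim_pairs, threshold = config$similarity_threshold)
    }
  } else notice("atlas skipped")

  ct <- load_input(config$ct, read_ct_tsv)
  if (!is.null(ct) && !is.null(config$qpcr_targets)) {
    notice("qPCR: %d targets", length(config$qpcr_targets))
    res$qpcr <- purrr::map_dfr(config$qpcr_targets, function(tg) {
      ddct_fold(ct, tg, config$qpcr_references, cutoff = config$fold_cutoff)
    })
  } else notice("qPCR skipped")

  res$summary <- list(
    seed = config$seed,
    n_proteins = res$tally$totals$n_proteins,
    n_motifs = res$tally$totals$n_motifs,
    n_single_motif_proteins =
      sum(res$tally$per_protein$n_motifs == 1),
    n_clades = if (!is.null(res$clades)) nrow(res$clades$clades) else NULL,
    n_singletons = if (!is.null(res$clades)) length(res$clades$singletons) else NULL,
    duplication_types = if (!is.null(res$duplication))
      as.list(table(res$duplication$dup_type)) else NULL,
    selection_classes = if (!is.null(res$kaks))
      as.list(table(res$kaks$selection)) else NULL,
    n_induced = if (!is.null(res$qpcr))
      sum(res$qpcr$induced & res$qpcr$timepoint != 0) else NULL
  )
  res$summary <- res$summary[!vapply(res$summary, is.null, logical(1))]

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$out_dir, name)
    readr::write_tsv(res$hits, out("motif_hits.tsv"))
    readr::write_tsv(res$tally$per_pattern, out("motif_patterns.tsv"))
    if (!is.null(res$tree)) {
      write_newick(res$tree, out("tree.nwk"))
      readr::write_tsv(
        mutate(res$clades$clades,
               members = purrr::map_chr(.data$members, paste, collapse = ",")),
        out("clades.tsv"))
    }
    if (!is.null(res$duplication)) readr::write_tsv(res$duplication, out("duplication.tsv"))
    if (!is.null(res$kaks)) readr::write_tsv(res$kaks, out("kaks.tsv"))
    if (!is.null(res$element_hits)) readr::write_tsv(res$element_hits, out("element_hits.tsv"))
    if (!is.null(res$atlas)) readr::write_tsv(res$atlas$values, out("atlas_normalized.tsv"))
    if (!is.null(res$pair_similarity)) readr::write_tsv(res$pair_similarity, out("pair_similarity.tsv"))
    if (!is.null(res$qpcr)) readr::write_tsv(res$qpcr, out("qpcr_folds.tsv"))
    jsonlite::write_json(res$summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  class(res) <- "family_analysis"
  res
}

#' @export
print.family_analysis <- function(x, ...) {
  cat("<family_analysis>\n")
  s <- x$summary
  cat(sprintf("  %d proteins, %d CCCH motifs (%d single-motif proteins)\n",
              s$n_proteins, s$n_motifs, s$n_single_motif_proteins))
  if (!is.null(s$n_clades)) {
    cat(sprintf("  %d clades, %d singletons\n", s$n_clades, s$n_singletons))
  }
  if (!is.null(s$selection_classes)) {
    cat("  selection: ",
        paste(names(s$selection_classes), unlist(s$selection_classes),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
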