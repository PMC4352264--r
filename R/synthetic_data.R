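# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes, each emitting a machine-readable truth table. All
# generators are pure functions of their arguments plus the seed (the RNG
# state is scoped with withr, so callers' RNG streams are untouched).

BACKGROUND18 <- setdiff(AA20, c("C", "H"))

#' Generate a proteome with planted CCCH motifs
#'
#' Builds one protein per entry of `motifs_per_protein`, planting that many
#' CCCH motif instances. The background alphabet excludes C and H by default
#' and planted motifs are separated by at least `min_gap = 18` residues, so
#' no accidental anchor combination can arise: scanner recall and precision
#' on the truth table are exactly 1 in both overlap modes. A
#' realistic-composition background (all 20 residues) is available for
#' stress testing, at the price of possible extra hits.
#'
#' @param motifs_per_protein Integer vector; entry g is the number of motifs
#'   planted in protein g.
#' @param pattern_table Optional tibble `i`, `j`, `count` prescribing how
#'   many planted instances carry each spacer signature (counts must sum to
#'   `sum(motifs_per_protein)`); by default signatures are drawn uniformly
#'   from the scanner's default ranges.
#' @param params [scan_params()] supplying the spacer ranges.
#' @param background `"ch_free"` (default) or `"uniform20"`.
#' @param min_gap Minimum residues between planted motifs (>= 18 guarantees
#'   no cross-motif anchor placements).
#' @param seed RNG seed.
#' @return A list: `records` (protein tibble) and `truth` (tibble
#'   `protein_id`, `start`, `end`, `i`, `j`, `k`, `pattern`).
#' @export
gen_proteome <- function(motifs_per_protein, pattern_table = NULL,
                         params = scan_params(), background = c("ch_free", "uniform20"),
                         min_gap = 18, seed = 1) {
  background <- match.arg(background)
  min_gap <- as.integer(min_gap)
  alpha <- if (background == "ch_free") BACKGROUND18 else AA20
  n_motifs <- sum(motifs_per_protein)
  withr::with_seed(seed, {
    if (is.null(pattern_table)) {
      sig <- tibble(i = sample(params$i_min:params$i_max, n_motifs, replace = TRUE),
                    j = sample(params$j_min:params$j_max, n_motifs, replace = TRUE))
    } else {
      if (sum(pattern_table$count) != n_motifs) {
        abort("pattern_table counts must sum to the total planted motifs")
      }
      sig <- pattern_table[rep(seq_len(nrow(pattern_table)), pattern_table$count),
                           c("i", "j")]
      sig <- sig[sample.int(nrow(sig)), ]
    }
    sig$k <- params$k
    cursor <- 0L
    recs <- vector("list", length(motifs_per_protein))
    truth <- vector("list", length(motifs_per_protein))
    for (g in seq_along(motifs_per_protein)) {
      id <- sprintf("SYN%03d", g)
      n_g <- motifs_per_protein[g]
      parts <- character(); starts <- integer(); pos <- 0L
      lead <- sample(alpha, min_gap, replace = TRUE)
      parts <- paste(lead, collapse = ""); pos <- min_gap
      rows <- list()
      if (n_g > 0) {
        for (mi in seq_len(n_g)) {
          s <- sig[cursor + mi, ]
          spacer <- function(len) paste(sample(alpha, len, replace = TRUE), collapse = "")
          inst <- paste0("C", spacer(s$i), "C", spacer(s$j), "C", spacer(s$k), "H")
          rows[[mi]] <- tibble(protein_id = id, start = pos + 1L,
                               end = pos + nchar(inst), i = s$i, j = s$j,
                               k = s$k, pattern = pattern_label(s$i, s$j, s$k))
          gap <- paste(sample(alpha, min_gap, replace = TRUE), collapse = "")
          parts <- c(parts, inst, gap)
          pos <- pos + nchar(inst) + min_gap
        }
      }
      cursor <- cursor + n_g
      recs[[g]] <- tibble(id = id, description = "", gene_group = NA_character_,
                          sequence = paste(parts, collapse = ""))
      truth[[g]] <- if (length(rows)) bind_rows(rows) else NULL
    }
    list(records = bind_rows(recs) |> select("id", "description", "sequence", "gene_group"),
         truth = bind_rows(truth))
  })
}

#' The paper-scale motif planting design
#'
#' The published family has 103 proteins carrying 202 CCCH motifs, 53 of the
#' proteins with exactly one motif. This helper returns a per-protein motif
#' count vector realizing those totals (53 x 1, 13 x 2, 29 x 3, 5 x 4,
#' 2 x 5, 1 x 6).
#'
#' @return Integer vector of length 103 summing to 202.
#' @export
paper_scale_design <- function() {
  rep(c(1L, 2L, 3L, 4L, 5L, 6L), c(53L, 13L, 29L, 5L, 2L, 1L))
}

sense_codons <- function() {
  cods <- names(GENETIC_CODE_STD)
  cods[GENETIC_CODE_STD != "*"]
}

#' Generate a codon-sequence pair evolved at a chosen Ka/Ks
#'
#' Starts from a random sense-codon ancestor and derives the second sequence
#' by applying single-nucleotide substitutions whose realized synonymous and
#' nonsynonymous counts match the targets implied by `ks_target` and
#' `omega` (the generator controls realized, not expected, counts, which
#' keeps estimator checks tight at small n). At most one substitution is
#' placed per codon, so the estimator's difference counts equal the truth
#' counts exactly; the targets are pre-inflated through the inverse
#' Jukes-Cantor map so the corrected estimates still center on `ks_target`
#' and `omega`. Substitutions creating stop codons are never applied.
#'
#' @param n_codons Number of codons.
#' @param omega Target Ka/Ks ratio (> 0).
#' @param ks_target Target synonymous rate (JC scale). Requests implying raw
#'   difference proportions of 0.7 or more (where the JC correction blows
#'   up) are rejected as saturated.
#' @param seed RNG seed.
#' @return A list: `seq_a`, `seq_b`, and `truth` tibble with the realized
#'   counts (`n_syn`, `n_nonsyn`) and the targets.
#' @export
gen_codon_pair <- function(n_codons = 500, omega = 1, ks_target = 0.2, seed = 1) {
  stopifnot(omega > 0, ks_target >= 0)
  p_of_d <- function(d) 3 / 4 * (1 - exp(-4 * d / 3))
  if (p_of_d(ks_target) >= 0.7 || p_of_d(omega * ks_target) >= 0.7) {
    abort("saturation: requested rates exceed the JC-correctable range")
  }
  withr::with_seed(seed, {
    pool <- sense_codons()
    anc <- sample(pool, n_codons, replace = TRUE)
    sites <- vapply(anc, function(cd) ng86_sites(cd), numeric(2))
    S <- sum(sites["s", ]); N <- sum(sites["n", ])
    n_syn_t <- round(p_of_d(ks_target) * S)
    n_nonsyn_t <- round(p_of_d(omega * ks_target) * N)
    if (n_syn_t + n_nonsyn_t > n_codons) {
      abort("saturation: more substitutions requested than codons available")
    }
    der <- anc
    untouched <- rep(TRUE, n_codons)
    quota <- sample(rep(c("syn", "nonsyn"), c(n_syn_t, n_nonsyn_t)))
    bases <- c("A", "C", "G", "T")
    applied <- c(syn = 0L, nonsyn = 0L)
    for (want in quota) {
      done <- FALSE
      for (try in 1:2000) {
        open <- which(untouched)
        if (!length(open)) break
        ci <- open[sample.int(length(open), 1)]
        cod <- strsplit(der[ci], "")[[1]]
        aa <- GENETIC_CODE_STD[der[ci]]
        cands <- list()
        for (p in 1:3) for (b in setdiff(bases, cod[p])) {
          mut <- cod; mut[p] <- b
          mcod <- paste(mut, collapse = "")
          maa <- GENETIC_CODE_STD[mcod]
          if (maa == "*") next
          cls <- if (maa == aa) "syn" else "nonsyn"
          if (cls == want) cands[[length(cands) + 1L]] <- mcod
        }
        if (length(cands)) {
          der[ci] <- cands[[sample.int(length(cands), 1)]]
          untouched[ci] <- FALSE
          applied[want] <- applied[want] + 1L
          done <- TRUE
          break
        }
      }
      if (!done) abort("could not place a requested substitution (infeasible spec)")
    }
    list(seq_a = paste(anc, collapse = ""), seq_b = paste(der, collapse = ""),
         truth = tibble(n_codons = n_codons, omega = omega,
                        ks_target = ks_target, n_syn = applied[["syn"]],
                        n_nonsyn = applied[["nonsyn"]]))
  })
}

#' Generate a gene-locus table with planted duplicate pairs
#'
#' Lays out genes over homeologous chromosome pairs `Chr1a/1b ..` and plants
#' duplicate pairs of each type: tandem (same chromosome, at most
#' `max_intervening` loci in between), homeologous (same chromosome number,
#' subgenomes a and b), and paralogous (different chromosome numbers).
#'
#' @param n_chromosome_pairs Homeologous chromosome pairs (default 9, the
#'   base number of the tetraploid).
#' @param genes_per_chromosome Background gene loci per chromosome.
#' @param n_tandem,n_homeologous,n_paralogous Planted pair counts.
#' @param tandem_intervening Intervening loci for planted tandem pairs
#'   (default 1).
#' @param seed RNG seed.
#' @return A list: `loci` (locus tibble) and `truth` (tibble `gene_a`,
#'   `gene_b`, `dup_type`).
#' @export
gen_locus_table <- function(n_chromosome_pairs = 9, genes_per_chromosome = 12,
                            n_tandem = 3, n_homeologous = 15, n_paralogous = 1,
                            tandem_intervening = 1, seed = 1) {
  withr::with_seed(seed, {
    chroms <- as.vector(t(outer(seq_len(n_chromosome_pairs), c("a", "b"),
                                function(n, s) paste0("Chr", n, s))))
    loci <- purrr::map_dfr(chroms, function(ch) {
      tibble(gene_id = sprintf("G_%s_%02d", ch, seq_len(genes_per_chromosome)),
             chromosome = ch, ordinal = seq_len(genes_per_chromosome),
             start = seq_len(genes_per_chromosome) * 10000,
             end = seq_len(genes_per_chromosome) * 10000 + 3000,
             strand = sample(c("+", "-"), genes_per_chromosome, replace = TRUE))
    })
    pick <- function(ch, ord) loci$gene_id[loci$chromosome == ch & loci$ordinal == ord]
    used <- character()
    draw_pair <- function(gen) {
      for (try in 1:1000) {
        p <- gen()
        if (!any(p[1:2] %in% used)) {
          used <<- c(used, p[1:2])
          return(tibble(gene_a = p[1], gene_b = p[2], dup_type = p[3]))
        }
      }
      abort("could not plant disjoint duplicate pairs (plan too dense)")
    }
    truth <- list()
    # homeologous: same slot on ChrNa / ChrNb
    for (hpair in seq_len(n_homeologous)) {
      truth[[length(truth) + 1L]] <- draw_pair(function() {
        nchr <- sample.int(n_chromosome_pairs, 1)
        ord <- sample.int(genes_per_chromosome, 1)
        c(pick(paste0("Chr", nchr, "a"), ord),
          pick(paste0("Chr", nchr, "b"), ord), "homeologous")
      })
    }
    # tandem: nearby loci on one chromosome
    for (tpair in seq_len(n_tandem)) {
      truth[[length(truth) + 1L]] <- draw_pair(function() {
        ch <- sample(chroms, 1)
        o1 <- sample.int(genes_per_chromosome - tandem_intervening - 1, 1)
        c(pick(ch, o1), pick(ch, o1 + tandem_intervening + 1), "tandem")
      })
    }
    # paralogous: different chromosome numbers
    for (ppair in seq_len(n_paralogous)) {
      truth[[length(truth) + 1L]] <- draw_pair(function() {
        ns <- sample.int(n_chromosome_pairs, 2)
        c(pick(paste0("Chr", ns[1], "a"), sample.int(genes_per_chromosome, 1)),
          pick(paste0("Chr", ns[2], "b"), sample.int(genes_per_chromosome, 1)),
          "paralogous")
      })
    }
    list(loci = loci, truth = bind_rows(truth))
  })
}

#' Generate promoters with planted cis-elements
#'
#' The background alternates only A and C (drawn randomly) and every planted
#' instance is padded with a fixed `A` on both sides, so for libraries whose
#' consensi require at least one G or T on each strand (true of the default
#' stress-element library) no accidental match can span background or
#' junctions: planted counts are recovered exactly -- provided the scanned
#' library's elements do not match inside one another's instances (see
#' [default_element_library()] on the shared CCGAC core).
#'
#' @param plant Tibble `promoter_id`, `motif`, `count`.
#' @param library Element library supplying the consensi to instantiate.
#' @param length Promoter length (default 2000, the -2 kb window).
#' @param seed RNG seed.
#' @return A list: `promoters` (tibble `id`, `sequence`) and `truth` (the
#'   planting table with planted positions unnested in `positions`).
#' @export
gen_promoters <- function(plant, library = default_element_library(),
                          length = 2000, seed = 1) {
  library <- validate_element_library(library)
  iupac_pick <- function(consensus) {
    paste(vapply(strsplit(consensus, "")[[1]], function(code) {
      opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
      opts[sample.int(length(opts), 1)]
    }, character(1)), collapse = "")
  }
  withr::with_seed(seed, {
    cons <- setNames(library$consensus, library$name)
    ids <- unique(plant$promoter_id)
    out_p <- vector("list", length(ids)); out_t <- vector("list", length(ids))
    for (pi in seq_along(ids)) {
      rows_p <- plant[plant$promoter_id == ids[pi], ]
      motif_of <- rep(rows_p$motif, rows_p$count)
      insts <- vapply(motif_of, function(mn) iupac_pick(cons[[mn]]), character(1))
      ord <- sample.int(length(insts))          # shuffle placement order
      motif_of <- motif_of[ord]; insts <- insts[ord]
      padded <- paste0("A", insts, "A")
      need <- sum(nchar(padded))
      if (need + length(padded) >= length) abort("promoter too short for planting")
      bg_total <- length - need
      # split background into length(padded)+1 chunks
      cuts <- sort(sample.int(bg_total - 1, length(padded)))
      sizes <- diff(c(0, cuts, bg_total))
      bg <- function(nn) paste(sample(c("A", "C"), nn, replace = TRUE), collapse = "")
      pieces <- character(); pos <- 0L
      starts <- integer(length(padded))
      for (s in seq_along(padded)) {
        chunk <- bg(sizes[s])
        pieces <- c(pieces, chunk, padded[s])
        starts[s] <- pos + sizes[s] + 2L      # skip the leading pad A
        pos <- pos + sizes[s] + nchar(padded[s])
      }
      pieces <- c(pieces, bg(sizes[length(sizes)]))
      out_p[[pi]] <- tibble(id = ids[pi], sequence = paste(pieces, collapse = ""))
      out_t[[pi]] <- tibble(promoter_id = ids[pi], motif = motif_of,
                            start = starts, instance = insts)
    }
    list(promoters = bind_rows(out_p), truth = plant,
         positions = bind_rows(out_t))
  })
}

#' Generate an expression atlas with cluster structure and planted pair
#' correlations
#'
#' Background genes form `n_clusters` blocks sharing a profile; for each row
#' of `pairs_plan` two extra genes are emitted whose centered log2 profiles
#' have the requested population correlation.
#'
#' @param n_background Background genes (split over `n_clusters`).
#' @param n_clusters Number of background co-expression blocks.
#' @param n_samples Samples/organs (default 21, the atlas design).
#' @param pairs_plan Tibble `gene_a`, `gene_b`, `r` (target correlation),
#'   optionally `selection`.
#' @param noise_sd Within-block noise on the log2 scale.
#' @param seed RNG seed.
#' @return A list: `expr` (tibble `gene_id` + samples), `truth` (pairs plan),
#'   `clusters` (tibble `gene_id`, `cluster`).
#' @export
gen_expression <- function(n_background = 40, n_clusters = 4, n_samples = 21,
                           pairs_plan = NULL, noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    clus <- rep(seq_len(n_clusters), length.out = n_background)
    centers <- matrix(rnorm(n_clusters * n_samples, sd = 2), n_clusters)
    rows <- list(); cluster_map <- list()
    for (g in seq_len(n_background)) {
      prof <- centers[clus[g], ] + rnorm(n_samples, sd = noise_sd)
      rows[[length(rows) + 1L]] <- tibble(gene_id = sprintf("BG%03d", g),
                                          !!!setNames(as.list(2^(prof + 8)), samples))
      cluster_map[[g]] <- tibble(gene_id = sprintf("BG%03d", g), cluster = clus[g])
    }
    if (!is.null(pairs_plan)) {
      for (r in seq_len(nrow(pairs_plan))) {
        z1 <- rnorm(n_samples, sd = 2)
        rho <- pairs_plan$r[r]
        z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n_samples, sd = 2)
        rows[[length(rows) + 1L]] <- tibble(gene_id = pairs_plan$gene_a[r],
                                            !!!setNames(as.list(2^(z1 + 8)), samples))
        rows[[length(rows) + 1L]] <- tibble(gene_id = pairs_plan$gene_b[r],
                                            !!!setNames(as.list(2^(z2 + 8)), samples))
      }
    }
    list(expr = bind_rows(rows), truth = pairs_plan,
         clusters = bind_rows(cluster_map))
  })
}

#' Generate a qPCR Ct table realizing chosen fold changes
#'
#' Reference genes get constant baseline Ct; the target's control Ct is
#' `ct_target_base`, and treated Ct is shifted by `-log2(fold)`; Gaussian
#' noise `sd_ct` is added to every measurement.
#'
#' @param plan Tibble `gene`, `treatment`, `timepoint`, `fold` (the control
#'   timepoint 0 rows are added automatically with fold 1).
#' @param references Reference gene names (default `c("PvFTSH4", "Actin2")`).
#' @param n_replicates Biological replicates (default 3).
#' @param sd_ct Ct noise standard deviation (default 0.05 cycles).
#' @param ct_target_base,ct_ref_base Baseline Ct values.
#' @param seed RNG seed.
#' @return A list: `ct` (long Ct tibble) and `truth` (the plan, controls
#'   included).
#' @export
gen_qpcr <- function(plan, references = c("PvFTSH4", "Actin2"),
                     n_replicates = 3, sd_ct = 0.05,
                     ct_target_base = 25, ct_ref_base = 20, seed = 1) {
  withr::with_seed(seed, {
    full <- plan |>
      bind_rows(plan |> distinct(.data$gene, .data$treatment) |>
                  mutate(timepoint = 0, fold = 1)) |>
      distinct(.data$gene, .data$treatment, .data$timepoint, .keep_all = TRUE) |>
      arrange(.data$gene, .data$treatment, .data$timepoint)
    rows <- purrr::pmap_dfr(full, function(gene, treatment, timepoint, fold) {
      reps <- seq_len(n_replicates)
      tgt <- tibble(gene = gene, treatment = treatment, timepoint = timepoint,
                    replicate = reps,
                    ct = ct_target_base - log2(fold) + rnorm(n_replicates, sd = sd_ct))
      refs <- purrr::map_dfr(references, function(rg) {
        tibble(gene = rg, treatment = treatment, timepoint = timepoint,
               replicate = reps,
               ct = ct_ref_base + rnorm(n_replicates, sd = sd_ct))
      })
      bind_rows(tgt, refs)
    })
    # reference rows are emitted per target; keep one set per condition
    ct <- rows |>
      distinct(.data$gene, .data$treatment, .data$timepoint, .data$replicate,
               .keep_all = TRUE)
    list(ct = ct, truth = full)
  })
}

#' Generate a grouped protein alignment with planted high-support clades
#'
#' Members of each planted group share a private block of columns that
#' differ from the family consensus, so the group's bipartition is supported
#' by every resample of that block. Deep (between-group) relationships are
#' deliberately made unstable: for every pair of units, `conflict_cols`
#' balanced "affinity" columns are added in which just that pair shares a
#' deviant letter, so every possible deep join has equal, mutually
#' contradictory signal and no between-group edge is bootstrap-stable.
#' Singletons get their own private blocks and no partners.
#'
#' @param group_sizes Integer vector of planted group sizes (each >= 2).
#' @param n_singletons Extra unplaced taxa.
#' @param block Columns per private group block (default 25).
#' @param member_private Private sites per member (default 2).
#' @param conflict_cols Pair-affinity columns per unit pair (default 2).
#' @param seed RNG seed.
#' @return A list: `alignment` (tibble `id`, `sequence`) and `truth`
#'   (tibble `gene_id`, `group`; `NA` group for singletons).
#' @export
gen_alignment <- function(group_sizes, n_singletons = 0, block = 25,
                          member_private = 2, conflict_cols = 2, seed = 1) {
  stopifnot(all(group_sizes >= 2))
  n_units <- length(group_sizes) + n_singletons
  pairs_u <- if (n_units >= 2) utils::combn(n_units, 2) else matrix(0, 2, 0)
  L <- n_units * block + ncol(pairs_u) * conflict_cols
  withr::with_seed(seed, {
    consensus <- sample(AA20, L, replace = TRUE)
    alt <- vapply(consensus, function(a) sample(setdiff(AA20, a), 1), character(1))
    unit_of <- rep(seq_len(n_units),
                   c(group_sizes, rep(1L, n_singletons)))
    n_taxa <- length(unit_of)
    mat <- matrix(rep(consensus, each = n_taxa), n_taxa, L)
    for (u in seq_len(n_units)) {
      cols <- ((u - 1) * block + 1):(u * block)
      mat[unit_of == u, cols] <- rep(alt[cols], each = sum(unit_of == u))
    }
    if (conflict_cols > 0 && ncol(pairs_u) > 0) {
      base <- n_units * block
      for (pp in seq_len(ncol(pairs_u))) {
        cols <- base + ((pp - 1) * conflict_cols + 1):(pp * conflict_cols)
        rows <- unit_of %in% pairs_u[, pp]
        mat[rows, cols] <- rep(alt[cols], each = sum(rows))
      }
    }
    for (tx in seq_len(n_taxa)) {
      own <- ((unit_of[tx] - 1) * block + 1):(unit_of[tx] * block)
      priv <- sample(setdiff(seq_len(L), own), member_private)
      for (ppos in priv) {
        mat[tx, ppos] <- sample(setdiff(AA20, mat[tx, ppos]), 1)
      }
    }
    ids <- sprintf("T%03d", seq_len(n_taxa))
    groups <- ifelse(unit_of <= length(group_sizes),
                     sprintf("G%02d", unit_of), NA_character_)
    list(alignment = tibble(id = ids,
                            sequence = apply(mat, 1, paste, collapse = "")),
         truth = tibble(gene_id = ids, group = groups))
  })
}
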