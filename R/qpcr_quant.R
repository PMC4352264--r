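# Relative qRT-PCR quantification by the delta-delta-Ct method: target Ct
# normalized against the mean Ct of the reference genes, fold change vs the
# 0 h control within each treatment, replicate-level statistics.

check_ct <- function(ct) {
  ct <- as_tibble(ct)
  need <- c("gene", "treatment", "timepoint", "replicate", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing)) abort(paste0("Ct table lacks column(s): ",
                                    paste(missing, collapse = ", ")))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) abort("Ct values must be finite and > 0")
  ct
}

# per (treatment, timepoint, replicate): dCt = Ct_target - mean(Ct_references)
delta_ct <- function(ct, target, references) {
  ct <- check_ct(ct)
  tgt <- filter(ct, .data$gene == target)
  if (nrow(tgt) == 0) abort(paste0("target not measured: ", target))
  ref <- ct |>
    filter(.data$gene %in% references) |>
    group_by(.data$treatment, .data$timepoint, .data$replicate) |>
    summarise(ref_ct = mean(.data$ct), n_refs = n(), .groups = "drop")
  if (any(ref$n_refs < length(references))) abort("missing reference measurement in a replicate")
  joined <- left_join(tgt, ref, by = c("treatment", "timepoint", "replicate"))
  if (any(is.na(joined$ref_ct))) abort("missing reference measurement in a replicate")
  mutate(joined, dct = .data$ct - .data$ref_ct)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each (treatment, timepoint, replicate) the target's Ct is normalized
#' against the arithmetic mean Ct of the reference genes (the geometric mean
#' of their expression), giving `dCt`. `ddCt` is the mean treated `dCt`
#' minus the mean control (`timepoint == control_timepoint`, within the same
#' treatment) `dCt`, and fold change is `efficiency^(-ddCt)`. Replicate-level
#' folds are tested against the control replicates with a two-sided Welch t
#' test on the `dCt` scale (equivalently, on log2 folds).
#'
#' @param ct Long Ct tibble: `gene`, `treatment`, `timepoint`, `replicate`,
#'   `ct`. Reference genes appear as ordinary rows.
#' @param target Target gene id.
#' @param references Character vector of reference gene ids (e.g.
#'   `c("PvFTSH4", "Actin2")`).
#' @param control_timepoint Timepoint of the control (default 0).
#' @param cutoff Induction cut-off on fold change (default 2: induced when
#'   fold >= 2 or <= 0.5).
#' @param efficiency Amplification efficiency (default 2, i.e. perfect
#'   doubling per cycle).
#' @param alpha Significance level for the Welch test (default 0.05).
#' @return Tibble per (treatment, timepoint): `gene`, `treatment`,
#'   `timepoint`, `fold`, `induced`, `p`, `significant`, `n_replicates`.
#' @export
ddct_fold <- function(ct, target, references, control_timepoint = 0,
                      cutoff = 2, efficiency = 2, alpha = 0.05) {
  d <- delta_ct(ct, target, references)
  ctrl <- filter(d, .data$timepoint == control_timepoint)
  if (nrow(ctrl) == 0) abort("no control (timepoint 0) measurements for target")
  ctrl_means <- ctrl |> group_by(.data$treatment) |>
    summarise(ctrl_dct = mean(.data$dct), .groups = "drop")
  ctrl_by_tr <- split(ctrl$dct, ctrl$treatment)
  d |>
    left_join(ctrl_means, by = "treatment") |>
    group_by(.data$treatment, .data$timepoint) |>
    summarise(
      gene = target,
      fold = efficiency^(-(mean(.data$dct) - .data$ctrl_dct[1])),
      p = {
        cd <- ctrl_by_tr[[as.character(.data$treatment[1])]]
        if (.data$timepoint[1] == control_timepoint) NA_real_
        else qpcr_welch_p(.data$dct, cd)
      },
      n_replicates = n(),
      .groups = "drop") |>
    mutate(induced = .data$fold >= cutoff | .data$fold <= 1 / cutoff,
           significant = !is.na(.data$p) & .data$p < alpha) |>
    select("gene", "treatment", "timepoint", "fold", "induced", "p",
           "significant", "n_replicates") |>
    arrange(.data$treatment, .data$timepoint)
}

qpcr_welch_p <- function(treated_dct, control_dct) {
  if (length(treated_dct) < 2 || length(control_dct) < 2) {
    warn("fewer than 2 replicates; significance is NA")
    return(NA_real_)
  }
  if (stats::sd(treated_dct) == 0 && stats::sd(control_dct) == 0) {
    return(if (mean(treated_dct) == mean(control_dct)) 1 else 0)
  }
  t.test(treated_dct, control_dct)$p.value
}

#' Significance of replicate fold changes
#'
#' Two-sided test on log2 fold changes of treated vs control replicates.
#' `method = "welch_t"` is Welch's t test; `"tukey_hsd"` is available through
#' [qpcr_tukey()] when more than two timepoints are compared jointly.
#'
#' @param treated_folds,control_folds Replicate-level fold changes.
#' @param method Only `"welch_t"` here.
#' @param alpha Significance level.
#' @return A one-row tibble: `p`, `significant`.
#' @export
qpcr_significance <- function(treated_folds, control_folds,
                              method = "welch_t", alpha = 0.05) {
  stopifnot(method == "welch_t")
  p <- qpcr_welch_p(log2(treated_folds), log2(control_folds))
  tibble(p = p, significant = !is.na(p) & p < alpha)
}

#' Tukey HSD comparison of timepoints within a treatment
#'
#' Joint one-way comparison of all timepoints of one treatment on the `dCt`
#' scale (Tukey's honestly-significant-difference procedure), returning the
#' pairwise comparisons against the control timepoint.
#'
#' @inheritParams ddct_fold
#' @param treatment Treatment to analyze.
#' @return Tibble: `comparison`, `diff_dct`, `p_adj`, `significant`.
#' @export
qpcr_tukey <- function(ct, target, references, treatment,
                       control_timepoint = 0, alpha = 0.05) {
  d <- delta_ct(ct, target, references) |>
    filter(.data$treatment == !!treatment)
  if (dplyr::n_distinct(d$timepoint) < 3) {
    abort("Tukey HSD needs more than 2 timepoints; use the Welch test")
  }
  fit <- aov(dct ~ factor(timepoint), data = d)
  tk <- TukeyHSD(fit)[["factor(timepoint)"]]
  res <- tibble(comparison = rownames(tk), diff_dct = tk[, "diff"],
                p_adj = tk[, "p adj"]) |>
    mutate(significant = .data$p_adj < alpha)
  filter(res, grepl(paste0("(^|-)", control_timepoint, "$"), .data$comparison))
}
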