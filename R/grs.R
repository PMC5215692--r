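#' Build genetic-risk-score weights from an association table
#'
#' Turns per-marker odds ratios into a "positive score" weight set:
#' each weight is `ln(OR)`, and any marker with `OR < 1` is flipped —
#' its orientation swaps to the other allele and the OR is inverted —
#' so that every weight is non-negative and every marker contributes
#' risk in the same direction.  (The alternative reading, keeping only
#' `OR > 1` markers unflipped, is available with
#' `drop_protective = TRUE`.)  In `allele_count` mode all weights are 1
#' with the same orientation rule, so the score is a plain count of
#' risk-oriented alleles.
#'
#' @param assoc_table Association results (or a printed-table fixture)
#'   with `marker_id`, `comparison`, `or_value` columns.
#' @param marker_ids Markers to include; default: every nominally
#'   significant, testable marker of the source comparison.
#' @param mode `"weighted"` or `"allele_count"`.
#' @param comparison Source comparison for the odds ratios.
#' @param drop_protective Drop OR < 1 markers instead of flipping.
#' @return An object of class `grs_model`: data frame `entries`
#'   (`marker_id`, `orientation`, `weight`) plus `mode` and `source`.
#' @export
build_weights <- function(assoc_table, marker_ids = NULL,
                          mode = c("weighted", "allele_count"),
                          comparison = "CD_vs_ctrl",
                          drop_protective = FALSE) {
  mode <- match.arg(mode)
  df <- assoc_table[assoc_table$comparison == comparison, , drop = FALSE]
  if ("model" %in% names(df)) {
    df <- df[df$model == "allelic" | !df$marker_id %in%
               df$marker_id[df$model == "allelic"], , drop = FALSE]
  }
  if (is.null(marker_ids)) {
    sig <- !is.na(df$p_value) & df$p_value < 0.05 & !is.na(df$or_value)
    if ("composite_flag" %in% names(df)) sig <- sig & !df$composite_flag
    marker_ids <- df$marker_id[sig]
  }
  idx <- match(marker_ids, df$marker_id)
  if (anyNA(idx)) {
    stop("no ", comparison, " odds ratio for marker(s): ",
         paste(marker_ids[is.na(idx)], collapse = ", "))
  }
  or <- df$or_value[idx]
  bad <- is.na(or) | or <= 0
  if (any(bad)) {
    warning("excluding untestable marker(s): ",
            paste(marker_ids[bad], collapse = ", "))
    marker_ids <- marker_ids[!bad]
    or <- or[!bad]
  }
  flip <- or < 1
  if (drop_protective) {
    marker_ids <- marker_ids[!flip]
    or <- or[!flip]
    flip <- flip[!flip]
  }
  or_oriented <- ifelse(flip, 1 / or, or)
  entries <- data.frame(
    marker_id = marker_ids,
    orientation = ifelse(flip, "flipped", "as-panel"),
    weight = if (mode == "weighted") log(or_oriented) else
      rep(1, length(or_oriented)),
    stringsAsFactors = FALSE)
  structure(list(entries = entries, mode = mode, source = comparison),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat("GRS model (", x$mode, " mode, ORs from ", x$source, "): ",
      nrow(x$entries), " markers\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Score subjects with a genetic risk score
#'
#' Per-subject score `sum(oriented dosage * weight)` over the model's
#' markers, where a flipped marker counts copies of the panel's *other*
#' allele (`2 - dosage`).  A missing dosage contributes the marker's
#' mean oriented dosage over the genotyped subjects (mean imputation,
#' reported via a message); subjects missing every marker get `NA`.
#'
#' @param cohort A `cd_cohort`.
#' @param model A `grs_model`.
#' @return Numeric vector of scores, one per subject.
#' @export
score_subjects <- function(cohort, model) {
  stopifnot(inherits(model, "grs_model"))
  entries <- model$entries
  absent <- setdiff(entries$marker_id, cohort$panel$snp_id)
  if (length(absent)) {
    stop("model marker(s) not in cohort panel: ",
         paste(absent, collapse = ", "))
  }
  d <- cohort$dosage[, entries$marker_id, drop = FALSE]
  flip <- entries$orientation == "flipped"
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  n_imputed <- sum(is.na(d) & !apply(d, 1L, function(z) all(is.na(z))))
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
    if (n_imputed > 0) {
      message("mean-imputed ", n_imputed, " missing oriented dosages")
    }
  }
  score <- as.numeric(d %*% entries$weight)
  all_missing <- apply(cohort$dosage[, entries$marker_id, drop = FALSE],
                       1L, function(z) all(is.na(z)))
  score[all_missing] <- NA_real_
  stats::setNames(score, cohort$subjects$subject_id)
}

#' ROC curve and AUC for case versus control scores
#'
#' Sweeps thresholds over the distinct observed scores (classifying
#' `score >= threshold` as case) and reports sensitivity and
#' specificity at each, the area under the curve by the Mann-Whitney
#' identity (ties counted one-half), and a normal-approximation p-value
#' (tie-corrected) for AUC = 0.5.  The trapezoidal area of the swept
#' curve is computed alongside and must agree with the Mann-Whitney
#' area to numerical precision; both are returned.  For tiny samples an
#' exact permutation p-value is available.
#'
#' @param case_scores,control_scores Numeric score vectors (NAs
#'   dropped); at least one finite score per arm.
#' @param exact_p Use exact permutation p (only for
#'   `n_case + n_control <= 30`).
#' @param n_perm Permutation count for the exact option.
#' @return An object of class `roc_curve`: data frame `sweep`
#'   (`threshold`, `sensitivity`, `specificity`), `auc`, `auc_trapezoid`,
#'   `auc_p_value`, and sample sizes.
#' @export
roc_auc <- function(case_scores, control_scores, exact_p = FALSE,
                    n_perm = 20000L) {
  x <- case_scores[!is.na(case_scores)]
  y <- control_scores[!is.na(control_scores)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("each arm needs at least one non-missing score")
  }
  n1 <- length(x)
  n0 <- length(y)
  # Mann-Whitney AUC with ties counted one-half, via midranks
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  thresholds <- sort(unique(pooled), decreasing = TRUE)
  sens <- vapply(thresholds, function(t) mean(x >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(y < t), numeric(1))
  # trapezoid over the full sweep incl. the (0,0) and (1,1) endpoints
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (abs(auc_trap - auc) > 1e-8) {
    stop("internal error: trapezoidal and Mann-Whitney AUC disagree")
  }
  if (exact_p && (n1 + n0) <= 30L) {
    stat_obs <- abs(auc - 0.5)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pooled)
      rkp <- rank(perm)
      Up <- sum(rkp[seq_len(n1)]) - n1 * (n1 + 1) / 2
      if (abs(Up / (n1 * n0) - 0.5) >= stat_obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  } else {
    # normal approximation to U with tie correction
    nt <- n1 + n0
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n0 / 12 * ((nt + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n0 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(
    sweep = data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = spec),
    auc = auc, auc_trapezoid = auc_trap, auc_p_value = p,
    n_case = n1, n_control = n0,
    case_scores = x, control_scores = y),
    class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls; AUC = %.4f (p = %.3g)\n",
              x$n_case, x$n_control, x$auc, x$auc_p_value))
  invisible(x)
}

#' Choose an operating cutoff on a ROC curve
#'
#' Youden method: the cutoff maximizing `sensitivity + specificity - 1`.
#' Candidate cutoffs are the midpoints between adjacent distinct
#' observed scores (plus half-unit margins beyond the extremes), so the
#' reported cutoff falls between score levels — the "5.5 alleles" style
#' of an allele-count score.  Exact ties in the Youden index resolve to
#' the more specific cutoff, then (should specificity also tie) to the
#' lowest qualifying cutoff.
#'
#' @param roc A `roc_curve`.
#' @param method Only `"youden"` is implemented.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(roc, method = "youden") {
  stopifnot(inherits(roc, "roc_curve"))
  method <- match.arg(method)
  scores <- sort(unique(c(roc$case_scores, roc$control_scores)))
  if (length(scores) < 2L) {
    stop("degenerate score distribution: a single distinct value")
  }
  gap <- min(diff(scores)) / 2
  cand <- c(scores[1L] - gap,
            (utils::head(scores, -1) + utils::tail(scores, -1)) / 2,
            scores[length(scores)] + gap)
  sens <- vapply(cand, function(t) mean(roc$case_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(roc$control_scores < t), numeric(1))
  j <- sens + spec - 1
  # ties in the Youden index resolve toward specificity, then to the
  # lowest qualifying cutoff (determinism guard)
  tied <- which(j >= max(j) - 1e-12)
  best <- tied[order(-spec[tied], cand[tied])][1L]
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}
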