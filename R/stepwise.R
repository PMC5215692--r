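#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least
#' squares, via `glm.fit`) of a binary outcome on a design of marker
#' codings — dosage `{0,1,2}` or carrier `{0,1}` columns both work.
#' Complete separation is detected (fitted probabilities numerically 0
#' or 1) and flagged rather than silently reported; rank-deficient
#' designs are rejected with the offending columns named.
#'
#' @param design Numeric matrix or data frame, subjects x terms; an
#'   intercept is added automatically.
#' @param outcome Binary vector (0/1 or logical), one per subject.
#' @return An object of class `logistic_fit`: coefficients, standard
#'   errors, per-term OR with 95% Wald CI, log-likelihood, `n_used`,
#'   `converged` and `separation` flags.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)),
            nrow(design) == length(outcome) || ncol(design) == 0L)
  if (ncol(design) > 0L) {
    ok <- stats::complete.cases(design) & !is.na(outcome)
    design <- design[ok, , drop = FALSE]
    outcome <- outcome[ok]
    constant <- apply(design, 2L, function(x) length(unique(x)) == 1L)
    if (any(constant)) {
      stop("constant non-intercept column(s): ",
           paste(colnames(design)[constant], collapse = ", "))
    }
  } else {
    outcome <- outcome[!is.na(outcome)]
  }
  n <- length(outcome)
  if (n <= ncol(design) + 1L) {
    stop("need more subjects (", n, ") than model terms (",
         ncol(design) + 1L, ")")
  }
  X <- cbind(`(Intercept)` = 1, design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, outcome, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 50L)))
  mu <- fit$fitted.values
  eps <- 1e-8
  separation <- any(mu < eps | mu > 1 - eps)
  loglik <- sum(outcome * log(pmax(mu, 1e-300)) +
                (1 - outcome) * log(pmax(1 - mu, 1e-300)))
  w <- mu * (1 - mu)
  xtwx <- crossprod(X, X * w)
  se <- tryCatch(sqrt(diag(solve(xtwx))),
                 error = function(e) rep(NA_real_, ncol(X)))
  coef <- fit$coefficients
  structure(list(
    coefficients = coef,
    se = stats::setNames(se, names(coef)),
    or = exp(coef),
    or_ci_low = exp(coef - 1.96 * se),
    or_ci_high = exp(coef + 1.96 * se),
    loglik = loglik,
    n_used = n,
    terms = colnames(design),
    converged = fit$converged,
    separation = separation,
    design = design, outcome = outcome),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit on", x$n_used, "subjects;",
      "logLik =", format(x$loglik, digits = 6), "\n")
  if (x$separation) cat("  ! complete or quasi-complete separation\n")
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$or_ci_low, ci_high = x$or_ci_high)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' `2 * (logLik(big) - logLik(small))` referred to chi-square with
#' degrees of freedom equal to the difference in term counts.  The
#' smaller model's terms must be a subset of the larger's and both fits
#' must use the same subjects.
#'
#' @param fit_small,fit_big Nested `logistic_fit` objects.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "logistic_fit"),
            inherits(fit_big, "logistic_fit"))
  if (!all(fit_small$terms %in% fit_big$terms)) {
    stop("models are not nested: ",
         paste(setdiff(fit_small$terms, fit_big$terms), collapse = ", "),
         " only in the smaller model")
  }
  if (fit_small$n_used != fit_big$n_used) {
    stop("nested fits must use the same subjects (",
         fit_small$n_used, " vs ", fit_big$n_used, ")")
  }
  df <- length(fit_big$terms) - length(fit_small$terms)
  stat <- max(0, 2 * (fit_big$loglik - fit_small$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Forward stepwise logistic selection
#'
#' Iteratively adds the candidate with the smallest likelihood-ratio
#' p-value below `p_enter`, then removes any included term whose
#' drop-one likelihood-ratio p-value exceeds `p_remove`, until neither
#' step changes the model.  Candidates are typically the markers that
#' survived the Bonferroni-corrected univariate screen, with a
#' composite carrier indicator replacing its member SNPs; both dosage
#' and carrier codings are legitimate columns.  Ties in p-value break
#' deterministically by candidate column order, then lexicographic name.
#'
#' @param candidates Numeric matrix or data frame of coded marker
#'   columns (named).
#' @param outcome Binary outcome vector.
#' @param p_enter,p_remove Entry and stay thresholds (conventional 0.05
#'   and 0.10).
#' @return An object of class `stepwise_path`: the step log (`step`,
#'   `action`, `term`, `p_value`), `selected` terms, and the `final_fit`
#'   (`NULL` when nothing enters).
#' @export
forward_stepwise <- function(candidates, outcome, p_enter = 0.05,
                             p_remove = 0.10) {
  candidates <- as.matrix(candidates)
  if (ncol(candidates) > 0L && is.null(colnames(candidates))) {
    colnames(candidates) <- paste0("x", seq_len(ncol(candidates)))
  }
  ok <- stats::complete.cases(candidates) & !is.na(outcome)
  candidates <- candidates[ok, , drop = FALSE]
  outcome <- outcome[ok]
  pool <- colnames(candidates)
  selected <- character(0)
  log_rows <- list()
  step <- 0L
  if (length(pool) == 0L) {
    return(new_stepwise_path(log_rows, selected, NULL))
  }
  refit <- function(terms) {
    fit_logistic(candidates[, terms, drop = FALSE], outcome)
  }
  current <- fit_logistic(candidates[, character(0), drop = FALSE],
                          outcome)
  repeat {
    changed <- FALSE
    remaining <- setdiff(pool, selected)
    if (length(remaining)) {
      p_add <- vapply(remaining, function(term) {
        tryCatch(
          likelihood_ratio_test(current, refit(c(selected, term)))$p_value,
          error = function(e) 1)   # constant/collinear candidate: never enters
      }, numeric(1))
      ord <- order(p_add, match(remaining, pool), remaining)
      best <- remaining[ord[1L]]
      if (p_add[ord[1L]] < p_enter) {
        selected <- c(selected, best)
        current <- refit(selected)
        step <- step + 1L
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = step, action = "add", term = best,
          p_value = p_add[ord[1L]], stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (length(selected)) {
      p_drop <- vapply(selected, function(term) {
        likelihood_ratio_test(refit(setdiff(selected, term)),
                              current)$p_value
      }, numeric(1))
      worst_i <- order(-p_drop, match(selected, pool), selected)[1L]
      if (p_drop[worst_i] > p_remove) {
        worst <- selected[worst_i]
        selected <- setdiff(selected, worst)
        current <- refit(selected)
        step <- step + 1L
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = step, action = "remove", term = worst,
          p_value = p_drop[worst_i], stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final <- if (length(selected)) refit(selected) else NULL
  new_stepwise_path(log_rows, selected, final)
}

new_stepwise_path <- function(log_rows, selected, final_fit) {
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(0), action = character(0),
               term = character(0), p_value = numeric(0))
  structure(list(log = log_df, selected = selected,
                 final_fit = final_fit),
            class = "stepwise_path")
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat("Forward stepwise path (", nrow(x$log), " steps)\n", sep = "")
  if (nrow(x$log)) print(x$log)
  cat("selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Screen pairwise gene-gene interactions
#'
#' For every pair of selected terms, compares the main-effects model
#' with the model plus the product term by likelihood-ratio test.  This
#' is the conventional check that the jointly selected markers act
#' without statistical interaction (flagged pairs have `p < alpha`).
#'
#' @param design Numeric matrix of the selected terms (named columns).
#' @param outcome Binary outcome vector.
#' @param alpha Flagging level.
#' @return Data frame with `term_a`, `term_b`, `statistic`, `p_value`,
#'   `flagged`; empty when fewer than two terms are supplied.
#' @export
interaction_screen <- function(design, outcome, alpha = 0.05) {
  design <- as.matrix(design)
  empty <- data.frame(term_a = character(0), term_b = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      flagged = logical(0))
  if (ncol(design) < 2L) return(empty)
  terms <- colnames(design)
  base_fit <- fit_logistic(design, outcome)
  rows <- list()
  for (i in seq_len(ncol(design) - 1L)) {
    for (j in seq((i + 1L), ncol(design))) {
      prod_col <- design[, i] * design[, j]
      aug <- cbind(design, prod_col)
      colnames(aug) <- c(terms, paste0(terms[i], ":", terms[j]))
      lrt <- tryCatch({
        fit_aug <- fit_logistic(aug, outcome)
        likelihood_ratio_test(base_fit, fit_aug)
      }, error = function(e) NULL)   # e.g. constant/collinear product
      if (is.null(lrt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        term_a = terms[i], term_b = terms[j],
        statistic = lrt$statistic, p_value = lrt$p_value,
        flagged = lrt$p_value < alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Build a stepwise design matrix from a cohort
#'
#' Extracts coded marker columns for one comparison: carrier (default)
#' or dosage coding per SNP, with composite markers replacing their
#' member SNPs, and the binary outcome (case arm = 1).  Complete-case
#' on the candidate set.
#'
#' @param cohort A `cd_cohort`.
#' @param comparison One of [cd_comparisons()].
#' @param marker_ids Candidate SNP ids and/or composite names.
#' @param composites Named list of composite member vectors.
#' @param coding `"carrier"` or `"dosage"`.
#' @return List with `design` (matrix) and `outcome` (0/1 vector).
#' @export
stepwise_design <- function(cohort, comparison, marker_ids,
                            composites = list(NOD2_any = nod2_snps()),
                            coding = c("carrier", "dosage")) {
  coding <- match.arg(coding)
  sel <- comparison_groups(comparison)
  case_rows <- select_group(cohort, sel[1L])
  ref_rows <- select_group(cohort, sel[2L])
  rows <- case_rows | ref_rows
  cols <- lapply(marker_ids, function(m) {
    if (m %in% names(composites)) {
      composite_indicator(cohort, composites[[m]])[rows]
    } else {
      d <- cohort$dosage[rows, m]
      if (coding == "carrier") as.integer(d >= 1) else d
    }
  })
  design <- do.call(cbind, cols)
  colnames(design) <- marker_ids
  outcome <- as.integer(case_rows[rows])
  keep <- stats::complete.cases(design)
  list(design = design[keep, , drop = FALSE], outcome = outcome[keep])
}
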