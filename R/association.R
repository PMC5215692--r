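#' The seven disease-site comparisons
#'
#' Labels of the case-control and site-versus-site contrasts: all CD or
#' one Montreal location versus healthy controls, and the three pairwise
#' site contrasts.  In each contrast the first-named group is the "case"
#' arm of the 2x2 table.
#'
#' @return Character vector of the seven comparison labels.
#' @export
cd_comparisons <- function() {
  c("CD_vs_ctrl", "L1_vs_ctrl", "L2_vs_ctrl", "L3_vs_ctrl",
    "L1_vs_L2", "L3_vs_L2", "L3_vs_L1")
}

comparison_groups <- function(label) {
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("unknown comparison label: ", label)
  parts
}

select_group <- function(cohort, sel) {
  s <- cohort$subjects
  switch(sel,
         ctrl = s$group == "control",
         CD = s$group == "CD",
         L1 = s$site == "L1",
         L2 = s$site == "L2",
         L3 = s$site == "L3",
         stop("unknown group selector: ", sel))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against Hardy-Weinberg proportions at the sample allele frequency.
#' Monomorphic samples are in trivial equilibrium and return `p = 1`.
#'
#' @param n_hom_risk,n_het,n_hom_other Genotype counts (dosage 2, 1, 0).
#' @return List with `chi2`, `p_value`, and the fitted allele frequency
#'   `p_hat`.
#' @export
hwe_test <- function(n_hom_risk, n_het, n_hom_other) {
  counts <- c(n_hom_risk, n_het, n_hom_other)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("hwe_test needs at least one genotyped subject")
  p_hat <- (2 * n_hom_risk + n_het) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(list(chi2 = 0, p_value = 1, p_hat = p_hat))
  }
  expected <- n * hwe_genotype_probs(p_hat)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       p_hat = p_hat)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' For a 2x2 table with cells `a` (case, exposed), `b` (case,
#' unexposed), `c` (reference, exposed), `d` (reference, unexposed):
#' `OR = ad / bc` with the Woolf log-scale interval
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.  If any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells
#' before estimation (the correction never touches test statistics).
#'
#' @param a,b,c,d Non-negative 2x2 cell counts; both rows must be
#'   non-empty.
#' @return List with `or`, `ci_low`, `ci_high`, and `corrected` (whether
#'   the 0.5 correction was applied).
#' @export
odds_ratio_ci <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0) {
    stop("odds_ratio_ci needs both table rows to be non-empty")
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       corrected = corrected)
}

# shared 2x2 engine: Pearson chi-square unless any expected cell < 5,
# then the two-sided Fisher exact test (Cochran's rule)
test_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE)
  if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5)) {
      list(p = stats::fisher.test(m)$p.value, test = "fisher")
    } else {
      list(p = stats::chisq.test(m, correct = FALSE)$p.value,
           test = "chi2")
    }
  } else {
    list(p = 1, test = "untestable")
  }
}

assoc_row <- function(marker_id, comparison, model, a, b, c, d,
                      alpha = 0.05, bonferroni_alpha = 0.05 / 19) {
  if ((a + b) == 0 || (c + d) == 0) {
    stop("association test needs non-missing observations in both arms")
  }
  untestable <- (a + c == 0) || (b + d == 0)
  if (untestable) {
    tst <- list(p = 1, test = "untestable")
    orci <- list(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                 corrected = FALSE)
  } else {
    tst <- test_2x2(a, b, c, d)
    orci <- odds_ratio_ci(a, b, c, d)
  }
  data.frame(marker_id = marker_id, comparison = comparison,
             model = model, a = a, b = b, c = c, d = d,
             p_value = tst$p, or_value = orci$or,
             ci_low = orci$ci_low, ci_high = orci$ci_high,
             test_used = tst$test,
             nominal_significant = tst$p < alpha,
             bonferroni_significant = tst$p < bonferroni_alpha,
             stringsAsFactors = FALSE)
}

#' Allelic case-control association test
#'
#' Builds the 2x2 table of risk versus other allele counts (each
#' genotyped subject contributes two chromosomes) and tests it by
#' Pearson's chi-square, falling back to the two-sided Fisher exact test
#' whenever any expected cell is below 5.  The odds ratio carries a
#' Woolf 95% CI; a marker monomorphic in both arms is flagged
#' `untestable` with `p = 1`, `OR = 1`.
#'
#' @param case_dosages,ref_dosages Dosage vectors in `{0, 1, 2, NA}`;
#'   missing dosages are dropped arm-wise (complete-case per SNP).
#' @param marker_id,comparison Labels copied into the result row.
#' @param alpha Nominal significance level.
#' @param bonferroni_alpha Corrected level, by default the locus-level
#'   `0.05 / 19` of the bundled panel.
#' @return One-row data frame (an association result).
#' @export
allelic_test <- function(case_dosages, ref_dosages, marker_id = "marker",
                         comparison = "CD_vs_ctrl", alpha = 0.05,
                         bonferroni_alpha = 0.05 / 19) {
  x <- case_dosages[!is.na(case_dosages)]
  y <- ref_dosages[!is.na(ref_dosages)]
  assoc_row(marker_id, comparison, "allelic",
            a = sum(x), b = 2 * length(x) - sum(x),
            c = sum(y), d = 2 * length(y) - sum(y),
            alpha = alpha, bonferroni_alpha = bonferroni_alpha)
}

#' Carrier (dominant) genotype association test
#'
#' Tests carriers of at least one risk allele (dosage >= 1, the
#' "aa + Aa" coding) against non-carriers in a subject-level 2x2 table,
#' with the same chi-square/Fisher and odds-ratio machinery as
#' [allelic_test()].
#'
#' @inheritParams allelic_test
#' @return One-row data frame (an association result).
#' @export
carrier_test <- function(case_dosages, ref_dosages, marker_id = "marker",
                         comparison = "CD_vs_ctrl", alpha = 0.05,
                         bonferroni_alpha = 0.05 / 19) {
  x <- case_dosages[!is.na(case_dosages)]
  y <- ref_dosages[!is.na(ref_dosages)]
  assoc_row(marker_id, comparison, "carrier",
            a = sum(x >= 1), b = sum(x == 0),
            c = sum(y >= 1), d = sum(y == 0),
            alpha = alpha, bonferroni_alpha = bonferroni_alpha)
}

#' Composite carrier indicator over several SNPs
#'
#' Per-subject indicator that at least one member SNP carries a risk
#' allele, e.g. the "at least one NOD2 risk genotype" marker over
#' rs2066844, rs2066845 and rs2066847.  With partial missingness a
#' subject whose present members are all dosage 0 scores 0
#' (optimistic-absence rule); only subjects missing every member are
#' missing.  Set `strict_missing = TRUE` to score any subject with a
#' missing member and no observed risk allele as missing instead.
#'
#' @param cohort A `cd_cohort`.
#' @param member_snp_ids SNP ids of the members; must be in the panel.
#' @param strict_missing Use the conservative missingness rule.
#' @return Integer vector (0/1/NA), one element per subject.
#' @export
composite_indicator <- function(cohort,
                                member_snp_ids = nod2_snps(),
                                strict_missing = FALSE) {
  if (length(member_snp_ids) == 0L) {
    stop("composite marker needs at least one member SNP")
  }
  missing_members <- setdiff(member_snp_ids, cohort$panel$snp_id)
  if (length(missing_members)) {
    stop("member SNP(s) not in panel: ",
         paste(missing_members, collapse = ", "))
  }
  d <- cohort$dosage[, member_snp_ids, drop = FALSE]
  any_risk <- apply(d, 1L, function(z) any(!is.na(z) & z >= 1))
  all_missing <- apply(d, 1L, function(z) all(is.na(z)))
  out <- ifelse(any_risk, 1L, 0L)
  out[all_missing] <- NA_integer_
  if (strict_missing) {
    some_missing <- apply(d, 1L, anyNA)
    out[some_missing & !any_risk] <- NA_integer_
  }
  out
}

#' The three NOD2 risk variants
#'
#' R702W, G908R and the 1007fs frameshift — the members of the default
#' composite marker.
#'
#' @return Character vector of three rsIDs.
#' @export
nod2_snps <- function() c("rs2066844", "rs2066845", "rs2066847")

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise threshold `alpha / n_loci`.  The bundled panel corrects
#' at the locus level (19 loci rather than 29 SNPs), giving the
#' conventional `0.05 / 19 = 2.6e-3`.
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param n_loci Number of independent loci.
#' @return The adjusted per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_loci = 19L) {
  stopifnot(alpha > 0, alpha < 1, n_loci >= 1)
  alpha / n_loci
}

#' Run the full association battery
#'
#' Applies the allelic and/or carrier test to every panel SNP and every
#' requested composite marker across the requested comparisons,
#' producing one association-result row per (marker, comparison, model).
#' Comparisons whose groups are absent from the cohort are skipped with
#' a warning.  Composite markers are tested under the carrier model
#' only (their indicator is already a carrier coding).
#'
#' @param cohort A `cd_cohort`.
#' @param models Subset of `c("allelic", "carrier")`.
#' @param comparisons Subset of [cd_comparisons()].
#' @param composites Named list of member-SNP vectors; default adds the
#'   `NOD2_any` composite.  Use `list()` for none.
#' @param alpha,n_loci Nominal level and Bonferroni denominator.
#' @return Data frame of association results (class `assoc_table`).
#' @export
run_comparisons <- function(cohort,
                            models = c("allelic", "carrier"),
                            comparisons = cd_comparisons(),
                            composites = list(NOD2_any = nod2_snps()),
                            alpha = 0.05, n_loci = 19L) {
  models <- match.arg(models, several.ok = TRUE)
  bad <- setdiff(comparisons, cd_comparisons())
  if (length(bad)) stop("unknown comparison label(s): ",
                        paste(bad, collapse = ", "))
  bonf <- bonferroni_threshold(alpha, n_loci)
  comp_ind <- lapply(composites, function(m) composite_indicator(cohort, m))
  rows <- list()
  for (cmp in comparisons) {
    sel <- comparison_groups(cmp)
    case_rows <- select_group(cohort, sel[1L])
    ref_rows <- select_group(cohort, sel[2L])
    if (!any(case_rows) || !any(ref_rows)) {
      warning("comparison ", cmp, " skipped: group absent from cohort")
      next
    }
    for (sid in cohort$panel$snp_id) {
      dc <- cohort$dosage[case_rows, sid]
      dr <- cohort$dosage[ref_rows, sid]
      if (all(is.na(dc)) || all(is.na(dr))) next
      if ("allelic" %in% models) {
        rows[[length(rows) + 1L]] <-
          allelic_test(dc, dr, sid, cmp, alpha, bonf)
      }
      if ("carrier" %in% models) {
        rows[[length(rows) + 1L]] <-
          carrier_test(dc, dr, sid, cmp, alpha, bonf)
      }
    }
    for (cid in names(comp_ind)) {
      ind <- comp_ind[[cid]]
      rows[[length(rows) + 1L]] <-
        carrier_test(ind[case_rows], ind[ref_rows], cid, cmp, alpha, bonf)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- assoc_row("x", "CD_vs_ctrl", "allelic", 1, 1, 1, 1)[0, ]
  }
  out$composite_flag <- out$marker_id %in% names(composites)
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Count significant markers in one comparison
#'
#' Number of rows with `p < alpha` for a given comparison, in either a
#' computed association table or a bundled printed-table fixture.  SNP
#' rows only by default; composite rows (e.g. `NOD2_any`) are counted
#' when `include_composite = TRUE` — the published tallies themselves
#' count the composite in the versus-control strata (16, 14) but not in
#' the site-versus-site strata (5, 3).
#'
#' @param table Data frame with `comparison`, `p_value` and
#'   `composite_flag` columns (an `assoc_table` or a table fixture).
#' @param comparison One of [cd_comparisons()].
#' @param alpha Significance level.
#' @param include_composite Count composite-marker rows too.
#' @param model Restrict to one genetic model if the table carries a
#'   `model` column (default: count each marker once, preferring the
#'   carrier row when both are present).
#' @return Integer count.
#' @export
tally_significant <- function(table, comparison, alpha = 0.05,
                              include_composite = FALSE,
                              model = NULL) {
  if (!comparison %in% cd_comparisons()) {
    stop("unknown comparison label: ", comparison)
  }
  if (!all(c("comparison", "p_value") %in% names(table))) {
    stop("table lacks comparison/p_value columns")
  }
  df <- table[table$comparison == comparison, , drop = FALSE]
  if (!is.null(model) && "model" %in% names(df)) {
    df <- df[df$model == model, , drop = FALSE]
  } else if ("model" %in% names(df) && any(duplicated(df$marker_id))) {
    keep <- df$model == "carrier" |
      !df$marker_id %in% df$marker_id[df$model == "carrier"]
    df <- df[keep, , drop = FALSE]
  }
  if (!include_composite && "composite_flag" %in% names(df)) {
    df <- df[!df$composite_flag, , drop = FALSE]
  }
  sum(!is.na(df$p_value) & df$p_value < alpha)
}

#' Hardy-Weinberg screen across a cohort
#'
#' Runs [hwe_test()] for every panel SNP within each subject group
#' (controls and each disease site), the routine equilibrium check done
#' before association testing.
#'
#' @param cohort A `cd_cohort`.
#' @param groups Group selectors (subset of `ctrl`, `CD`, `L1`, `L2`,
#'   `L3`).
#' @return Data frame with `snp_id`, `group`, genotype counts, `chi2`,
#'   `p_value`.
#' @export
hwe_by_group <- function(cohort, groups = c("ctrl", "L1", "L2", "L3")) {
  rows <- list()
  for (g in groups) {
    in_g <- select_group(cohort, g)
    if (!any(in_g)) next
    for (sid in cohort$panel$snp_id) {
      d <- cohort$dosage[in_g, sid]
      d <- d[!is.na(d)]
      if (!length(d)) next
      res <- hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = sid, group = g, n_hom_risk = sum(d == 2),
        n_het = sum(d == 1), n_hom_other = sum(d == 0),
        chi2 = res$chi2, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
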