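#' Published summary tables bundled as fixtures
#'
#' The package ships the printed summary tables of the source cohort as
#' plain-text fixtures, for tally and reporting operations on the
#' published numbers (the underlying genotypes were never deposited, so
#' these cells are data, not recomputation targets):
#'
#' * `"table1"` — clinical/demographic counts of the 708 CD patients by
#'   disease site (237 L1, 300 L3, 171 L2).
#' * `"table2"` — allelic case-control results for the 29 SNPs: risk
#'   allele frequencies, p-values, odds ratios, 95% CIs, Bonferroni flag.
#'   For rs2066847 the CI is the one given in the running text (1.8-4.6);
#'   the table as printed carries an inconsistent lower bound.
#' * `"table3"` — genotype (carrier) analyses per disease-site
#'   comparison, stored long: one row per non-empty printed cell, with a
#'   `composite_flag` marking the "at least one NOD2 risk genotype" row.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`.
#' @return A data frame; `table2`/`table3` have numeric `p_value`,
#'   `or_value`, `ci_low`, `ci_high` (NA where the printed cell is empty)
#'   plus `comparison` labels (`table2` rows are all `CD_vs_ctrl`).
#' @export
cd_table_fixture <- function(table_id = c("table1", "table2", "table3")) {
  table_id <- match.arg(table_id)
  fname <- switch(table_id,
                  table1 = "table1_clinical.tsv",
                  table2 = "table2_allelic.tsv",
                  table3 = "table3_genotype.tsv")
  path <- system.file("extdata", fname, package = "crohnsite",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (table_id == "table1") return(df)
  for (col in c("p_value", "or_value", "ci_low", "ci_high")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$composite_flag <- df$composite_flag == 1
  df$bonferroni_flag <- df$bonferroni_flag == 1
  if (table_id == "table2") {
    stopifnot(nrow(df) == 29L)
    df$marker_id <- df$snp_id
    df$comparison <- "CD_vs_ctrl"
  } else {
    stopifnot(length(unique(df$marker_id)) == 20L,
              length(unique(df$comparison)) == 6L)
  }
  df
}

#' Percentages from the clinical-characteristics fixture
#'
#' Recomputes the per-column percentages of the printed clinical table
#' from its counts, excluding `missing` rows from the denominator and
#' rounding half-up to integers, i.e. the same convention as
#' [cohort_summary()].
#'
#' @param fixture The `"table1"` fixture (default: load it).
#' @return The fixture with a `percent` column added (NA on `missing`
#'   rows).
#' @export
table1_percentages <- function(fixture = cd_table_fixture("table1")) {
  fixture$percent <- NA_real_
  key <- interaction(fixture$covariate, fixture$group, drop = TRUE)
  for (k in levels(key)) {
    rows <- which(key == k)
    known <- rows[fixture$category[rows] != "missing"]
    denom <- sum(fixture$count[known])
    if (denom > 0) {
      fixture$percent[known] <-
        floor(100 * fixture$count[known] / denom + 0.5)
    }
  }
  fixture
}
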