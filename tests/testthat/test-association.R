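test_that("HWE test matches hand-computed goodness of fit", {
  res <- hwe_test(25, 50, 25)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(hwe_test(100, 0, 0)$p_value, 1)   # monomorphic convention
  res <- hwe_test(30, 60, 10)
  expect_equal(res$p_hat, 0.6)
  expect_equal(res$chi2, 6.25)
  expect_equal(res$p_value, pchisq(6.25, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 0.012419, tolerance = 1e-4)
  expect_error(hwe_test(0, 0, 0), "at least one")
})

test_that("Woolf odds-ratio interval and Haldane correction", {
  res <- odds_ratio_ci(50, 50, 50, 50)
  expect_equal(res$or, 1)
  expect_true(res$ci_low < 1 && res$ci_high > 1)

  res <- odds_ratio_ci(100, 100, 50, 150)
  expect_equal(res$or, 3)
  se <- sqrt(1 / 100 + 1 / 100 + 1 / 50 + 1 / 150)
  expect_equal(res$ci_low, exp(log(3) - 1.96 * se))
  expect_equal(res$ci_low, 1.9645, tolerance = 1e-4)
  expect_equal(res$ci_high, 4.5815, tolerance = 1e-4)

  res <- odds_ratio_ci(10, 90, 0, 100)
  expect_true(res$corrected)
  expect_equal(res$or, (10.5 * 100.5) / (90.5 * 0.5))
  expect_equal(res$or, 23.32, tolerance = 1e-3)

  expect_error(odds_ratio_ci(0, 0, 5, 5), "non-empty")
})

test_that("allelic test builds the published-style 2x2 from dosages", {
  # identical arms: no association
  d <- c(rep(0L, 50), rep(1L, 30), rep(2L, 20))
  res <- allelic_test(d, d)
  expect_equal(res$or_value, 1)
  expect_equal(res$p_value, 1)

  # counts reconstructed from printed frequencies (0.09 vs 0.04)
  a <- raf_to_allele_counts(0.09, 708)   # 127
  c_ <- raf_to_allele_counts(0.04, 537)  # 43
  res <- assoc_or <- odds_ratio_ci(a, 2 * 708 - a, c_, 2 * 537 - c_)
  expect_equal(res$or, 2.362, tolerance = 1e-3)

  # missing dosages drop out arm-wise
  res <- allelic_test(c(2L, NA, 0L), c(0L, 0L, NA))
  expect_equal(res$a + res$b, 4)   # 2 subjects x 2 alleles
  expect_equal(res$c + res$d, 4)

  # small arms with a zero cell trigger the Fisher fallback
  res <- allelic_test(c(1L, 1L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L, 0L))
  expect_equal(res$test_used, "fisher")

  # monomorphic in both arms: untestable
  res <- allelic_test(rep(0L, 10), rep(0L, 10))
  expect_equal(res$test_used, "untestable")
  expect_equal(res$p_value, 1)
  expect_equal(res$or_value, 1)
})

test_that("carrier test uses the dominant coding", {
  cases <- c(rep(1L, 60), rep(0L, 40))
  refs <- c(rep(2L, 40), rep(0L, 60))
  res <- carrier_test(cases, refs)
  expect_equal(res$or_value, 2.25)
  res <- carrier_test(c(2L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L))
  expect_equal(c(res$a, res$b, res$c, res$d), c(2, 2, 1, 3))
  res <- carrier_test(rep(2L, 5), rep(1L, 5))
  expect_equal(res$test_used, "untestable")
})

test_that("composite indicator implements the any-risk-genotype rule", {
  panel <- toy_panel(3)
  dos <- rbind(c(0L, 0L, 1L),
               c(0L, 0L, 0L),
               c(NA, 0L, 0L),
               c(NA, NA, NA),
               c(NA, 2L, NA))
  co <- toy_cohort(dos, sites = c("none", "none", "L1", "L1", "L2"),
                   panel = panel)
  ind <- composite_indicator(co, c("rs1", "rs2", "rs3"))
  expect_equal(unname(ind), c(1L, 0L, 0L, NA, 1L))
  strict <- composite_indicator(co, c("rs1", "rs2", "rs3"),
                                strict_missing = TRUE)
  expect_equal(unname(strict), c(1L, 0L, NA, NA, 1L))
  expect_error(composite_indicator(co, character(0)), "at least one")
  expect_error(composite_indicator(co, "rs99"), "not in panel")
})

test_that("Bonferroni threshold divides by the locus count", {
  expect_equal(signif(bonferroni_threshold(0.05, 19), 2), 2.6e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 29), 0.05 / 29)
  expect_error(bonferroni_threshold(0, 19))
})

test_that("run_comparisons covers markers x comparisons and skips absent groups", {
  set.seed(8)
  sim <- simulate_cohort(sim_config(
    panel = cd_panel(),
    group_sizes = c(control = 60, L1 = 40, L2 = 0, L3 = 30),
    seed = 12))
  # three comparisons involve the absent L2 group; each warns once
  expect_warning(expect_warning(expect_warning(
    tab <- run_comparisons(sim$cohort), "skipped"), "skipped"), "skipped")
  expect_false(any(grepl("L2", tab$comparison)))
  expect_true(all(c("CD_vs_ctrl", "L1_vs_ctrl", "L3_vs_ctrl", "L3_vs_L1")
                  %in% tab$comparison))
  # both models for SNPs, carrier-only for the composite
  cd <- tab[tab$comparison == "CD_vs_ctrl", ]
  expect_equal(sum(cd$model == "allelic"), 29L)
  expect_equal(sum(cd$model == "carrier"), 30L)
  expect_true(all(tab$or_value > 0, na.rm = TRUE))
  expect_true(all(tab$ci_low <= tab$or_value & tab$or_value <= tab$ci_high,
                  na.rm = TRUE))
  # margins equal the non-missing totals
  expect_true(all(tab$a + tab$b > 0 & tab$c + tab$d > 0))
})

test_that("single-SNP cohort produces one row per comparison and model", {
  set.seed(9)
  panel <- toy_panel(1)
  raf <- matrix(0.4, 1, 4, dimnames = list("rs1",
                                           c("control", "L1", "L2", "L3")))
  sim <- simulate_cohort(sim_config(
    panel = panel, raf = raf,
    group_sizes = c(control = 50, L1 = 20, L2 = 20, L3 = 20), seed = 3))
  tab <- run_comparisons(sim$cohort, models = "allelic",
                         composites = list())
  expect_equal(nrow(tab), 7L)
  expect_setequal(tab$comparison, cd_comparisons())
})

test_that("results are invariant to subject and SNP order", {
  set.seed(10)
  sim <- simulate_cohort(sim_config(
    panel = cd_panel(),
    group_sizes = c(control = 80, L1 = 40, L2 = 30, L3 = 40), seed = 44))
  co <- sim$cohort
  tab1 <- run_comparisons(co, comparisons = "CD_vs_ctrl")
  perm <- sample(nrow(co$subjects))
  co2 <- cd_cohort(co$subjects[perm, ], co$panel,
                   co$dosage[perm, ])
  snp_perm <- sample(nrow(co$panel))
  panel3 <- new_panel <- co$panel[snp_perm, ]
  class(panel3) <- class(co$panel)
  co3 <- cd_cohort(co$subjects, panel3, co$dosage[, snp_perm])
  tab2 <- run_comparisons(co2, comparisons = "CD_vs_ctrl")
  tab3 <- run_comparisons(co3, comparisons = "CD_vs_ctrl")
  expect_equal(tab2[order(tab2$marker_id, tab2$model),
                    c("p_value", "or_value")],
               tab1[order(tab1$marker_id, tab1$model),
                    c("p_value", "or_value")],
               ignore_attr = TRUE)
  expect_equal(tab3[order(tab3$marker_id, tab3$model),
                    c("p_value", "or_value")],
               tab1[order(tab1$marker_id, tab1$model),
                    c("p_value", "or_value")],
               ignore_attr = TRUE)
})

test_that("tally_significant counts fixture cells and is monotone in alpha", {
  t3 <- cd_table_fixture("table3")
  expect_equal(tally_significant(t3, "L2_vs_ctrl", 0.05), 7L)
  expect_equal(tally_significant(t3, "L1_vs_L2", 0.05), 5L)
  expect_equal(tally_significant(t3[0, ], "L1_vs_ctrl"), 0L)
  expect_error(tally_significant(t3, "L9_vs_ctrl"), "unknown comparison")
  alphas <- c(1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.5)
  tallies <- vapply(alphas, function(a)
    tally_significant(t3, "L1_vs_ctrl", a, include_composite = TRUE),
    integer(1))
  expect_true(all(diff(tallies) >= 0))
})

test_that("HWE screen runs per group over a cohort", {
  set.seed(13)
  sim <- simulate_cohort(sim_config(
    panel = cd_panel(),
    group_sizes = c(control = 100, L1 = 50, L2 = 50, L3 = 50), seed = 2))
  hw <- hwe_by_group(sim$cohort)
  expect_setequal(unique(hw$group), c("ctrl", "L1", "L2", "L3"))
  expect_equal(nrow(hw), 4L * 29L)
  expect_true(all(hw$p_value >= 0 & hw$p_value <= 1))
})
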