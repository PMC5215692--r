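test_that("bundled panel has 29 SNPs over 19 loci with valid alleles", {
  p <- cd_panel()
  expect_s3_class(p, "snp_panel")
  expect_equal(nrow(p), 29L)
  expect_equal(length(unique(p$locus_id)), 19L)
  expect_false(anyDuplicated(p$snp_id) > 0)
  expect_true(all(p$risk_allele != p$other_allele))
  expect_setequal(unique(c(p$risk_allele, p$other_allele)),
                  c("A", "C", "G", "T"))
})

test_that("panel loading validates structure and rejects bad rows", {
  path <- tempfile(fileext = ".tsv")
  header <- "snp_id\tchrom_band\tlocus_id\tgene_label\trisk_allele\tother_allele"
  writeLines(header, path)
  expect_warning(p0 <- load_panel(path), "no entries")
  expect_equal(nrow(p0), 0L)

  writeLines(c(header, "rs1\t1p\t1p\tG1\tA\tA"), path)
  expect_error(load_panel(path), "risk_allele equals other_allele")

  writeLines(c(header, "rs1\t1p\t1p\tG1\tA\tN"), path)
  expect_error(load_panel(path), "malformed allele")

  writeLines(c(header, "rs1\t1p\t1p\tG1\tA\tG", "rs1\t2p\t2p\tG2\tT\tC"),
             path)
  expect_error(load_panel(path), "duplicate snp_id")

  writeLines("snp_id\tchrom_band", path)
  expect_error(load_panel(path), "missing column")
})

test_that("dosage encoding counts risk alleles symmetrically", {
  expect_equal(encode_dosage("T/T", "T", "C"), 2L)
  expect_equal(encode_dosage("C/T", "T", "C"), 1L)
  expect_equal(encode_dosage("T/C", "T", "C"), 1L)
  expect_equal(encode_dosage("C/C", "T", "C"), 0L)
  expect_equal(encode_dosage("./.", "T", "C"), NA_integer_)
  expect_error(encode_dosage("A/T", "T", "C", snp_id = "rsX"), "rsX")
  # vectorised with mixed missing
  expect_equal(encode_dosage(c("T/T", "./.", "C/T"), "T", "C"),
               c(2L, NA, 1L))
})

test_that("RAF-to-count reconstruction rounds to the nearest integer", {
  expect_equal(raf_to_allele_counts(0.5, 100), 100L)
  expect_equal(raf_to_allele_counts(0.09, 708), 127L)
  expect_equal(raf_to_allele_counts(0.0, 537), 0L)
  # property: reconstructed frequency within 1/(4n) of the input
  set.seed(11)
  for (i in 1:50) {
    raf <- runif(1)
    n <- sample(10:2000, 1)
    cnt <- raf_to_allele_counts(raf, n)
    expect_lte(abs(cnt / (2 * n) - raf), 1 / (4 * n) + 1e-12)
  }
})

test_that("cohort loading enforces id matching and label domains", {
  panel <- toy_panel(2)
  gpath <- tempfile(fileext = ".tsv")
  ppath <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\trs1\trs2",
               "s1\tT/T\tC/G", "s2\tC/T\tG/G", "s3\t./.\tC/C"), gpath)
  writeLines(c("subject_id\tgroup\tsite",
               "s1\tcontrol\tnone", "s2\tCD\tL1", "s3\tCD\tL2"), ppath)
  co <- load_cohort(gpath, ppath, panel, quiet = TRUE)
  expect_equal(dim(co$dosage), c(3L, 2L))
  expect_equal(unname(co$dosage[, "rs1"]), c(2L, 1L, NA))
  expect_equal(unname(co$dosage[, "rs2"]), c(1L, 0L, 2L))

  writeLines(c("subject_id\tgroup\tsite",
               "s1\tcontrol\tnone", "s2\tCD\tL5", "s3\tCD\tL2"), ppath)
  expect_error(load_cohort(gpath, ppath, panel, quiet = TRUE),
               "unknown site")

  writeLines(c("subject_id\tgroup\tsite",
               "s1\tcontrol\tnone", "s2\tCD\tL1", "s4\tCD\tL2"), ppath)
  expect_error(load_cohort(gpath, ppath, panel, quiet = TRUE),
               "do not match")

  writeLines(c("subject_id\trs1\trsX",
               "s1\tT/T\tC/G", "s2\tC/T\tG/G", "s3\t./.\tC/C"), gpath)
  expect_error(load_cohort(gpath, ppath, panel, quiet = TRUE), "rsX")
})

test_that("write_cohort / load_cohort round-trips dosages and labels", {
  set.seed(42)
  sim <- simulate_cohort(sim_config(
    panel = cd_panel(),
    group_sizes = c(control = 40, L1 = 20, L2 = 15, L3 = 25),
    missing_rate = 0.05, seed = 99))
  dir <- tempfile()
  dir.create(dir)
  gp <- file.path(dir, "g.tsv")
  pp <- file.path(dir, "p.tsv")
  write_cohort(sim$cohort, gp, pp)
  re <- load_cohort(gp, pp, sim$cohort$panel, quiet = TRUE)
  expect_identical(re$dosage, sim$cohort$dosage)
  expect_identical(re$subjects$group, sim$cohort$subjects$group)
  expect_identical(re$subjects$site, sim$cohort$subjects$site)
})

test_that("VCF genotypes map onto panel dosages by ID", {
  skip_if_not_installed("vcfR")
  panel <- toy_panel(2)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t./.",
    "2\t200\trs2\tC\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), vcf)
  pp <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tgroup\tsite",
               "s1\tcontrol\tnone", "s2\tCD\tL1", "s3\tCD\tL3"), pp)
  co <- load_cohort_vcf(vcf, pp, panel)
  # rs1 risk T = ALT; rs2 risk C = REF
  expect_equal(unname(co$dosage[, "rs1"]), c(2L, 1L, NA))
  expect_equal(unname(co$dosage[, "rs2"]), c(2L, 1L, 0L))
})

test_that("cohort summary counts, percentages and missing rows", {
  subjects <- data.frame(
    subject_id = sprintf("s%02d", 1:10),
    group = c("control", rep("CD", 9)),
    site = c("none", rep(c("L1", "L2", "L3"), each = 3)),
    sex = c("f", "f", "f", "m", "f", "m", NA, "m", "m", "f"),
    stringsAsFactors = FALSE)
  panel <- toy_panel(1)
  co <- cd_cohort(subjects, panel,
                  matrix(0L, 10, 1, dimnames = list(NULL, "rs1")))
  s <- cohort_summary(co, "sex")
  all_f <- s[s$group == "all" & s$category == "f", ]
  expect_equal(all_f$count, 4L)        # 9 CD, one NA sex
  expect_equal(all_f$percent, 50)      # 4 of 8 known
  expect_equal(s[s$group == "all" & s$category == "missing", "count"], 1L)
  # single-category covariate gives 100%
  co$subjects$onecat <- "x"
  s2 <- cohort_summary(co, "onecat")
  expect_true(all(s2$percent == 100))
  # percentages per covariate/group sum to 100 +/- 1
  sums <- tapply(s$percent[s$category != "missing"],
                 s$group[s$category != "missing"], sum)
  expect_true(all(abs(sums - 100) <= 1))
})

test_that("printed-table fixtures match their published shape", {
  t1 <- cd_table_fixture("table1")
  t2 <- cd_table_fixture("table2")
  t3 <- cd_table_fixture("table3")
  expect_equal(nrow(t2), 29L)
  expect_equal(length(unique(t3$marker_id)), 20L)
  expect_equal(length(unique(t3$comparison)), 6L)
  expect_equal(sum(t3$composite_flag), 4L)   # NOD2_any appears in 4 strata
  # group sizes recoverable from the clinical fixture
  gender <- t1[t1$covariate == "gender", ]
  expect_equal(sum(gender$count[gender$group == "all"]), 708L)
  expect_equal(sum(gender$count[gender$group == "L1"]), 237L)
  expect_equal(sum(gender$count[gender$group == "L2"]), 171L)
  expect_equal(sum(gender$count[gender$group == "L3"]), 300L)
  # female row as printed
  expect_equal(gender$count[gender$group == "all" &
                              gender$category == "female"], 294L)
})
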