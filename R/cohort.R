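#' Construct a case-control cohort object
#'
#' A cohort couples a phenotype table (one row per subject) with a panel
#' and a subjects-by-SNPs dosage matrix of risk-allele counts.  Controls
#' carry `site == "none"`; every Crohn's disease (CD) subject carries a
#' Montreal location label: L1 (ileal), L2 (colonic) or L3 (ileocolonic).
#'
#' @param subjects Data frame with at least `subject_id`, `group`
#'   (`"control"` or `"CD"`) and `site` (`"none"`, `"L1"`, `"L2"`,
#'   `"L3"`); further columns are kept as covariates.
#' @param panel An `snp_panel`.
#' @param dosage Integer matrix, `nrow(subjects)` by `nrow(panel)`, values
#'   in `{0, 1, 2, NA}`; column names must equal `panel$snp_id`.
#' @return An object of class `cd_cohort`.
#' @export
cd_cohort <- function(subjects, panel, dosage) {
  stopifnot(is.data.frame(subjects), inherits(panel, "snp_panel"))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(subjects) || ncol(dosage) != nrow(panel)) {
    stop("dosage matrix is ", nrow(dosage), "x", ncol(dosage),
         " but cohort has ", nrow(subjects), " subjects and ",
         nrow(panel), " SNPs")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- panel$snp_id
  if (!identical(colnames(dosage), panel$snp_id)) {
    dosage <- dosage[, panel$snp_id, drop = FALSE]
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  validate_subjects(subjects)
  rownames(dosage) <- subjects$subject_id
  structure(list(subjects = subjects, panel = panel,
                 dosage = dosage),
            class = "cd_cohort")
}

validate_subjects <- function(subjects) {
  required <- c("subject_id", "group", "site")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols)) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in phenotype table")
  }
  bad_group <- !subjects$group %in% c("control", "CD")
  if (any(bad_group)) {
    stop("unknown group label(s): ",
         paste(unique(subjects$group[bad_group]), collapse = ", "))
  }
  bad_site <- !subjects$site %in% c("none", "L1", "L2", "L3")
  if (any(bad_site)) {
    stop("unknown site label(s): ",
         paste(unique(subjects$site[bad_site]), collapse = ", "))
  }
  ctrl_site <- subjects$group == "control" & subjects$site != "none"
  if (any(ctrl_site)) stop("controls must carry site = none")
  cd_site <- subjects$group == "CD" & !subjects$site %in% c("L1", "L2", "L3")
  if (any(cd_site)) stop("CD subjects must carry site L1, L2 or L3")
  invisible(subjects)
}

#' @export
print.cd_cohort <- function(x, ...) {
  tab <- table(factor(x$subjects$site, c("none", "L1", "L2", "L3")))
  cat("Case-control cohort:", nrow(x$subjects), "subjects x",
      nrow(x$panel), "SNPs\n")
  cat("  controls:", tab[["none"]],
      " L1:", tab[["L1"]], " L2:", tab[["L2"]], " L3:", tab[["L3"]], "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Read a cohort from genotype and phenotype files
#'
#' The genotype file is tab-separated with a `subject_id` column followed
#' by one column per rsID holding diploid calls `"X/Y"` (missing:
#' `"./."`).  The phenotype file is tab-separated with `subject_id`,
#' `group`, `site` and optional covariate columns.  Subject ids must
#' match one-to-one between the two files.
#'
#' @param genotype_path,phenotype_path Paths to the two TSV files.
#' @param panel An `snp_panel`; every rsID column in the genotype file
#'   must appear in the panel and vice versa.
#' @param quiet Suppress the per-SNP missingness message.
#' @return A `cd_cohort`.
#' @export
load_cohort <- function(genotype_path, phenotype_path, panel,
                        quiet = FALSE) {
  geno <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                            check.names = FALSE,
                            colClasses = "character")
  pheno <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  if (!"subject_id" %in% names(geno)) {
    stop("genotype file lacks a subject_id column")
  }
  snp_cols <- setdiff(names(geno), "subject_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  absent <- setdiff(panel$snp_id, snp_cols)
  if (length(unknown) || length(absent)) {
    stop("genotype columns do not match panel; unmatched: ",
         paste(c(unknown, absent), collapse = ", "))
  }
  pheno$subject_id <- as.character(pheno$subject_id)
  only_geno <- setdiff(geno$subject_id, pheno$subject_id)
  only_pheno <- setdiff(pheno$subject_id, geno$subject_id)
  if (length(only_geno) || length(only_pheno)) {
    stop("subject ids do not match between files; only in genotypes: ",
         paste(utils::head(only_geno, 5), collapse = ", "),
         "; only in phenotypes: ",
         paste(utils::head(only_pheno, 5), collapse = ", "))
  }
  geno <- geno[match(pheno$subject_id, geno$subject_id), , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(pheno), nrow(panel),
                   dimnames = list(pheno$subject_id, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    sid <- panel$snp_id[j]
    dosage[, sid] <- encode_dosage(geno[[sid]], panel$risk_allele[j],
                                   panel$other_allele[j], snp_id = sid,
                                   subject_id = geno$subject_id)
  }
  if (!quiet) {
    miss <- colMeans(is.na(dosage))
    worst <- sort(miss, decreasing = TRUE)[1L]
    message(sprintf(
      "loaded %d subjects x %d SNPs; mean missingness %.2f%% (max %.2f%% at %s)",
      nrow(dosage), ncol(dosage), 100 * mean(miss), 100 * worst,
      names(worst)))
  }
  cd_cohort(pheno, panel, dosage)
}

#' Write a cohort back to the genotype/phenotype file dialect
#'
#' Inverse of [load_cohort()]: dosages are rendered as diploid calls
#' using the panel's alleles (heterozygotes as `other/risk`), missing as
#' `"./."`.  `load_cohort(write_cohort(x))` reproduces `x`'s dosage
#' matrix, labels and covariates exactly.
#'
#' @param cohort A `cd_cohort`.
#' @param genotype_path,phenotype_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, genotype_path, phenotype_path) {
  panel <- cohort$panel
  d <- cohort$dosage
  calls <- matrix("./.", nrow(d), ncol(d),
                  dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    r <- panel$risk_allele[j]
    o <- panel$other_allele[j]
    gg <- c(paste(o, o, sep = "/"), paste(o, r, sep = "/"),
            paste(r, r, sep = "/"))
    ok <- !is.na(d[, j])
    calls[ok, j] <- gg[d[ok, j] + 1L]
  }
  geno <- data.frame(subject_id = cohort$subjects$subject_id,
                     calls, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(geno, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$subjects, phenotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Read genotypes from a VCF file against a panel
#'
#' Maps `GT` fields of an (uncompressed or bgzipped) VCF onto risk-allele
#' dosages, matching records to the panel by the `ID` column; positions
#' are ignored.  REF/ALT must be the panel's two alleles (in either
#' orientation).  Requires the `vcfR` package.
#'
#' @param vcf_path Path to the VCF.
#' @param phenotype_path Phenotype TSV as in [load_cohort()].
#' @param panel An `snp_panel`.
#' @return A `cd_cohort`.
#' @export
load_cohort_vcf <- function(vcf_path, phenotype_path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("load_cohort_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- ids %in% panel$snp_id
  if (!any(keep)) stop("no VCF record ID matches the panel")
  gt <- vcfR::extract.gt(v, element = "GT")
  pheno <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  pheno$subject_id <- as.character(pheno$subject_id)
  dosage <- matrix(NA_integer_, nrow(pheno), nrow(panel),
                   dimnames = list(pheno$subject_id, panel$snp_id))
  for (i in which(keep)) {
    sid <- ids[i]
    j <- match(sid, panel$snp_id)
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    if (!setequal(c(ref, alt),
                  c(panel$risk_allele[j], panel$other_allele[j]))) {
      stop("VCF REF/ALT (", ref, "/", alt, ") do not match panel alleles",
           " for ", sid)
    }
    risk_code <- if (alt == panel$risk_allele[j]) "1" else "0"
    g <- gt[i, pheno$subject_id]
    al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    dosage[, j] <- vapply(al, function(x) {
      if (length(x) != 2L || any(x == ".")) return(NA_integer_)
      sum(x == risk_code)
    }, integer(1))
  }
  cd_cohort(pheno, panel, dosage)
}

#' Summarise a cohort's clinical covariates by disease site
#'
#' For each categorical covariate the summary reports counts and
#' integer percentages (half-up) per column: all CD subjects together,
#' then per site (L1, L3, L2).  Subjects with a missing value are listed
#' in a `missing` row and excluded from the percentage denominator.
#'
#' @param cohort A `cd_cohort`; only the CD subjects enter the summary.
#' @param covariates Covariate column names; default: every subject
#'   column other than the id/group/site labels.
#' @return Data frame with columns `covariate`, `category`, `group`,
#'   `count`, `percent` (NA for `missing` rows).
#' @export
cohort_summary <- function(cohort, covariates = NULL) {
  subj <- cohort$subjects[cohort$subjects$group == "CD", , drop = FALSE]
  if (nrow(subj) == 0L) stop("cohort has no CD subjects to summarise")
  if (is.null(covariates)) {
    covariates <- setdiff(names(subj), c("subject_id", "group", "site"))
  }
  groups <- list(all = rep(TRUE, nrow(subj)),
                 L1 = subj$site == "L1",
                 L3 = subj$site == "L3",
                 L2 = subj$site == "L2")
  out <- list()
  for (cv in covariates) {
    x <- as.character(subj[[cv]])
    cats <- unique(x[!is.na(x)])
    for (g in names(groups)) {
      xg <- x[groups[[g]]]
      n_known <- sum(!is.na(xg))
      for (cat_ in cats) {
        cnt <- sum(!is.na(xg) & xg == cat_)
        pct <- if (n_known > 0) floor(100 * cnt / n_known + 0.5) else NA
        out[[length(out) + 1L]] <- data.frame(
          covariate = cv, category = cat_, group = g,
          count = cnt, percent = pct, stringsAsFactors = FALSE)
      }
      n_miss <- sum(is.na(xg))
      if (n_miss > 0) {
        out[[length(out) + 1L]] <- data.frame(
          covariate = cv, category = "missing", group = g,
          count = n_miss, percent = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
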