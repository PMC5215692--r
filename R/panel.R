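#' SNP panel: load and validate
#'
#' A panel is a data frame with one row per SNP and columns `snp_id`,
#' `chrom_band`, `locus_id`, `gene_label`, `risk_allele`, `other_allele`.
#' The `locus_id` groups SNPs that share a susceptibility locus (e.g. the
#' four 5q31 SNPs) and is the denominator unit for the locus-level
#' Bonferroni correction.
#'
#' @param path Path to a tab-separated panel file with the six columns
#'   above in any order.
#' @return An object of class `snp_panel` (a validated data frame).
#' @details Alleles must be single bases in A/C/G/T and the risk and other
#'   allele must differ; duplicate `snp_id`s are rejected.  An empty body
#'   under a valid header yields an empty panel with a warning.
#' @seealso [cd_panel()] for the bundled 29-SNP Crohn's disease panel.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("snp_id", "chrom_band", "locus_id", "gene_label",
                "risk_allele", "other_allele")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("panel file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  if (nrow(df) == 0L) {
    warning("panel file ", path, " has a valid header but no entries")
    return(new_snp_panel(df))
  }
  bad_allele <- !(df$risk_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) {
    stop("malformed allele at line(s) ",
         paste(which(bad_allele) + 1L, collapse = ", "),
         " of ", path, " (alleles must be one of A/C/G/T)")
  }
  same <- df$risk_allele == df$other_allele
  if (any(same)) {
    stop("risk_allele equals other_allele at line(s) ",
         paste(which(same) + 1L, collapse = ", "), " of ", path)
  }
  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(df$snp_id[dup]), collapse = ", "))
  }
  new_snp_panel(df)
}

new_snp_panel <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' The bundled 29-SNP / 19-locus Crohn's disease panel
#'
#' Twenty-nine SNPs spanning 19 inflammatory-bowel-disease susceptibility
#' loci (IL23R, NOD2, IRGM, TNFSF15, the 5q31 cassette, three HLA-region
#' markers, ...).  Risk-allele orientation follows the published risk
#' allele frequencies; the allele letters themselves are conventional
#' labels for several SNPs whose exact base change is not carried by the
#' bundled metadata (the NOD2 frameshift rs2066847 is encoded C/G by
#' convention).
#'
#' @return An `snp_panel` with 29 rows and 19 distinct `locus_id`s.
#' @export
cd_panel <- function() {
  load_panel(system.file("extdata", "panel_cd29.tsv",
                         package = "crohnsite", mustWork = TRUE))
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "SNPs over",
      length(unique(x$locus_id)), "loci\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Encode a genotype call as a risk-allele dosage
#'
#' Converts diploid calls written `"X/Y"` into the number of risk-allele
#' copies: 0 (no copy), 1 (heterozygote) or 2 (risk homozygote), the
#' common 0/1/2 coding of case-control genetics.  The missing sentinel
#' `"./."` maps to `NA`.  Allele order is irrelevant: `"C/T"` and `"T/C"`
#' encode identically.
#'
#' @param call Character vector of genotype calls (`"A/G"`, `"./."`, ...).
#' @param risk_allele,other_allele Single bases defining the SNP.
#' @param snp_id,subject_id Optional labels used in error messages.
#' @return Integer vector of dosages in `{0, 1, 2, NA}`.
#' @export
encode_dosage <- function(call, risk_allele, other_allele,
                          snp_id = "?", subject_id = NULL) {
  out <- rep(NA_integer_, length(call))
  miss <- is.na(call) | call == "./." | call == "." | call == ""
  todo <- which(!miss)
  if (length(todo)) {
    parts <- strsplit(call[todo], "/", fixed = TRUE)
    bad_fmt <- lengths(parts) != 2L
    if (any(bad_fmt)) {
      stop("malformed genotype call ", call[todo][bad_fmt][1L],
           " for SNP ", snp_id, label_subject(subject_id, todo[bad_fmt][1L]))
    }
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, `[`, "", 2L)
    ok <- c(risk_allele, other_allele)
    bad <- !(a1 %in% ok) | !(a2 %in% ok)
    if (any(bad)) {
      stop("allele not in {", risk_allele, ",", other_allele,
           "} in call ", call[todo][bad][1L], " for SNP ", snp_id,
           label_subject(subject_id, todo[bad][1L]))
    }
    out[todo] <- (a1 == risk_allele) + (a2 == risk_allele)
  }
  out
}

label_subject <- function(subject_id, idx) {
  if (is.null(subject_id)) return("")
  paste0(" (subject ", subject_id[idx], ")")
}

#' Convert a printed risk-allele frequency to an allele count
#'
#' Reconstructs the risk-allele count out of `2 * n` chromosomes implied
#' by a (typically 2-decimal) printed frequency.  The result is the
#' nearest integer to `2 * n * raf` and is therefore approximate whenever
#' the original frequency was rounded for print.
#'
#' @param raf Risk-allele frequency in `[0, 1]`.
#' @param n_subjects Number of diploid subjects.
#' @return Integer count of risk alleles.
#' @export
raf_to_allele_counts <- function(raf, n_subjects) {
  stopifnot(all(raf >= 0 & raf <= 1), all(n_subjects >= 0))
  # half-up, so that ties never depend on banker's rounding
  as.integer(floor(2 * n_subjects * raf + 0.5))
}
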