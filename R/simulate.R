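#' Hardy-Weinberg genotype probabilities
#'
#' For a risk-allele frequency `p`, returns the Hardy-Weinberg genotype
#' distribution over dosages as `(P(2), P(1), P(0)) = (p^2, 2p(1-p),
#' (1-p)^2)`.
#'
#' @param p Risk-allele frequency in `[0, 1]`.
#' @return Named numeric vector `c(hom_risk, het, hom_other)` summing
#'   to 1.
#' @export
hwe_genotype_probs <- function(p) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  c(hom_risk = p^2, het = 2 * p * (1 - p), hom_other = (1 - p)^2)
}

#' Haplotype frequencies for a pair of loci at a target correlation
#'
#' Given marginal risk-allele frequencies `p_a`, `p_b` and a target
#' haplotype correlation `r`, returns the four haplotype frequencies
#' `(AB, Ab, aB, ab)` (capital = risk allele), i.e. a 2x2 distribution
#' with the requested marginals and `D = r * sqrt(p_a q_a p_b q_b)`.
#' The feasible range of `D` for the marginals is checked and an
#' infeasible `r` is rejected with the admissible interval in the error.
#'
#' @param p_a,p_b Risk-allele frequencies of the two loci.
#' @param target_r Haplotype correlation, `|r| <= 1`.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` summing to 1.
#' @export
pair_haplotype_freqs <- function(p_a, p_b, target_r) {
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1,
            abs(target_r) <= 1)
  q_a <- 1 - p_a
  q_b <- 1 - p_b
  denom <- sqrt(p_a * q_a * p_b * q_b)
  D <- target_r * denom
  d_min <- -min(p_a * p_b, q_a * q_b)
  d_max <- min(p_a * q_b, q_a * p_b)
  if (D < d_min - 1e-12 || D > d_max + 1e-12) {
    r_lo <- if (denom > 0) d_min / denom else 0
    r_hi <- if (denom > 0) d_max / denom else 0
    stop(sprintf(
      "target_r = %.4g infeasible for frequencies (%.3g, %.3g); feasible r in [%.4g, %.4g]",
      target_r, p_a, p_b, r_lo, r_hi))
  }
  out <- c(AB = p_a * p_b + D, Ab = p_a * q_b - D,
           aB = q_a * p_b - D, ab = q_a * q_b + D)
  pmax(out, 0) / sum(pmax(out, 0))
}

#' Simulation configuration for synthetic case-control cohorts
#'
#' Defines the cohort structure the association machinery assumes: group
#' sizes for controls and the three CD sites, per-SNP per-group
#' risk-allele frequencies, optional pairwise linkage disequilibrium
#' within locus blocks, and a per-SNP genotype dropout rate.  The
#' defaults reproduce the study conditions of the bundled panel: 537
#' controls and 708 CD patients (237 L1, 171 L2, 300 L3), with control
#' and all-CD risk-allele frequencies taken from the published allelic
#' table and applied to every site (the publication gives no per-site
#' frequencies; site contrasts therefore require explicit overrides).
#'
#' @param panel An `snp_panel` (default: the bundled 29-SNP panel).
#' @param group_sizes Named counts for `control`, `L1`, `L2`, `L3`.
#' @param raf Numeric matrix, SNPs x groups, with columns `control`,
#'   `L1`, `L2`, `L3` and rownames `panel$snp_id`; defaults to the
#'   published control/all-CD frequencies.
#' @param ld_pairs List of `list(snp_a=, snp_b=, r=)`; each pair must
#'   share a `locus_id`.
#' @param missing_rate Scalar or per-SNP dropout probability.
#' @param seed Master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(panel = cd_panel(),
                       group_sizes = c(control = 537, L1 = 237,
                                       L2 = 171, L3 = 300),
                       raf = NULL,
                       ld_pairs = list(),
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  groups <- c("control", "L1", "L2", "L3")
  stopifnot(all(groups %in% names(group_sizes)),
            all(group_sizes >= 0))
  group_sizes <- group_sizes[groups]
  if (is.null(raf)) {
    t2 <- cd_table_fixture("table2")
    idx <- match(panel$snp_id, t2$snp_id)
    if (anyNA(idx)) {
      stop("no default frequencies for SNP(s) outside the bundled panel; ",
           "supply raf explicitly")
    }
    raf <- cbind(control = t2$raf_control[idx], L1 = t2$raf_case[idx],
                 L2 = t2$raf_case[idx], L3 = t2$raf_case[idx])
    rownames(raf) <- panel$snp_id
  }
  raf <- as.matrix(raf)[, groups, drop = FALSE]
  stopifnot(identical(rownames(raf), panel$snp_id),
            all(raf >= 0 & raf <= 1))
  for (pair in ld_pairs) {
    stopifnot(all(c("snp_a", "snp_b", "r") %in% names(pair)))
    ia <- match(pair$snp_a, panel$snp_id)
    ib <- match(pair$snp_b, panel$snp_id)
    if (is.na(ia) || is.na(ib)) {
      stop("LD pair references SNP outside the panel: ",
           pair$snp_a, " / ", pair$snp_b)
    }
    if (panel$locus_id[ia] != panel$locus_id[ib]) {
      stop("LD pair ", pair$snp_a, " / ", pair$snp_b,
           " does not share a locus_id")
    }
    stopifnot(abs(pair$r) <= 1)
    # fail fast on infeasible r for any group's marginals
    for (g in groups) pair_haplotype_freqs(raf[ia, g], raf[ib, g], pair$r)
  }
  if (length(missing_rate) == 1L) {
    missing_rate <- rep(missing_rate, nrow(panel))
  }
  stopifnot(length(missing_rate) == nrow(panel),
            all(missing_rate >= 0 & missing_rate < 1))
  structure(list(panel = panel, group_sizes = group_sizes, raf = raf,
                 ld_pairs = ld_pairs, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-(group, item) stream seed below 2^31
stream_seed <- function(seed, group_idx, item_idx) {
  (as.double(seed) + 1000003 * group_idx + 7919 * item_idx) %%
    2147483629
}

#' Simulate a synthetic case-control cohort
#'
#' Draws genotypes group by group: independent SNPs as Hardy-Weinberg
#' multinomials at the group's risk-allele frequency, LD pairs as two
#' haplotypes per subject from [pair_haplotype_freqs()], then applies
#' per-SNP genotype dropout.  Each (group, SNP-or-pair) uses its own
#' PRNG stream derived from the master seed, so edits to one part of the
#' configuration do not perturb the rest, and the same configuration and
#' seed reproduce the cohort bit for bit.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the cohort is written
#'   in the genotype/phenotype TSV dialect plus a `truth.json` recording
#'   the generating frequencies, the implied allelic odds ratios, the
#'   realized frequencies and LD, and the seed.
#' @return A list with elements `cohort` (a `cd_cohort`) and `truth`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  groups <- names(config$group_sizes)
  n_snp <- nrow(panel)
  ld_snps <- unlist(lapply(config$ld_pairs,
                           function(p) c(p$snp_a, p$snp_b)))
  if (anyDuplicated(ld_snps)) {
    stop("a SNP may appear in at most one LD pair; chain blocks as ",
         "successive pairs over disjoint SNPs")
  }
  indep <- setdiff(panel$snp_id, ld_snps)

  blocks <- list()
  subj_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[g]]
    d <- matrix(NA_integer_, n, n_snp,
                dimnames = list(NULL, panel$snp_id))
    if (n > 0) {
      for (sid in indep) {
        j <- match(sid, panel$snp_id)
        set.seed(stream_seed(config$seed, gi, j))
        pr <- hwe_genotype_probs(config$raf[j, g])
        d[, j] <- sample(c(2L, 1L, 0L), n, replace = TRUE, prob = pr)
      }
      for (pi in seq_along(config$ld_pairs)) {
        pair <- config$ld_pairs[[pi]]
        ia <- match(pair$snp_a, panel$snp_id)
        ib <- match(pair$snp_b, panel$snp_id)
        set.seed(stream_seed(config$seed, gi, n_snp + pi))
        hf <- pair_haplotype_freqs(config$raf[ia, g], config$raf[ib, g],
                                   pair$r)
        h1 <- sample.int(4L, n, replace = TRUE, prob = hf)
        h2 <- sample.int(4L, n, replace = TRUE, prob = hf)
        d[, ia] <- (h1 <= 2L) + (h2 <= 2L)       # AB or Ab carries risk a
        d[, ib] <- (h1 %% 2L == 1L) + (h2 %% 2L == 1L)  # AB or aB
      }
      for (j in seq_len(n_snp)) {
        if (config$missing_rate[j] > 0) {
          set.seed(stream_seed(config$seed, gi, 2L * n_snp + j))
          drop <- stats::runif(n) < config$missing_rate[j]
          d[drop, j] <- NA_integer_
        }
      }
    }
    blocks[[g]] <- d
    subj_rows[[g]] <- data.frame(
      subject_id = if (n > 0) sprintf("%s_%04d", g, seq_len(n)) else character(0),
      group = rep(if (g == "control") "control" else "CD", n),
      site = rep(if (g == "control") "none" else g, n),
      stringsAsFactors = FALSE)
  }
  dosage <- do.call(rbind, blocks)
  subjects <- do.call(rbind, subj_rows)
  rownames(subjects) <- NULL
  cohort <- cd_cohort(subjects, panel, dosage)

  truth <- sim_truth(config, cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "genotypes.tsv"),
                 file.path(out_dir, "phenotypes.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, truth = truth)
}

sim_truth <- function(config, cohort) {
  groups <- names(config$group_sizes)
  snps <- rownames(config$raf)
  realized <- vapply(groups, function(g) {
    rows <- if (g == "control") cohort$subjects$site == "none"
            else cohort$subjects$site == g
    colMeans(cohort$dosage[rows, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(length(snps)))
  realized <- matrix(realized, nrow = length(snps),
                     dimnames = list(snps, groups))
  gen_or <- vapply(c("L1", "L2", "L3"), function(g) {
    p1 <- config$raf[, g]
    p0 <- config$raf[, "control"]
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }, numeric(length(snps)))
  gen_or <- matrix(gen_or, nrow = length(snps),
                   dimnames = list(snps, c("L1", "L2", "L3")))
  ld <- lapply(config$ld_pairs, function(pair) {
    da <- cohort$dosage[, pair$snp_a]
    db <- cohort$dosage[, pair$snp_b]
    ok <- !is.na(da) & !is.na(db)
    list(snp_a = pair$snp_a, snp_b = pair$snp_b, target_r = pair$r,
         realized_r = if (sum(ok) > 2) stats::cor(da[ok], db[ok]) else NA)
  })
  list(seed = config$seed,
       group_sizes = as.list(config$group_sizes),
       generating_raf = apply(config$raf, 2, function(x)
         stats::setNames(as.list(x), rownames(config$raf))),
       generating_allelic_or = apply(gen_or, 2, function(x)
         stats::setNames(as.list(x), rownames(config$raf))),
       realized_raf = apply(realized, 2, function(x)
         stats::setNames(as.list(x), rownames(config$raf))),
       ld_pairs = ld,
       missing_rate = as.list(stats::setNames(config$missing_rate,
                                              config$panel$snp_id)))
}
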