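# shared fixture builders: everything constructed in code at test time

toy_panel <- function(n = 2L, locus = NULL) {
  if (is.null(locus)) locus <- paste0("loc", seq_len(n))
  df <- data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom_band = locus, locus_id = locus,
    gene_label = paste0("GENE", seq_len(n)),
    risk_allele = rep(c("T", "C", "A", "G"), length.out = n),
    other_allele = rep(c("C", "G", "G", "A"), length.out = n),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_panel(path)
}

toy_cohort <- function(dosage, sites = NULL, panel = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(panel)) panel <- toy_panel(ncol(dosage))
  colnames(dosage) <- panel$snp_id
  if (is.null(sites)) sites <- rep(c("none", "L1"), length.out = n)
  subjects <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = ifelse(sites == "none", "control", "CD"),
    site = sites, stringsAsFactors = FALSE)
  cd_cohort(subjects, panel, dosage)
}

# independent textbook Pearson chi-square on a 2x2, no continuity correction
oracle_pearson_p <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, c, b, d), 2L)
  chi2 <- sum((o - e)^2 / e)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # col 1 total
  n2 <- c + d
  x <- max(0, k - n2):min(m, k)
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# binomial log-likelihood for the optim-based logistic oracle
oracle_loglik <- function(beta, X, y) {
  eta <- X %*% beta
  sum(y * eta - log1p(exp(eta)))
}

oracle_logistic_loglik <- function(design, outcome) {
  X <- cbind(1, as.matrix(design))
  fit <- optim(rep(0, ncol(X)), fn = oracle_loglik, X = X, y = outcome,
               method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  fit$value
}

# exhaustive admissible-subset selection under the same LRT thresholds:
# every included term must stay (drop-one p <= p_stay) and no excluded
# term may enter (add-one p >= p_enter); pick max log-likelihood, then
# fewest terms, then lexicographic
oracle_best_subset <- function(candidates, outcome, p_enter = 0.05,
                               p_stay = 0.05) {
  terms <- colnames(candidates)
  subsets <- unlist(lapply(0:length(terms), function(k)
    combn(terms, k, simplify = FALSE)), recursive = FALSE)
  fit_of <- function(s) fit_logistic(candidates[, s, drop = FALSE], outcome)
  admissible <- list()
  for (s in subsets) {
    f <- fit_of(s)
    ok <- TRUE
    for (t in s) {
      p <- likelihood_ratio_test(fit_of(setdiff(s, t)), f)$p_value
      if (p > p_stay) { ok <- FALSE; break }
    }
    if (ok) for (t in setdiff(terms, s)) {
      p <- likelihood_ratio_test(f, fit_of(c(s, t)))$p_value
      if (p < p_enter) { ok <- FALSE; break }
    }
    if (ok) admissible[[length(admissible) + 1L]] <-
        list(terms = s, loglik = f$loglik)
  }
  ll <- vapply(admissible, `[[`, numeric(1), "loglik")
  sz <- vapply(admissible, function(x) length(x$terms), integer(1))
  key <- vapply(admissible, function(x)
    paste(sort(x$terms), collapse = ","), character(1))
  admissible[[order(-ll, sz, key)[1L]]]$terms
}
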