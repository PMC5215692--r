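#' Run the full site-stratified analysis pipeline
#'
#' Orchestrates one reproducible run: obtain a cohort (load it from
#' genotype/phenotype files or simulate one), screen Hardy-Weinberg,
#' run the association battery over the requested comparisons, fit
#' forward-stepwise models on the Bonferroni survivors of each
#' versus-control comparison (the composite NOD2 indicator replacing its
#' member SNPs), screen gene-gene interactions, and evaluate weighted
#' and allele-count genetic risk scores by ROC/AUC.  All tables are
#' written as TSV plus a `manifest.json` (seed, configuration echo,
#' package version); the same configuration and seed give a byte-identical
#' bundle.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `panel` (path, optional — default bundled panel), either
#'   `genotypes` + `phenotypes` (paths) or `simulate` (a list of
#'   [sim_config()] arguments), `comparisons` (default all seven),
#'   `alpha` (0.05), `n_loci` (panel loci), `p_enter` (0.05), `p_remove`
#'   (0.10), `grs_comparison` (`"CD_vs_ctrl"`), `seed`.
#' @param out_dir Output directory for the bundle.
#' @return Invisibly, a list with the computed objects (`cohort`,
#'   `hwe`, `assoc`, `stepwise`, `interactions`, `grs`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(comparisons = cd_comparisons(), alpha = 0.05,
                   p_enter = 0.05, p_remove = 0.10,
                   grs_comparison = "CD_vs_ctrl", seed = 1L)
  config <- utils::modifyList(defaults, config)

  panel <- if (!is.null(config$panel)) {
    if (!file.exists(config$panel)) {
      stop("panel file not found: ", config$panel)
    }
    load_panel(config$panel)
  } else cd_panel()
  if (is.null(config$n_loci)) {
    config$n_loci <- length(unique(panel$locus_id))
  }

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$panel <- panel
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$group_sizes)) {
      sim_args$group_sizes <- unlist(sim_args$group_sizes)
    }
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    for (key in c("genotypes", "phenotypes")) {
      if (is.null(config[[key]])) {
        stop("config needs either `simulate` or `genotypes`+`phenotypes`")
      }
      if (!file.exists(config[[key]])) {
        stop(key, " file not found: ", config[[key]])
      }
    }
    cohort <- load_cohort(config$genotypes, config$phenotypes, panel,
                          quiet = TRUE)
    truth <- NULL
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hwe <- hwe_by_group(cohort)
  assoc <- run_comparisons(cohort, comparisons = config$comparisons,
                           alpha = config$alpha, n_loci = config$n_loci)

  steps <- list()
  inter <- list()
  for (cmp in intersect(config$comparisons,
                        c("L1_vs_ctrl", "L2_vs_ctrl", "L3_vs_ctrl",
                          "CD_vs_ctrl"))) {
    sub <- assoc[assoc$comparison == cmp & assoc$model == "carrier" &
                   assoc$bonferroni_significant, , drop = FALSE]
    cand <- unique(sub$marker_id)
    if ("NOD2_any" %in% cand) cand <- setdiff(cand, nod2_snps())
    if (!length(cand)) next
    dm <- stepwise_design(cohort, cmp, cand)
    path <- forward_stepwise(dm$design, dm$outcome,
                             p_enter = config$p_enter,
                             p_remove = config$p_remove)
    steps[[cmp]] <- path
    if (length(path$selected) >= 2L) {
      inter[[cmp]] <- interaction_screen(
        dm$design[, path$selected, drop = FALSE], dm$outcome,
        alpha = config$alpha)
    }
  }

  grs_res <- list()
  for (mode in c("weighted", "allele_count")) {
    model <- build_weights(assoc, mode = mode,
                           comparison = config$grs_comparison)
    if (nrow(model$entries) == 0L) {
      message("GRS (", mode, ") skipped: no significant markers")
      next
    }
    scores <- score_subjects(cohort, model)
    sel <- comparison_groups(config$grs_comparison)
    roc <- roc_auc(scores[select_group(cohort, sel[1L])],
                   scores[select_group(cohort, sel[2L])])
    cut <- optimal_cutoff(roc)
    grs_res[[mode]] <- list(model = model, roc = roc, cutoff = cut)
  }

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(hwe, "hwe.tsv")
  for (cmp in unique(assoc$comparison)) {
    write_tsv(assoc[assoc$comparison == cmp, , drop = FALSE],
              paste0("assoc_", cmp, ".tsv"))
  }
  for (cmp in names(steps)) {
    write_tsv(steps[[cmp]]$log, paste0("stepwise_", cmp, "_path.tsv"))
    fit <- steps[[cmp]]$final_fit
    if (!is.null(fit)) {
      write_tsv(data.frame(term = names(fit$coefficients),
                           coef = fit$coefficients, se = fit$se,
                           or = fit$or, ci_low = fit$or_ci_low,
                           ci_high = fit$or_ci_high),
                paste0("stepwise_", cmp, "_model.tsv"))
    }
    if (!is.null(inter[[cmp]]) && nrow(inter[[cmp]])) {
      write_tsv(inter[[cmp]], paste0("interactions_", cmp, ".tsv"))
    }
  }
  for (mode in names(grs_res)) {
    g <- grs_res[[mode]]
    write_tsv(g$roc$sweep, paste0("grs_", mode, "_roc.tsv"))
    write_tsv(data.frame(mode = mode, comparison = config$grs_comparison,
                         auc = g$roc$auc, auc_p = g$roc$auc_p_value,
                         cutoff = g$cutoff$cutoff,
                         sensitivity = g$cutoff$sensitivity,
                         specificity = g$cutoff$specificity,
                         n_markers = nrow(g$model$entries)),
              paste0("grs_", mode, "_summary.tsv"))
    write_tsv(g$model$entries, paste0("grs_", mode, "_weights.tsv"))
  }
  manifest <- list(
    package = "crohnsite",
    version = as.character(utils::packageVersion("crohnsite")),
    seed = config$seed,
    n_subjects = nrow(cohort$subjects),
    n_snps = nrow(cohort$panel),
    comparisons = config$comparisons,
    alpha = config$alpha, n_loci = config$n_loci,
    p_enter = config$p_enter, p_remove = config$p_remove,
    grs_comparison = config$grs_comparison,
    config = config[setdiff(names(config), "panel_object")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cohort = cohort, hwe = hwe, assoc = assoc,
                 stepwise = steps, interactions = inter, grs = grs_res,
                 manifest = manifest, out_dir = out_dir))
}

#' Render a human-readable summary of a pipeline bundle
#'
#' Produces a plain-text report from an existing output bundle: per
#' comparison, the number of nominally significant markers (SNP rows,
#' and with the composite counted) and the Bonferroni survivors; then
#' the stepwise selections and the GRS AUC table.  Rendering only reads
#' bundle files — every number it shows is traceable to a TSV in the
#' bundle.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", out_dir, "; incomplete bundle")
  }
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(sprintf("crohnsite run (seed %s): %s subjects x %s SNPs",
                     manifest$seed, manifest$n_subjects, manifest$n_snps))
  bonf <- bonferroni_threshold(manifest$alpha, manifest$n_loci)
  lines <- c(lines, sprintf("alpha = %g; Bonferroni threshold = %.2g (%d loci)",
                            manifest$alpha, bonf, manifest$n_loci))
  for (cmp in unlist(manifest$comparisons)) {
    f <- file.path(out_dir, paste0("assoc_", cmp, ".tsv"))
    if (!file.exists(f)) {
      lines <- c(lines, sprintf("%-12s : [missing from bundle]", cmp))
      next
    }
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    n_snp <- tally_significant(tab, cmp, manifest$alpha)
    n_all <- tally_significant(tab, cmp, manifest$alpha,
                               include_composite = TRUE)
    surv <- unique(tab$marker_id[tab$bonferroni_significant])
    lines <- c(lines, sprintf(
      "%-12s : %d significant SNPs (%d incl. composite); Bonferroni survivors: %s",
      cmp, n_snp, n_all,
      if (length(surv)) paste(surv, collapse = ", ") else "none"))
  }
  step_files <- list.files(out_dir, "^stepwise_.*_model\\.tsv$")
  for (f in step_files) {
    cmp <- sub("^stepwise_(.*)_model\\.tsv$", "\\1", f)
    tab <- utils::read.delim(file.path(out_dir, f))
    terms <- setdiff(tab$term, "(Intercept)")
    lines <- c(lines, sprintf("stepwise %-10s: %s", cmp,
                              paste(terms, collapse = ", ")))
  }
  grs_lines <- character(0)
  for (mode in c("weighted", "allele_count")) {
    f <- file.path(out_dir, paste0("grs_", mode, "_summary.tsv"))
    if (!file.exists(f)) {
      grs_lines <- c(grs_lines, sprintf("GRS %-12s: [skipped]", mode))
      next
    }
    tab <- utils::read.delim(file.path(f))
    grs_lines <- c(grs_lines, sprintf(
      "GRS %-12s: AUC = %.3f (p = %.2g), cutoff %.2f (sens %.2f, spec %.2f)",
      mode, tab$auc, tab$auc_p, tab$cutoff, tab$sensitivity,
      tab$specificity))
  }
  lines <- c(lines, grs_lines)
  cat(lines, sep = "\n")
  invisible(lines)
}
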