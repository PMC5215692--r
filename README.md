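# crohnsite

Site-stratified case-control SNP association and genetic risk scores for
Crohn's disease (CD).

Crohn's disease location — ileal (Montreal L1), colonic (L2), ileocolonic
(L3) — is one of its most stable clinical features, and the question of
whether the three sites are genetically distinct entities is usually
attacked with exactly the battery this package implements:

* **Association**: per-SNP allelic (risk vs other allele, 2 chromosomes per
  subject) and carrier (dosage ≥ 1 vs 0) 2×2 tests across seven strata
  (all CD and each site vs controls; the three site-vs-site contrasts).
  Pearson χ² without continuity correction, two-sided Fisher exact
  whenever an expected cell is < 5; odds ratios with Woolf 95% CIs
  (`exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`), Haldane–Anscombe 0.5 on zero
  cells; Hardy–Weinberg screening; locus-level Bonferroni (`α/19` for the
  bundled 29-SNP/19-locus panel, i.e. 2.6e-3).
* **Composite markers**: e.g. "at least one NOD2 risk genotype" over
  rs2066844 / rs2066845 / rs2066847.
* **Stepwise modelling**: forward stepwise logistic regression
  (likelihood-ratio criterion, `p_enter = 0.05`, `p_remove = 0.10`) on the
  Bonferroni survivors, with pairwise gene–gene interaction screening.
* **Genetic risk score**: weighted (`Σ oriented dosage × ln OR`) or
  allele-count GRS with all weights oriented non-negative, evaluated by
  ROC; AUC via the Mann–Whitney identity (ties half-counted, verified
  against trapezoidal integration), tie-corrected normal AUC p-value,
  Youden cutoff.
* **Synthetic cohorts**: Hardy–Weinberg genotypes at group-specific
  risk-allele frequencies, optional pairwise LD within locus blocks,
  genotype dropout, per-stream seeding — bit-reproducible, with a
  ground-truth file for recovery testing.  Defaults reproduce the bundled
  study conditions: 537 controls, 708 CD (237 L1, 171 L2, 300 L3), with
  the published risk-allele frequencies.

The published summary tables (clinical characteristics, allelic
case-control results, per-site genotype results) ship as plain-text
fixtures for tally and reporting operations; the underlying patient
genotypes were never deposited, so those cells are data, not
recomputation targets.

## Worked example

```r
library(crohnsite)

sim <- simulate_cohort(sim_config(seed = 1))   # study-sized synthetic cohort
sim$cohort
#> Case-control cohort: 1245 subjects x 29 SNPs
#>   controls: 537  L1: 237  L2: 171  L3: 300

tab <- run_comparisons(sim$cohort, comparisons = c("CD_vs_ctrl", "L1_vs_ctrl"))
sub <- tab[tab$comparison == "L1_vs_ctrl" & tab$model == "carrier" &
           tab$marker_id %in% c(nod2_snps(), "NOD2_any"), ]
sub[, c("marker_id", "a", "b", "c", "d", "p_value", "or_value", "ci_low", "ci_high")]
#>     marker_id  a   b  c   d  p_value or_value ci_low ci_high
#> 107 rs2066844 40 197 45 492 4.92e-04     2.22  1.406    3.51
#> 109 rs2066845 31 206 12 525 1.27e-09     6.58  3.317   13.07
#> 111 rs2066847 20 217 27 510 6.70e-02     1.74  0.956    3.17
#> 118  NOD2_any 85 152 77 460 1.16e-11     3.34  2.334    4.78
```

Each row is one 2×2 carrier test of ileal cases against controls: `a`/`b`
are carrier/non-carrier cases, `c`/`d` controls; the composite `NOD2_any`
row shows the familiar pattern that carrying *any* NOD2 risk genotype is a
stronger ileal signal than most single variants (here OR 3.3, p ≈ 1e-11 on
simulated data whose generating frequencies are the published ones).

```r
w <- build_weights(tab)                   # ln(OR) weights, all oriented >= 0
scores <- score_subjects(sim$cohort, w)
is_case <- sim$cohort$subjects$group == "CD"
roc <- roc_auc(scores[is_case], scores[!is_case])
roc
#> ROC: 708 cases vs 537 controls; AUC = 0.7628 (p = 6.33e-57)
optimal_cutoff(roc)
#> $cutoff      7.171263
#> $sensitivity 0.5918079
#> $specificity 0.8044693
#> $youden      0.3962772
```

The weighted GRS separates simulated cases from controls with AUC ≈ 0.76:
each subject's score sums risk-oriented allele copies weighted by the
cohort's own log odds ratios, and the Youden cutoff is the score threshold
maximizing sensitivity + specificity − 1.

One-shot runs with a config file (simulate → associate → stepwise → GRS,
all outputs as TSV plus a manifest):

```r
run_pipeline(list(simulate = list(), seed = 1), "out/")
render_report("out/")
```

or from a shell via `inst/scripts/run_pipeline.R`.

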