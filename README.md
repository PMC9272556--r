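# spatimmune

Quantifying the tumor immune microenvironment from multiplex
immunohistochemistry (m-IHC) per-cell exports, for analysts studying how
immune context differs between patient groups — here, gastric cancers
stratified by CLDN18.2 (claudin-18 isoform 2) positivity, the eligibility
marker for anti-CLDN18.2 therapy.

Starting from one CSV row per segmented cell (nucleus centroid in μm, cell
class, ordinal 0–3 marker intensities), the package:

- assigns **immune subtypes** with boolean marker-combination gates
  (multi-label, so CD8⁺ ⊃ CD8⁺PD-1⁻ counts stay nested);
- calls **patient-level CLDN18.2 status** by the clinical-trial rule —
  membrane intensity ≥ 2+ in ≥ 40% of tumor cells, pooled over the
  patient's tumor-core fields;
- computes **cell-type rates** (gated cells / all cells per field) and
  fixed-radius **spatial statistics** on the bipartite tumor–immune pairing
  graph at r = 20 μm:

  ```
  effective score   =  #edges / #central tumor cells
  effective percent =  #central tumor cells with ≥1 edge / #central tumor cells
  ```

  i.e. the mean number of immune neighbors per tumor cell, and the fraction
  of tumor cells with at least one immune neighbor within r;
- compares groups with two-tailed t-tests (Welch default), one-way ANOVA,
  Pearson correlation, and rank-based ROC-AUC; filters expression cohorts by
  percent-spliced-in (PSI > 0.9);
- runs survival analyses per endpoint (OS, irOS, irPFS): Kaplan–Meier
  curves, Mantel–Cox log-rank, and a single-covariate Cox hazard ratio;
- ships a seedable **synthetic cohort generator** that emulates the study
  design (two groups × 40 patients, 930 × 700 μm fields, planted rate and
  spatial-attraction differences, exponential survival), so the whole
  pipeline is testable without patient data.

Everything is tibble-in / tibble-out and chains with the pipe; fitted
survival objects have `tidy()` / `glance()` methods and results have ggplot2
helpers (`plot_roi()`, `plot_km()`, `autoplot()` on neighbor graphs).

## Worked example

A 12-cell hand-placed field (4 tumor cells with CLDN18.2 intensities
3/2/1/0, six CD8 T cells of which one PD-1⁺, one CD4 T cell, one other):

```r
library(spatimmune)
library(dplyr)

roi   <- generate_worked_roi()
panel <- default_gc_panel()

classify_cldn_status(roi, panel)
#> # A tibble: 1 × 4
#>   patient_id n_tumor cldn_proportion cldn_status
#>   <chr>        <int>           <dbl> <chr>
#> 1 PW1              4             0.5 positive

spatial_metrics(roi, panel = panel) %>%
  filter(phenotype %in% c("CD8+", "CD8+PD-1-")) %>%
  select(phenotype, n_central, n_peripheral, n_edges,
         effective_score, effective_percent)
#> # A tibble: 2 × 6
#>   phenotype n_central n_peripheral n_edges effective_score effective_percent
#>   <chr>         <int>        <int>   <int>           <dbl>             <dbl>
#> 1 CD8+              4            6       5            1.25              0.75
#> 2 CD8+PD-1-         4            5       4            1                 0.75
```

Two of the four tumor cells stain ≥ 2+, so the patient is CLDN18.2-positive
at the 40% cutoff; the five tumor–CD8⁺ pairs within 20 μm spread over three
of the four tumor cells, giving score 5/4 and percent 3/4 (one pair sits at
exactly 20 μm — the boundary is inclusive).

On a synthetic cohort, the pipeline detects the planted group differences
end to end:

```r
cohort <- generate_cohort(sim_config(n_per_group = 10, rois_per_patient = 2),
                          seed = 42)
res <- run_pipeline(cohort$cells, cohort$patients, out_dir = "reports",
                    seed = 42)
res$comparisons %>%
  filter(region == "TC", phenotype == "CD8+PD-1-") %>%
  select(metric, mean_a, mean_b, statistic, p_value)
#> # A tibble: 3 × 5
#>   metric            mean_a mean_b statistic  p_value
#>   <chr>              <dbl>  <dbl>     <dbl>    <dbl>
#> 1 effective_percent 0.107  0.175     -12.1  7.25e-10
#> 2 effective_score   0.112  0.193     -12.7  4.70e-10
#> 3 rate              0.0270 0.0406     -9.79 1.31e- 8
```

Group `a` is CLDN18.2-negative, `b` positive: the positive group carries a
higher CD8⁺PD-1⁻ rate (0.041 vs 0.027) and more CD8⁺PD-1⁻ cells in contact
range of tumor cells, the planted (and study-scale) effect.
`run_pipeline()` writes `rates.csv`, `spatial_metrics.csv`,
`patient_metrics.csv`, `comparisons.csv`, `correlations.csv`,
`survival.csv` and a `manifest.json` that fully determines the run.

A thin CLI over the same functions lives at `inst/cli/spatimmune.R`
(`simulate`, `fixtures`, `phenotype`, `spatial`, `stats`, `survival`,
`run`).

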