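#' Run the full m-IHC quantification pipeline
#'
#' Orchestrates phenotyping, CLDN18.2 calling, per-field rates, 20-micrometer
#' spatial metrics, per-patient aggregation, two-group comparisons of every
#' phenotype's rate / effective score / effective percent, correlations of
#' each phenotype rate with the CLDN18.2-expressing tumor fraction, ROC-AUC
#' of that fraction against immunotherapy response, and per-endpoint
#' survival comparisons. Invasion-margin (IM) fields are kept in the input
#' schema but excluded from the quantitative reports.
#'
#' Writes seven files to `out_dir`: `rates.csv`, `spatial_metrics.csv`,
#' `patient_metrics.csv`, `comparisons.csv`, `correlations.csv`,
#' `survival.csv` and `manifest.json`. Outputs are a pure function of the
#' inputs and options, so reruns are byte-identical. On error, files already
#' written by the failing run are removed.
#'
#' @param cells A validated cell tibble, or a path to a cell-table CSV.
#' @param patients A patient tibble, or a path to a patient-table CSV.
#' @param panel An `si_panel`, or a path to a panel config; defaults to
#'   [default_gc_panel()].
#' @param out_dir Output directory, created if needed.
#' @param radius Pairing radius in micrometers.
#' @param agg Per-patient aggregation over fields: `"mean"` or `"pooled"`.
#' @param ttest `"welch"` or `"pooled"`.
#' @param alpha Two-tailed significance level used to flag comparisons.
#' @param group_var Patient grouping column; when `"cldn_status"` and the
#'   patient table lacks it, the status is called from the cells.
#' @param seed Recorded in the manifest (the pipeline itself draws no random
#'   numbers; the seed documents the provenance of simulated inputs).
#' @return Invisibly, a list of the report tables and the manifest.
#' @export
run_pipeline <- function(cells, patients, panel = default_gc_panel(),
                         out_dir, radius = 20,
                         agg = c("mean", "pooled"),
                         ttest = c("welch", "pooled"),
                         alpha = 0.05, group_var = "cldn_status",
                         seed = NULL) {
  agg <- match.arg(agg); ttest <- match.arg(ttest)
  if (radius <= 0) abort("radius must be > 0")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (is.character(panel)) panel <- read_panel_config(panel)
  if (is.character(cells)) cells <- read_cell_table(cells, panel = panel)
  if (is.character(patients)) patients <- read_patient_table(patients)

  written <- character(0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    p <- file.path(out_dir, name)
    write_report_table(tbl, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  tryCatch({
    stage <- "phenotyping"
    labels <- assign_phenotypes(cells, panel)

    stage <- "CLDN18.2 call"
    cldn <- classify_cldn_status(cells, panel, region = "TC")
    patients <- patients %>%
      left_join(cldn %>% select("patient_id", "cldn_proportion", "cldn_status"),
                by = "patient_id")
    if (group_var == "cldn_status" && "cldn_status.x" %in% names(patients)) {
      # table-supplied status wins when present; computed fills the gaps
      patients <- patients %>%
        mutate(cldn_status = dplyr::coalesce(.data$cldn_status.x, .data$cldn_status.y)) %>%
        select(-"cldn_status.x", -"cldn_status.y")
    }

    stage <- "rates"
    analysed <- cells %>% filter(.data$region %in% c("TC", "N"))
    rates <- phenotype_rates(analysed, labels = labels)
    emit(rates, "rates.csv")

    stage <- "spatial metrics"
    spat <- suppressWarnings(spatial_metrics(analysed, labels = labels, radius = radius))
    emit(spat, "spatial_metrics.csv")

    stage <- "patient aggregation"
    pat_tbl <- bind_rows(lapply(intersect(c("TC", "N"), unique(analysed$region)),
      function(reg) {
        pr <- patient_rates(rates, region = reg, mode = agg)
        ps <- patient_spatial(spat, region = reg, mode = agg)
        pr %>%
          left_join(ps %>% select(-"n_rois"),
                    by = c("patient_id", "region", "phenotype"))
      }))
    emit(pat_tbl, "patient_metrics.csv")

    stage <- "group comparisons"
    grp <- patients %>% select("patient_id", group = dplyr::all_of(group_var))
    long <- pat_tbl %>%
      left_join(grp, by = "patient_id") %>%
      filter(!is.na(.data$group)) %>%
      tidyr::pivot_longer(c("rate", "effective_score", "effective_percent"),
                          names_to = "metric", values_to = "value")
    glv <- sort(unique(long$group))
    comparisons <- long %>%
      group_by(.data$region, .data$phenotype, .data$metric) %>%
      dplyr::group_modify(function(d, key) {
        a <- d$value[d$group == glv[1]]
        b <- d$value[d$group == glv[2]]
        if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return(tibble())
        compare_groups(a, b, mode = ttest, group_a = glv[1], group_b = glv[2])
      }) %>%
      ungroup() %>%
      mutate(significant = .data$p_value < alpha)
    emit(comparisons, "comparisons.csv")

    stage <- "correlations"
    tc_rates <- pat_tbl %>%
      filter(.data$region == "TC") %>%
      left_join(patients %>% select("patient_id", "cldn_proportion"),
                by = "patient_id")
    correlations <- tc_rates %>%
      group_by(.data$phenotype) %>%
      dplyr::group_modify(function(d, key) {
        ok <- !is.na(d$rate) & !is.na(d$cldn_proportion)
        if (sum(ok) < 3L || stats::sd(d$rate[ok]) == 0 ||
            stats::sd(d$cldn_proportion[ok]) == 0) return(tibble())
        pearson_corr(d$cldn_proportion, d$rate)
      }) %>%
      ungroup() %>%
      mutate(against = "cldn_proportion", .before = 1)
    emit(correlations, "correlations.csv")

    stage <- "response AUC"
    auc <- NA_real_
    if ("response" %in% names(patients)) {
      resp <- patients %>% filter(!is.na(.data$response), !is.na(.data$cldn_proportion))
      if (nrow(resp) >= 4L && dplyr::n_distinct(resp$response) == 2L) {
        auc <- roc_auc(resp$cldn_proportion, resp$response == "responder")
      }
    }

    stage <- "survival"
    surv <- survival_report(patients, group_var = group_var)
    emit(surv$summary, "survival.csv")

    stage <- "manifest"
    manifest <- list(
      package = "spatimmune",
      version = as.character(utils::packageVersion("spatimmune")),
      r_version = R.version.string,
      options = list(radius = radius, agg = agg, ttest = ttest, alpha = alpha,
                     group_var = group_var, seed = seed),
      inputs = list(n_cells = nrow(cells), n_patients = nrow(patients),
                    n_rois = dplyr::n_distinct(cells$roi_id),
                    markers = panel$markers,
                    phenotypes = names(panel$phenotypes)),
      results = list(
        n_group = as.list(table(patients[[group_var]])),
        auc_response_vs_cldn_proportion = auc
      )
    )
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mp)

    invisible(list(
      rates = rates, spatial = spat, patient_metrics = pat_tbl,
      comparisons = comparisons, correlations = correlations,
      survival = surv$summary, km_curves = surv$curves,
      auc_response = auc, patients = patients, manifest = manifest,
      files = written
    ))
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
}
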