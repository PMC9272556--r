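#' Assign marker-combination phenotypes to cells
#'
#' Evaluates every phenotype gate in the panel against every cell.
#' Assignment is multi-label: a cell receives every phenotype whose rule it
#' satisfies (a CD8+PD-1- cell is also CD8+), and a cell satisfying no rule
#' carries all-FALSE. Evaluation is per-cell, so it is idempotent and
#' independent of row order.
#'
#' @param cells A validated cell tibble (see [read_cell_table()]).
#' @param panel An `si_panel`.
#' @return A tibble with `cell_id`, `roi_id` and one logical column per
#'   phenotype, rows aligned with `cells`.
#' @export
assign_phenotypes <- function(cells, panel) {
  stopifnot(inherits(panel, "si_panel"))
  used <- unique(unlist(lapply(panel$phenotypes, function(p) {
    c(names(p$positive), names(p$negative))
  })))
  absent <- setdiff(used, names(cells))
  if (length(absent) > 0L) {
    abort(sprintf("cells lack marker column(s) referenced by the panel: %s",
                  paste(absent, collapse = ", ")))
  }
  out <- cells %>% select("cell_id", "roi_id")
  for (p in panel$phenotypes) {
    hit <- rep(TRUE, nrow(cells))
    if (p$cell_class != "any") hit <- cells$cell_class == p$cell_class
    for (m in names(p$positive)) hit <- hit & cells[[m]] >= p$positive[[m]]
    for (m in names(p$negative)) hit <- hit & cells[[m]] <= p$negative[[m]]
    out[[p$name]] <- hit
  }
  out
}

#' Call per-patient CLDN18.2 status
#'
#' Pools a patient's tumor cells over all their fields of one region
#' (tumor core by default) and computes the fraction with CLDN18.2 membrane
#' intensity at or above the panel's intensity cutoff. A patient is positive
#' when that fraction is at or above the proportion cutoff; with the default
#' panel this is the clinical-trial rule of >= 2+ staining in >= 40% of
#' tumor cells. For tumor-adjacent normal tissue (`region = "N"`), the same
#' rule is applied to the epithelial cells of the N fields, which the cell
#' table flags with `cell_class = "tumor"`.
#'
#' @param cells A validated cell tibble.
#' @param panel An `si_panel`.
#' @param region Region whose tumor/epithelial cells are pooled.
#' @return One row per patient: `patient_id`, `n_tumor`, `cldn_proportion`,
#'   `cldn_status` ("positive"/"negative").
#' @export
classify_cldn_status <- function(cells, panel, region = "TC") {
  stopifnot(inherits(panel, "si_panel"))
  mk <- panel$cldn_marker
  if (!mk %in% names(cells)) {
    abort(sprintf("cells lack the CLDN18.2 marker column '%s'", mk))
  }
  tum <- cells %>%
    filter(.data$region == !!region, .data$cell_class == "tumor")
  pts <- unique(cells$patient_id[cells$region == region])
  empty <- setdiff(pts, unique(tum$patient_id))
  if (length(empty) > 0L) {
    abort(sprintf("no tumor cells for CLDN18.2 call: patient %s, region %s",
                  empty[1], region))
  }
  tum %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_tumor = n(),
      cldn_proportion = mean(.data[[mk]] >= panel$cldn_intensity_cutoff),
      .groups = "drop"
    ) %>%
    mutate(cldn_status = ifelse(
      .data$cldn_proportion >= panel$cldn_proportion_cutoff,
      "positive", "negative"
    ))
}

#' Per-field cell-type rates
#'
#' The rate of a phenotype in a field is the number of cells carrying the
#' phenotype divided by the total number of cells in the field (all classes).
#'
#' @param cells A validated cell tibble.
#' @param labels Phenotype assignments from [assign_phenotypes()]; computed
#'   from `panel` when omitted.
#' @param panel An `si_panel`, required when `labels` is missing.
#' @return A tibble with one row per ROI x phenotype: `roi_id`,
#'   `patient_id`, `region`, `phenotype`, `n_cells`, `n_positive`, `rate`.
#' @export
phenotype_rates <- function(cells, labels = NULL, panel = NULL) {
  if (is.null(labels)) {
    if (is.null(panel)) abort("supply `labels` or `panel`")
    labels <- assign_phenotypes(cells, panel)
  }
  if (nrow(cells) == 0L) abort("empty cell table: rates undefined")
  phen_cols <- setdiff(names(labels), c("cell_id", "roi_id"))
  meta <- cells %>% select("cell_id", "roi_id", "patient_id", "region")
  labels %>%
    left_join(meta, by = c("cell_id", "roi_id")) %>%
    tidyr::pivot_longer(dplyr::all_of(phen_cols),
                        names_to = "phenotype", values_to = "hit") %>%
    group_by(.data$roi_id, .data$patient_id, .data$region, .data$phenotype) %>%
    summarise(
      n_cells = n(),
      n_positive = sum(.data$hit),
      rate = .data$n_positive / .data$n_cells,
      .groups = "drop"
    )
}

#' Aggregate per-field rates to one value per patient
#'
#' `"mean"` (default) averages the per-field rates of the patient's fields
#' in the region with equal weight; `"pooled"` divides total phenotype cells
#' by total cells over those fields, weighting fields by cellularity.
#'
#' @param rates Output of [phenotype_rates()].
#' @param region Region to aggregate within (`"TC"` or `"N"`).
#' @param mode `"mean"` or `"pooled"`.
#' @return One row per patient x phenotype: `patient_id`, `region`,
#'   `phenotype`, `n_rois`, `rate`.
#' @export
patient_rates <- function(rates, region = "TC", mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  r <- rates %>% filter(.data$region == !!region)
  r %>%
    group_by(.data$patient_id, .data$region, .data$phenotype) %>%
    summarise(
      n_rois = n(),
      rate = if (mode == "mean") mean(.data$rate)
             else sum(.data$n_positive) / sum(.data$n_cells),
      .groups = "drop"
    )
}
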