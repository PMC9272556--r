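#' Read a per-cell table exported from image analysis
#'
#' One row per segmented cell, the schema written by inForm-style per-cell
#' exports: `cell_id`, `roi_id`, `patient_id`, `region` (TC / IM / N,
#' case-insensitive), `x_um`, `y_um` (nucleus centroid in micrometers, origin
#' at the field's top-left corner, y downward), `cell_class`
#' (tumor / immune / other), plus one ordinal 0--3 intensity column per
#' marker. Rows are never silently dropped: every row either lands in the
#' returned table or raises a validation error naming the offending row.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @param panel Optional `si_panel`; when given, every panel marker must be
#'   present as a column.
#' @return A tibble of cells, one row per cell, marker columns as integers.
#' @export
read_cell_table <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(sprintf("cell table not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_cells(raw, panel = panel, source = path)
}

#' Validate and normalise a raw cell table
#'
#' @param cells Data frame with the cell-table schema (see
#'   [read_cell_table()]); columns may arrive as character.
#' @param panel Optional `si_panel` whose markers must all be present.
#' @param source Label used in error messages.
#' @return A validated tibble (regions upper-case, coordinates numeric,
#'   marker intensities integer).
#' @export
validate_cells <- function(cells, panel = NULL, source = "cell table") {
  cells <- as_tibble(cells)
  mandatory <- c("cell_id", "roi_id", "patient_id", "region",
                 "x_um", "y_um", "cell_class")
  miss <- setdiff(mandatory, names(cells))
  if (length(miss) > 0L) {
    abort(sprintf("%s: missing mandatory column(s): %s",
                  source, paste(miss, collapse = ", ")))
  }
  marker_cols <- setdiff(names(cells), mandatory)
  if (!is.null(panel)) {
    absent <- setdiff(panel$markers, marker_cols)
    if (length(absent) > 0L) {
      abort(sprintf("%s: panel marker column(s) missing: %s",
                    source, paste(absent, collapse = ", ")))
    }
  }
  if (nrow(cells) == 0L) {
    cells$x_um <- numeric(0); cells$y_um <- numeric(0)
    for (m in marker_cols) cells[[m]] <- integer(0)
    return(cells)
  }

  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      abort(sprintf("%s: non-numeric %s at row %d", source, col, bad[1]))
    }
    if (any(v < 0)) {
      abort(sprintf("%s: negative %s at row %d", source, col, which(v < 0)[1]))
    }
    cells[[col]] <- v
  }

  reg <- toupper(trimws(as.character(cells$region)))
  bad <- which(!reg %in% c("TC", "IM", "N"))
  if (length(bad) > 0L) {
    abort(sprintf("%s: unknown region label '%s' at row %d (expected TC, IM or N)",
                  source, cells$region[bad[1]], bad[1]))
  }
  cells$region <- reg

  cls <- tolower(trimws(as.character(cells$cell_class)))
  bad <- which(!cls %in% c("tumor", "immune", "other"))
  if (length(bad) > 0L) {
    abort(sprintf("%s: unknown cell_class '%s' at row %d (expected tumor, immune or other)",
                  source, cells$cell_class[bad[1]], bad[1]))
  }
  cells$cell_class <- cls

  for (m in marker_cols) {
    v <- suppressWarnings(as.numeric(cells[[m]]))
    bad <- which(is.na(v) | !v %in% 0:3)
    if (length(bad) > 0L) {
      abort(sprintf("%s: marker '%s' intensity outside {0,1,2,3} at row %d",
                    source, m, bad[1]))
    }
    cells[[m]] <- as.integer(v)
  }

  dup <- cells %>%
    count(.data$roi_id, .data$cell_id) %>%
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("%s: duplicate cell_id '%s' within roi '%s'",
                  source, dup$cell_id[1], dup$roi_id[1]))
  }
  multi <- cells %>% distinct(.data$roi_id, .data$patient_id) %>% count(.data$roi_id)
  if (any(multi$n > 1L)) {
    abort(sprintf("%s: roi '%s' maps to more than one patient",
                  source, multi$roi_id[multi$n > 1L][1]))
  }
  cells
}

#' Read a per-patient clinical table
#'
#' CSV with `patient_id` plus optional clinical and survival columns
#' (`cldn_status`, covariates, `os_months`/`os_event`,
#' `iros_months`/`iros_event`, `irpfs_months`/`irpfs_event`, `response`).
#' Blank survival cells become `NA`, never zeros.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per patient.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("patient table not found: %s", path))
  pts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(pts)) abort("patient table: missing column patient_id")
  pts$patient_id <- as.character(pts$patient_id)
  if (anyDuplicated(pts$patient_id)) {
    abort(sprintf("patient table: duplicate patient_id '%s'",
                  pts$patient_id[duplicated(pts$patient_id)][1]))
  }
  for (col in intersect(c("os_months", "iros_months", "irpfs_months"), names(pts))) {
    v <- as.numeric(pts[[col]])
    if (any(v < 0, na.rm = TRUE)) abort(sprintf("patient table: negative %s", col))
    pts[[col]] <- v
    evc <- sub("_months$", "_event", col)
    if (any(!is.na(v)) && !evc %in% names(pts)) {
      abort(sprintf("patient table: %s present but %s missing", col, evc))
    }
    if (evc %in% names(pts) && any(!is.na(v) & is.na(pts[[evc]]))) {
      abort(sprintf("patient table: %s present without %s", col, evc))
    }
  }
  pts
}

#' Write a report table to CSV
#'
#' Deterministic column order (as given); missing values are written as
#' empty fields so that reading the file back returns the same values.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path) {
  readr::write_csv(as_tibble(rows), path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarise a cell table by imaged field
#'
#' @param cells A validated cell tibble.
#' @return One row per ROI: patient, region, cell counts by class.
#' @export
roi_summary <- function(cells) {
  cells %>%
    group_by(.data$roi_id, .data$patient_id, .data$region) %>%
    summarise(
      n_cells = n(),
      n_tumor = sum(.data$cell_class == "tumor"),
      n_immune = sum(.data$cell_class == "immune"),
      n_other = sum(.data$cell_class == "other"),
      .groups = "drop"
    )
}
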