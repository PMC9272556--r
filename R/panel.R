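#' Define a marker-combination phenotype gate
#'
#' A phenotype is a boolean rule over per-cell ordinal marker intensities
#' (0--3; binary fluorescence markers use 0/1): every marker in `positive`
#' must be at or above its minimum intensity and every marker in `negative`
#' must be at or below its maximum (default 0). Cells may satisfy several
#' phenotypes at once, so nested subtypes such as CD8+ and CD8+PD-1- are
#' both assigned to the same cell.
#'
#' @param name Phenotype label, unique within a panel (e.g. `"CD8+PD-1-"`).
#' @param positive Named numeric vector of minimum intensities, or a
#'   character vector of marker names (minimum defaults to 1).
#' @param negative Named numeric vector of maximum intensities, or a
#'   character vector of marker names (maximum defaults to 0).
#' @param cell_class Cell class the gate applies to: `"immune"`, `"tumor"`
#'   or `"any"`.
#' @return An object of class `si_phenotype`.
#' @examples
#' phenotype_def("CD8+PD-1-", positive = "CD8", negative = "PD-1")
#' @export
phenotype_def <- function(name, positive = character(), negative = character(),
                          cell_class = c("immune", "tumor", "any")) {
  cell_class <- match.arg(cell_class)
  positive <- as_marker_bounds(positive, default = 1)
  negative <- as_marker_bounds(negative, default = 0)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a single non-empty string.")
  }
  overlap <- intersect(names(positive), names(negative))
  if (length(overlap) > 0L) {
    abort(sprintf("phenotype '%s': markers %s appear as both positive and negative",
                  name, paste(overlap, collapse = ", ")))
  }
  structure(
    list(name = name, cell_class = cell_class,
         positive = positive, negative = negative),
    class = "si_phenotype"
  )
}

as_marker_bounds <- function(x, default) {
  if (length(x) == 0L) return(setNames(numeric(0), character(0)))
  if (is.character(x)) x <- setNames(rep(default, length(x)), x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("marker thresholds must be named by marker")
  }
  bad <- !(x %in% 0:3)
  if (any(bad)) abort("marker thresholds must be ordinal intensities in 0..3")
  storage.mode(x) <- "double"
  x
}

#' Assemble a marker panel
#'
#' A panel bundles the marker list, the phenotype gates, and the two
#' CLDN18.2 positivity cutoffs: a tumor cell counts as CLDN18.2-expressing
#' at membrane intensity >= `cldn_intensity_cutoff` (default 2, i.e.
#' moderate-to-strong), and a patient is called positive when at least
#' `cldn_proportion_cutoff` (default 0.40) of pooled tumor-core tumor cells
#' express it. Both cutoffs are inclusive.
#'
#' @param markers Character vector of marker column names expected on cells.
#' @param phenotypes List of [phenotype_def()] objects.
#' @param cldn_marker Name of the claudin-18.2 marker column.
#' @param cldn_intensity_cutoff Ordinal intensity at or above which a tumor
#'   cell counts as CLDN18.2-expressing.
#' @param cldn_proportion_cutoff Fraction of tumor cells at or above which a
#'   patient is CLDN18.2-positive.
#' @return An object of class `si_panel`.
#' @export
panel <- function(markers, phenotypes, cldn_marker = "CLDN18.2",
                  cldn_intensity_cutoff = 2, cldn_proportion_cutoff = 0.40) {
  stopifnot(is.character(markers), length(markers) > 0L)
  if (anyDuplicated(markers)) abort("duplicate marker names in panel")
  if (inherits(phenotypes, "si_phenotype")) phenotypes <- list(phenotypes)
  ok <- vapply(phenotypes, inherits, logical(1), "si_phenotype")
  if (!all(ok)) abort("`phenotypes` must be a list of phenotype_def() objects")
  nms <- vapply(phenotypes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("duplicate phenotype names in panel")
  used <- unique(unlist(lapply(phenotypes, function(p) {
    c(names(p$positive), names(p$negative))
  })))
  missing_mk <- setdiff(used, markers)
  if (length(missing_mk) > 0L) {
    abort(sprintf("phenotypes reference markers not in the panel: %s",
                  paste(missing_mk, collapse = ", ")))
  }
  if (!cldn_intensity_cutoff %in% 0:3) abort("cldn_intensity_cutoff must be in 0..3")
  if (cldn_proportion_cutoff < 0 || cldn_proportion_cutoff > 1) {
    abort("cldn_proportion_cutoff must be in [0, 1]")
  }
  structure(
    list(markers = markers, phenotypes = setNames(phenotypes, nms),
         cldn_marker = cldn_marker,
         cldn_intensity_cutoff = cldn_intensity_cutoff,
         cldn_proportion_cutoff = cldn_proportion_cutoff),
    class = "si_panel"
  )
}

#' @export
print.si_panel <- function(x, ...) {
  cat(sprintf("<si_panel> %d markers, %d phenotypes\n",
              length(x$markers), length(x$phenotypes)))
  cat("markers:   ", paste(x$markers, collapse = ", "), "\n")
  cat("phenotypes:", paste(names(x$phenotypes), collapse = ", "), "\n")
  cat(sprintf("CLDN18.2 call: intensity >= %d in >= %.0f%% of tumor cells\n",
              x$cldn_intensity_cutoff, 100 * x$cldn_proportion_cutoff))
  invisible(x)
}

#' Default gastric-cancer immune panel
#'
#' The immune subtypes reported in the gastric-cancer tumor-microenvironment
#' analyses this package supports: CD8 T cells split by the PD-1, LAG-3 and
#' TIM-3 checkpoints, CD4 T cells split by FoxP3, CTLA-4 and PD-L1 (with
#' CD4+FoxP3+ regulatory T cells), CD20 B cells, CD66b neutrophils, and
#' CD68/CD163/HLA-DR macrophages with the M1 (CD68+CD163-HLA-DR+) and
#' M2 (CD68+CD163+HLA-DR-) polarisations. Users needing further subtypes
#' can extend the returned panel or build their own with [panel()].
#'
#' @return An `si_panel`.
#' @export
default_gc_panel <- function() {
  mk <- c("CD8", "PD-1", "LAG-3", "TIM-3",
          "CD4", "FoxP3", "CTLA-4", "PD-L1",
          "CD20", "CD66b", "CD68", "CD163", "HLA-DR", "CLDN18.2")
  ph <- list(
    phenotype_def("CD8+", positive = "CD8"),
    phenotype_def("CD8+PD-1-", positive = "CD8", negative = "PD-1"),
    phenotype_def("CD8+PD-1+", positive = c("CD8", "PD-1")),
    phenotype_def("CD8+LAG-3-", positive = "CD8", negative = "LAG-3"),
    phenotype_def("CD8+LAG-3+", positive = c("CD8", "LAG-3")),
    phenotype_def("CD8+TIM-3-", positive = "CD8", negative = "TIM-3"),
    phenotype_def("CD8+TIM-3+", positive = c("CD8", "TIM-3")),
    phenotype_def("CD4+", positive = "CD4"),
    phenotype_def("CD4+FoxP3-", positive = "CD4", negative = "FoxP3"),
    phenotype_def("Treg", positive = c("CD4", "FoxP3")),
    phenotype_def("CD4+FoxP3-CTLA-4-", positive = "CD4",
                  negative = c("FoxP3", "CTLA-4")),
    phenotype_def("CD4+FoxP3-PD-L1-", positive = "CD4",
                  negative = c("FoxP3", "PD-L1")),
    phenotype_def("CD4+PD-L1+", positive = c("CD4", "PD-L1")),
    phenotype_def("B cell", positive = "CD20"),
    phenotype_def("Neutrophil", positive = "CD66b"),
    phenotype_def("Macrophage", positive = "CD68"),
    phenotype_def("M1", positive = c("CD68", "HLA-DR"), negative = "CD163"),
    phenotype_def("M2", positive = c("CD68", "CD163"), negative = "HLA-DR")
  )
  panel(mk, ph)
}

#' Read a panel from a YAML or JSON config file
#'
#' The config has keys `markers` (list of names), `phenotypes` (list of
#' `{name, class, positive: {marker: min}, negative: [marker] or
#' {marker: max}}`), and optional `cldn_marker`, `cldn_intensity_cutoff`,
#' `cldn_proportion_cutoff`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `si_panel`.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel config not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$markers) || is.null(cfg$phenotypes)) {
    abort("panel config must define `markers` and `phenotypes`")
  }
  phens <- lapply(cfg$phenotypes, function(p) {
    phenotype_def(
      name = p$name,
      positive = bounds_from_config(p$positive, default = 1),
      negative = bounds_from_config(p$negative, default = 0),
      cell_class = p$class %||% "immune"
    )
  })
  panel(
    markers = unlist(cfg$markers),
    phenotypes = phens,
    cldn_marker = cfg$cldn_marker %||% "CLDN18.2",
    cldn_intensity_cutoff = cfg$cldn_intensity_cutoff %||% 2,
    cldn_proportion_cutoff = cfg$cldn_proportion_cutoff %||% 0.40
  )
}

bounds_from_config <- function(x, default) {
  if (is.null(x)) return(character())
  if (is.list(x) && !is.null(names(x))) return(unlist(x))
  unlist(x)  # character vector form
}

#' Write a panel to a YAML config file
#'
#' @param panel An `si_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "si_panel"))
  cfg <- list(
    markers = as.list(panel$markers),
    phenotypes = lapply(unname(panel$phenotypes), function(p) {
      list(name = p$name, class = p$cell_class,
           positive = as.list(p$positive), negative = as.list(p$negative))
    }),
    cldn_marker = panel$cldn_marker,
    cldn_intensity_cutoff = panel$cldn_intensity_cutoff,
    cldn_proportion_cutoff = panel$cldn_proportion_cutoff
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
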