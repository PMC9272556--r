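#' Build a fixed-radius bipartite neighbor graph
#'
#' Pairs every central (tumor) cell with every peripheral (immune) cell of
#' one field whose nucleus-to-nucleus Euclidean distance is at most
#' `radius`; 20 micrometers is the conventional range for effective
#' cell-to-cell contact. The boundary is inclusive (distance == radius is an
#' edge). A grid-bucket index with bucket size `radius` is used so only the
#' 3 x 3 neighborhood of buckets is scanned per central cell; the result is
#' identical to the all-pairs definition.
#'
#' @param central Tibble of central cells with `cell_id`, `x_um`, `y_um`.
#' @param peripheral Tibble of peripheral cells, same columns. Must not
#'   share any `cell_id` with `central`.
#' @param radius Pairing radius in micrometers (> 0).
#' @param torus Optional `c(width, height)`: measure distances on a torus
#'   (periodic boundary). Used for calibration against the homogeneous
#'   Poisson expectation, where edge effects would otherwise bias the score;
#'   routine analyses leave it `NULL`.
#' @return An `si_graph`: list with `edges` (tibble `central_id`,
#'   `peripheral_id`, `distance`), `n_central`, `n_peripheral`, `radius`.
#' @export
neighbor_graph <- function(central, peripheral, radius = 20, torus = NULL) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a single positive number")
  }
  for (d in list(central, peripheral)) {
    miss <- setdiff(c("cell_id", "x_um", "y_um"), names(d))
    if (length(miss) > 0L) {
      abort(sprintf("cell tibbles need columns: %s", paste(miss, collapse = ", ")))
    }
  }
  shared <- intersect(central$cell_id, peripheral$cell_id)
  if (length(shared) > 0L) {
    abort(sprintf("cell '%s' appears as both central and peripheral; the sets must be disjoint",
                  shared[1]))
  }
  edges <- if (is.null(torus)) {
    grid_pairs(central, peripheral, radius)
  } else {
    torus_pairs(central, peripheral, radius, torus)
  }
  structure(
    list(edges = edges,
         n_central = nrow(central), n_peripheral = nrow(peripheral),
         central_ids = central$cell_id, radius = radius),
    class = "si_graph"
  )
}

# Grid-bucket fixed-radius search; exact (bucket size == radius, so all
# points within radius of a central lie in its 3x3 bucket neighborhood).
grid_pairs <- function(central, peripheral, radius) {
  empty <- tibble(central_id = character(0), peripheral_id = character(0),
                  distance = numeric(0))
  if (nrow(central) == 0L || nrow(peripheral) == 0L) return(empty)
  px <- peripheral$x_um; py <- peripheral$y_um
  cx <- central$x_um; cy <- central$y_um
  pix <- floor(px / radius); piy <- floor(py / radius)
  cix <- floor(cx / radius); ciy <- floor(cy / radius)
  bucket_of <- split(seq_along(px), paste(pix, piy))
  acc_c <- integer(0); acc_p <- integer(0); acc_d <- numeric(0)
  for (dx in -1:1) {
    for (dy in -1:1) {
      cand_list <- bucket_of[paste(cix + dx, ciy + dy)]
      lens <- lengths(cand_list)
      if (sum(lens) == 0L) next
      ci <- rep.int(seq_along(lens), lens)
      pj <- unlist(cand_list, use.names = FALSE)
      d2 <- (px[pj] - cx[ci])^2 + (py[pj] - cy[ci])^2
      keep <- d2 <= radius^2
      acc_c <- c(acc_c, ci[keep])
      acc_p <- c(acc_p, pj[keep])
      acc_d <- c(acc_d, sqrt(d2[keep]))
    }
  }
  if (length(acc_c) == 0L) return(empty)
  tibble(
    central_id = central$cell_id[acc_c],
    peripheral_id = peripheral$cell_id[acc_p],
    distance = acc_d
  )
}

# All-pairs search with periodic (toroidal) distance.
torus_pairs <- function(central, peripheral, radius, torus) {
  stopifnot(length(torus) == 2L, all(torus > 0))
  empty <- tibble(central_id = character(0), peripheral_id = character(0),
                  distance = numeric(0))
  if (nrow(central) == 0L || nrow(peripheral) == 0L) return(empty)
  dx <- abs(outer(central$x_um, peripheral$x_um, "-"))
  dy <- abs(outer(central$y_um, peripheral$y_um, "-"))
  dx <- pmin(dx, torus[1] - dx)
  dy <- pmin(dy, torus[2] - dy)
  d <- sqrt(dx^2 + dy^2)
  hit <- which(d <= radius, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  tibble(
    central_id = central$cell_id[hit[, 1]],
    peripheral_id = peripheral$cell_id[hit[, 2]],
    distance = d[hit]
  )
}

#' Effective score of a neighbor graph
#'
#' The number of tumor-immune edges divided by the number of central tumor
#' cells: the average number of immune cells paired with each tumor cell
#' within the radius. Undefined (NA) when the field has no central cells.
#'
#' @param graph An `si_graph` from [neighbor_graph()].
#' @return A non-negative number, or `NA` if `n_central == 0`.
#' @export
effective_score <- function(graph) {
  stopifnot(inherits(graph, "si_graph"))
  if (graph$n_central == 0L) return(NA_real_)
  nrow(graph$edges) / graph$n_central
}

#' Effective percent of a neighbor graph
#'
#' The fraction of central tumor cells paired with at least one immune cell
#' within the radius. Always in [0, 1] and never exceeds the effective
#' score, with equality exactly when no tumor cell has more than one immune
#' neighbor.
#'
#' @inheritParams effective_score
#' @return A fraction in [0, 1], or `NA` if `n_central == 0`.
#' @export
effective_percent <- function(graph) {
  stopifnot(inherits(graph, "si_graph"))
  if (graph$n_central == 0L) return(NA_real_)
  dplyr::n_distinct(graph$edges$central_id) / graph$n_central
}

#' @export
print.si_graph <- function(x, ...) {
  cat(sprintf("<si_graph> %d central, %d peripheral, %d edges (radius %g um)\n",
              x$n_central, x$n_peripheral, nrow(x$edges), x$radius))
  invisible(x)
}

#' Expected effective score under complete spatial randomness
#'
#' When peripheral cells form a homogeneous Poisson process of intensity
#' `lambda` (cells per square micrometer), each central cell expects
#' `lambda * pi * radius^2` neighbors, ignoring edge effects. Useful as an
#' analytic null for calibrating the spatial metrics.
#'
#' @param lambda Peripheral cell intensity, cells per square micrometer.
#' @param radius Pairing radius in micrometers.
#' @return The expected effective score.
#' @export
csr_expected_score <- function(lambda, radius = 20) {
  if (any(lambda < 0) || any(radius < 0)) abort("lambda and radius must be >= 0")
  lambda * pi * radius^2
}

#' Per-field spatial metrics for every phenotype
#'
#' For each field, builds one neighbor graph between the central cells
#' (class `"tumor"`: tumor cells in tumor-core fields, epithelial cells in
#' normal-tissue fields) and all immune cells, then restricts its edges to
#' each phenotype's cells to obtain per-phenotype effective scores and
#' percents. Fields with no central cells are excluded with a warning and
#' reported with `NA` metrics.
#'
#' @param cells A validated cell tibble.
#' @param labels Phenotype assignments from [assign_phenotypes()]; computed
#'   from `panel` when omitted.
#' @param panel An `si_panel`, required when `labels` is missing.
#' @param radius Pairing radius in micrometers.
#' @return A tibble with one row per ROI x phenotype: `roi_id`,
#'   `patient_id`, `region`, `phenotype`, `n_central`, `n_peripheral`,
#'   `n_edges`, `effective_score`, `effective_percent`.
#' @export
spatial_metrics <- function(cells, labels = NULL, panel = NULL, radius = 20) {
  if (is.null(labels)) {
    if (is.null(panel)) abort("supply `labels` or `panel`")
    labels <- assign_phenotypes(cells, panel)
  }
  phen_cols <- setdiff(names(labels), c("cell_id", "roi_id"))
  rois <- cells %>% distinct(.data$roi_id, .data$patient_id, .data$region)
  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    rid <- rois$roi_id[i]
    rc <- cells %>% filter(.data$roi_id == rid)
    rl <- labels %>% filter(.data$roi_id == rid)
    rl <- rl[match(rc$cell_id, rl$cell_id), ]
    central <- rc %>% filter(.data$cell_class == "tumor")
    periph <- rc %>% filter(.data$cell_class == "immune")
    if (nrow(central) == 0L) {
      warn(sprintf("roi '%s' has no central tumor cells; spatial metrics excluded", rid))
      g <- NULL
    } else {
      g <- neighbor_graph(central %>% select("cell_id", "x_um", "y_um"),
                          periph %>% select("cell_id", "x_um", "y_um"),
                          radius = radius)
    }
    res <- lapply(phen_cols, function(ph) {
      ph_ids <- rl$cell_id[rl[[ph]] & rc$cell_class == "immune"]
      if (is.null(g)) {
        return(tibble(phenotype = ph, n_central = 0L,
                      n_peripheral = length(ph_ids), n_edges = NA_integer_,
                      effective_score = NA_real_, effective_percent = NA_real_))
      }
      e <- g$edges %>% filter(.data$peripheral_id %in% ph_ids)
      tibble(
        phenotype = ph,
        n_central = g$n_central,
        n_peripheral = length(ph_ids),
        n_edges = nrow(e),
        effective_score = nrow(e) / g$n_central,
        effective_percent = dplyr::n_distinct(e$central_id) / g$n_central
      )
    })
    out[[i]] <- bind_rows(res) %>%
      mutate(roi_id = rid, patient_id = rois$patient_id[i],
             region = rois$region[i], .before = 1)
  }
  bind_rows(out)
}

#' Aggregate per-field spatial metrics to one value per patient
#'
#' Mirrors [patient_rates()]: `"mean"` averages per-field metrics with equal
#' weight, `"pooled"` sums edges and central cells over the patient's fields
#' before dividing. Fields excluded for lack of central cells (NA metrics)
#' are dropped from the aggregate.
#'
#' @param spatial Output of [spatial_metrics()].
#' @param region Region to aggregate within.
#' @param mode `"mean"` or `"pooled"`.
#' @return One row per patient x phenotype with aggregated
#'   `effective_score` and `effective_percent`.
#' @export
patient_spatial <- function(spatial, region = "TC", mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  s <- spatial %>%
    filter(.data$region == !!region, !is.na(.data$effective_score))
  s %>%
    group_by(.data$patient_id, .data$region, .data$phenotype) %>%
    summarise(
      n_rois = n(),
      effective_score = if (mode == "mean") mean(.data$effective_score)
        else sum(.data$n_edges) / sum(.data$n_central),
      effective_percent = if (mode == "mean") mean(.data$effective_percent)
        else sum(.data$effective_percent * .data$n_central) / sum(.data$n_central),
      .groups = "drop"
    )
}
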