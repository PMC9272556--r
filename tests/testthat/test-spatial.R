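test_that("the pairing boundary is inclusive at exactly the radius", {
  cen <- tibble::tibble(cell_id = "c1", x_um = 0, y_um = 0)
  at <- tibble::tibble(cell_id = "p1", x_um = 20, y_um = 0)
  beyond <- tibble::tibble(cell_id = "p1", x_um = 20.1, y_um = 0)
  expect_equal(nrow(neighbor_graph(cen, at, 20)$edges), 1L)
  expect_equal(nrow(neighbor_graph(cen, beyond, 20)$edges), 0L)
})

test_that("central and peripheral sets must be disjoint", {
  cen <- tibble::tibble(cell_id = c("a", "b"), x_um = c(0, 5), y_um = 0)
  per <- tibble::tibble(cell_id = c("b", "c"), x_um = c(1, 2), y_um = 0)
  expect_error(neighbor_graph(cen, per, 20), "disjoint")
})

test_that("effective score and percent follow the edge-count definitions", {
  cen <- tibble::tibble(cell_id = c("c1", "c2"), x_um = c(0, 100), y_um = 0)
  per <- tibble::tibble(cell_id = c("i1", "i2"),
                        x_um = c(5, 95), y_um = c(0, 12))
  # c1-i1 (d=5), c2-i2 (d=13), c2-i1 (d=95) no; need edges {c1-i1, c1-i2?}
  g <- neighbor_graph(cen, per, 20)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(effective_score(g), 1)
  expect_equal(effective_percent(g), 1)

  # 2 centrals, 3 edges: c1 paired twice, c2 once -> score 1.5, percent 1
  cen <- tibble::tibble(cell_id = c("c1", "c2"), x_um = c(0, 30), y_um = 0)
  per <- tibble::tibble(cell_id = c("i1", "i2"),
                        x_um = c(15, 5), y_um = c(0, 5))
  g <- neighbor_graph(cen, per, 20)  # c1-i1, c1-i2, c2-i1
  expect_equal(nrow(g$edges), 3L)
  expect_equal(effective_score(g), 1.5)
  expect_equal(effective_percent(g), 1)

  # 4 centrals, edges only to one -> percent 0.25
  cen <- tibble::tibble(cell_id = paste0("c", 1:4),
                        x_um = c(0, 200, 400, 600), y_um = 0)
  per <- tibble::tibble(cell_id = c("i1", "i2"), x_um = c(5, 10), y_um = 0)
  g <- neighbor_graph(cen, per, 20)
  expect_equal(effective_score(g), 0.5)
  expect_equal(effective_percent(g), 0.25)

  # no edges at all
  per_far <- tibble::tibble(cell_id = "i1", x_um = 500, y_um = 500)
  g0 <- neighbor_graph(cen, per_far, 20)
  expect_equal(effective_score(g0), 0)
  expect_equal(effective_percent(g0), 0)
})

test_that("a field without central cells yields NA metrics and a warning", {
  g <- neighbor_graph(tibble::tibble(cell_id = character(0), x_um = numeric(0),
                                     y_um = numeric(0)),
                      tibble::tibble(cell_id = "i1", x_um = 1, y_um = 1), 20)
  expect_true(is.na(effective_score(g)))
  expect_true(is.na(effective_percent(g)))

  cells <- make_cells(5, cell_class = "immune")
  cells$CD8 <- 1L
  expect_warning(sm <- spatial_metrics(cells, panel = tiny_panel()),
                 "no central tumor cells")
  expect_true(all(is.na(sm$effective_score)))
})

test_that("the grid index reproduces the brute-force graph on random fields", {
  set.seed(2024)
  for (k in 1:15) {
    roi <- random_roi_cells(sample(1:250, 1), sample(1:250, 1))
    g <- neighbor_graph(roi$central, roi$peripheral, 20)
    expect_identical(graph_edge_keys(g),
                     bf_edge_keys(roi$central, roi$peripheral, 20))
  }
})

test_that("csr_expected_score is the Poisson disc expectation", {
  expect_equal(csr_expected_score(0, 20), 0)
  expect_equal(csr_expected_score(1 / (pi * 400), 20), 1)
  expect_error(csr_expected_score(-1, 20), ">= 0")
})

test_that("both metrics are non-decreasing in the radius", {
  set.seed(5)
  roi <- random_roi_cells(80, 120)
  radii <- c(5, 10, 20, 40, 80)
  scores <- numeric(0); pcts <- numeric(0)
  for (r in radii) {
    g <- neighbor_graph(roi$central, roi$peripheral, r)
    scores <- c(scores, effective_score(g))
    pcts <- c(pcts, effective_percent(g))
  }
  expect_true(all(diff(scores) >= 0))
  expect_true(all(diff(pcts) >= 0))
})

test_that("rigid motions leave the metrics unchanged", {
  set.seed(6)
  roi <- random_roi_cells(60, 90)
  g0 <- neighbor_graph(roi$central, roi$peripheral, 20)
  th <- 0.73; dx <- 311.5; dy <- -42.25
  rot <- function(d) dplyr::mutate(d,
    x2 = cos(th) * x_um - sin(th) * y_um + dx,
    y2 = sin(th) * x_um + cos(th) * y_um + dy,
    x_um = x2, y_um = y2)
  g1 <- neighbor_graph(rot(roi$central), rot(roi$peripheral), 20)
  expect_equal(effective_score(g1), effective_score(g0), tolerance = 1e-9)
  expect_equal(effective_percent(g1), effective_percent(g0), tolerance = 1e-9)
})

test_that("per-phenotype metrics equal metrics of per-phenotype graphs", {
  set.seed(8)
  pan <- tiny_panel()
  cells <- make_cells(400, cell_class = sample(c("tumor", "immune"), 400, TRUE,
                                               prob = c(0.5, 0.5)))
  imm <- cells$cell_class == "immune"
  cells$CD8[imm] <- sample(0:1, sum(imm), TRUE)
  cells$`PD-1`[imm] <- sample(0:1, sum(imm), TRUE)
  sm <- spatial_metrics(cells, panel = pan)
  lab <- assign_phenotypes(cells, pan)
  for (ph in c("CD8+", "CD8+PD-1-", "CD8+PD-1+")) {
    cen <- cells[cells$cell_class == "tumor", c("cell_id", "x_um", "y_um")]
    per <- cells[imm & lab[[ph]], c("cell_id", "x_um", "y_um")]
    g <- neighbor_graph(cen, per, 20)
    row <- sm[sm$phenotype == ph, ]
    expect_equal(row$effective_score, effective_score(g))
    expect_equal(row$effective_percent, effective_percent(g))
    expect_equal(row$n_edges, nrow(g$edges))
  }
})

test_that("patient-level spatial aggregation matches rate aggregation semantics", {
  sm <- tibble::tibble(
    roi_id = c("R1", "R2"), patient_id = "P1", region = "TC", phenotype = "CD8+",
    n_central = c(10L, 30L), n_peripheral = c(5L, 5L),
    n_edges = c(10L, 15L),
    effective_score = c(1.0, 0.5),
    effective_percent = c(0.6, 0.3)
  )
  m <- patient_spatial(sm, mode = "mean")
  expect_equal(m$effective_score, 0.75)
  expect_equal(m$effective_percent, 0.45)
  p <- patient_spatial(sm, mode = "pooled")
  expect_equal(p$effective_score, 25 / 40)
  expect_equal(p$effective_percent, (0.6 * 10 + 0.3 * 30) / 40)
})

test_that("toroidal distances wrap across field borders", {
  cen <- tibble::tibble(cell_id = "c1", x_um = 1, y_um = 350)
  per <- tibble::tibble(cell_id = "p1", x_um = 925, y_um = 350)
  expect_equal(nrow(neighbor_graph(cen, per, 20)$edges), 0L)
  g <- neighbor_graph(cen, per, 20, torus = c(930, 700))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$distance, 6)
})
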