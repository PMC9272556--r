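small_cfg <- function(...) {
  sim_config(n_per_group = 2, rois_per_patient = 1, normal_rois_per_patient = 1,
             tumor_density = 4e-4, immune_density = 4e-4, other_density = 2e-4,
             ...)
}

test_that("the same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(small_cfg(), seed = 99)
  b <- generate_cohort(small_cfg(), seed = 99)
  expect_identical(a$cells, b$cells)
  expect_identical(a$patients, b$patients)
  c <- generate_cohort(small_cfg(), seed = 100)
  expect_false(identical(a$cells, c$cells))
})

test_that("patients are generated from independent seeded streams", {
  full <- generate_cohort(sim_config(n_per_group = 2, rois_per_patient = 1,
                                     tumor_density = 3e-4, immune_density = 3e-4,
                                     other_density = 1e-4), seed = 5)
  # regenerating with the same master seed reproduces patient P003's cells
  again <- generate_cohort(sim_config(n_per_group = 2, rois_per_patient = 1,
                                      tumor_density = 3e-4, immune_density = 3e-4,
                                      other_density = 1e-4), seed = 5)
  p3a <- dplyr::filter(full$cells, patient_id == "P003")
  p3b <- dplyr::filter(again$cells, patient_id == "P003")
  expect_identical(p3a, p3b)
})

test_that("invalid config fields are rejected by name", {
  expect_error(sim_config(tumor_density = -1), "tumor_density")
  expect_error(sim_config(cldn_intensity_dist = list(
    positive = c(0.5, 0.5, 0.5, 0.5), negative = c(0.45, 0.35, 0.15, 0.05))),
    "cldn_intensity_dist\\$positive")
  expect_error(sim_config(attraction = list(positive = c(CD8T = -0.1),
                                            negative = c())),
               "attraction\\$positive")
})

test_that("generated cells honor the schema and field bounds", {
  co <- generate_cohort(small_cfg(), seed = 3)
  cells <- validate_cells(co$cells, panel = default_gc_panel())
  expect_true(all(cells$x_um >= 0 & cells$x_um <= 930))
  expect_true(all(cells$y_um >= 0 & cells$y_um <= 700))
  expect_true(all(cells$region %in% c("TC", "N")))
  expect_true(all(table(cells$roi_id) > 0))
})

test_that("marker co-expression is nested and lineage-consistent", {
  co <- generate_cohort(small_cfg(), seed = 13)
  imm <- dplyr::filter(co$cells, cell_class == "immune")
  # checkpoints only on their lineage
  expect_true(all(imm$CD8[imm$`PD-1` == 1] == 1))
  expect_true(all(imm$CD8[imm$`LAG-3` == 1] == 1))
  expect_true(all(imm$CD4[imm$FoxP3 == 1] == 1))
  # one lineage marker per immune cell
  lin <- imm$CD8 + imm$CD4 + imm$CD20 + imm$CD66b + imm$CD68
  expect_true(all(lin == 1))
  # macrophage polarisation is exclusive
  expect_true(all(imm$CD163 + imm$`HLA-DR` <= 1))
  # tumor cells carry no immune markers, immune cells no CLDN18.2
  tum <- dplyr::filter(co$cells, cell_class == "tumor")
  expect_true(all(tum$CD8 == 0 & tum$CD4 == 0))
  expect_true(all(imm$`CLDN18.2` == 0))
})

test_that("group-separated CLDN18.2 intensity yields clean patient calls", {
  cfg <- sim_config(n_per_group = 4, rois_per_patient = 1,
                    normal_rois_per_patient = 0,
                    tumor_density = 1e-3, immune_density = 1e-4,
                    other_density = 0,
                    cldn_patient_logit_sd = 0,   # fixed per-group intensity mix
                    cldn_intensity_dist = list(
                      positive = c(0.2, 0.2, 0.35, 0.25),  # P(>=2) = 0.6
                      negative = c(0.45, 0.35, 0.15, 0.05) # P(>=2) = 0.2
                    ))
  co <- generate_cohort(cfg, seed = 31)
  calls <- classify_cldn_status(co$cells, default_gc_panel())
  merged <- dplyr::left_join(calls, co$patients, by = "patient_id")
  expect_true(all(merged$n_tumor >= 500))
  expect_identical(merged$cldn_status, merged$group)  # binomial concentration
})

test_that("spatial attraction raises the effective score monotonically", {
  base <- list(n_per_group = 1, rois_per_patient = 8, normal_rois_per_patient = 0,
               tumor_density = 8e-4, immune_density = 6e-4, other_density = 0,
               cldn_patient_logit_sd = 0)
  mean_score <- function(theta) {
    cfg <- do.call(sim_config, c(base, list(
      attraction = list(positive = c(CD8T = theta), negative = c())
    )))
    co <- generate_cohort(cfg, seed = 77)
    sm <- spatial_metrics(co$cells, panel = default_gc_panel())
    mean(sm$effective_score[sm$phenotype == "CD8+"])
  }
  s0 <- mean_score(0); s1 <- mean_score(0.5); s2 <- mean_score(1)
  expect_lt(s0, s1)
  expect_lt(s1, s2)
})

test_that("survival times follow the per-group exponential model", {
  cfg <- sim_config(n_per_group = 400, rois_per_patient = 0,
                    normal_rois_per_patient = 0,
                    survival_model = list(
                      os_rate = c(positive = log(2) / 12, negative = log(2) / 24),
                      iros_rate = c(positive = 0.1, negative = 0.05),
                      irpfs_rate = c(positive = 0.2, negative = 0.1),
                      censor_rate = 1e-6,  # essentially no censoring
                      immunotherapy_prob = 0.5))
  # zero fields per patient: survival only
  co <- generate_cohort(cfg, seed = 41)
  expect_equal(nrow(co$cells), 0L)
  pos <- dplyr::filter(co$patients, group == "positive")
  neg <- dplyr::filter(co$patients, group == "negative")
  expect_gt(mean(co$patients$os_event), 0.99)
  expect_lt(abs(median(pos$os_months) - 12) / 12, 0.25)
  expect_lt(abs(median(neg$os_months) - 24) / 24, 0.25)
  # irOS/irPFS only for immunotherapy patients
  expect_true(all(is.na(co$patients$iros_months[!co$patients$immunotherapy])))
  expect_true(all(!is.na(co$patients$irpfs_months[co$patients$immunotherapy])))
})

test_that("the worked field matches its hand-counted figures", {
  roi <- generate_worked_roi()
  expect_equal(nrow(roi), 12L)
  pan <- default_gc_panel()

  rates <- phenotype_rates(roi, panel = pan)
  expect_equal(rates$rate[rates$phenotype == "CD8+"], 6 / 12)
  expect_equal(rates$rate[rates$phenotype == "CD8+PD-1-"], 5 / 12)
  expect_equal(rates$rate[rates$phenotype == "CD4+"], 1 / 12)

  # class composition is exhaustive
  expect_equal(sum(roi$cell_class == "tumor"), 4L)
  expect_equal(mean(roi$cell_class == "tumor") + mean(roi$cell_class == "immune") +
                 mean(roi$cell_class == "other"), 1)

  sm <- spatial_metrics(roi, panel = pan)
  # hand count: CD8+ edges T1-I1, T1-I2, T2-I3, T2-I6, T3-I4 (d = 20 exactly)
  cd8 <- sm[sm$phenotype == "CD8+", ]
  expect_equal(cd8$n_edges, 5L)
  expect_equal(cd8$effective_score, 5 / 4)
  expect_equal(cd8$effective_percent, 3 / 4)
  pd1n <- sm[sm$phenotype == "CD8+PD-1-", ]
  expect_equal(pd1n$effective_score, 1)
  expect_equal(pd1n$effective_percent, 3 / 4)
  cd4 <- sm[sm$phenotype == "CD4+", ]
  expect_equal(cd4$effective_score, 1 / 4)
  expect_equal(cd4$effective_percent, 1 / 4)

  # CLDN18.2: intensities 3,2,1,0 -> 2/4 at >=2 -> positive
  call <- classify_cldn_status(roi, pan)
  expect_equal(call$cldn_proportion, 0.5)
  expect_equal(call$cldn_status, "positive")

  # round-trips through the CSV schema
  dir <- withr::local_tempdir()
  write_report_table(roi, file.path(dir, "cells.csv"))
  back <- read_cell_table(file.path(dir, "cells.csv"), panel = pan)
  expect_equal(back$x_um, roi$x_um)
  expect_identical(back$`CLDN18.2`, roi$`CLDN18.2`)
})
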