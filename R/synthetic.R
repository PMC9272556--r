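#' Configuration for the synthetic m-IHC cohort generator
#'
#' Defaults emulate the design of the 80-patient gastric-cancer study the
#' pipeline targets: two patient groups (CLDN18.2 `positive` / `negative`,
#' 40 each), 930 x 700 micrometer imaged fields, tumor / immune / other cell
#' classes at tissue-like densities, binary immune markers with nested
#' co-expression (checkpoints drawn conditionally on lineage), ordinal 0--3
#' CLDN18.2 intensity on tumor cells with group-dependent mass at >= 2+,
#' optional tumor-immune spatial attraction, and exponential survival with
#' independent exponential censoring.
#'
#' @param n_per_group Patients per group.
#' @param rois_per_patient Tumor-core fields per patient.
#' @param normal_rois_per_patient Tumor-adjacent normal fields per patient.
#' @param roi_width,roi_height Field size in micrometers.
#' @param tumor_density,immune_density,other_density Cells per square
#'   micrometer for each class (tumor-core fields).
#' @param lineage_probs Named list (`positive`, `negative`) of probability
#'   vectors over immune lineages `CD8T`, `CD4T`, `B`, `Neutrophil`,
#'   `Macrophage`; each must sum to 1.
#' @param checkpoint_probs Named list (`positive`, `negative`) of
#'   conditional marker probabilities: `pd1_cd8`, `lag3_cd8`, `tim3_cd8`
#'   (given a CD8 T cell), `foxp3_cd4`, `ctla4_cd4`, `pdl1_cd4` (given a CD4
#'   T cell), `m1_mac` (probability a macrophage is M1 rather than M2).
#' @param cldn_intensity_dist Named list (`positive`, `negative`) of
#'   probability vectors over intensities 0..3 for tumor cells (group-mean
#'   distribution).
#' @param cldn_patient_logit_sd Between-patient SD, on the logit scale, of
#'   the per-patient probability of intensity >= 2 (0 = identical patients).
#' @param attraction Named list (`positive`, `negative`) of named vectors:
#'   per-lineage attraction strength theta >= 0. An immune cell of that
#'   lineage is anchored uniformly within `attraction_radius` of a random
#'   tumor cell with probability `min(theta, 1)`, and placed uniformly in
#'   the field otherwise; theta = 0 gives complete spatial randomness.
#' @param attraction_radius Anchoring radius in micrometers.
#' @param survival_model List of per-group exponential event rates
#'   (`os_rate`, `iros_rate`, `irpfs_rate`, each named `positive` /
#'   `negative`), a shared `censor_rate`, and `immunotherapy_prob`.
#' @param response_coef Intercept and slope of the logistic model giving
#'   the responder probability from the patient's CLDN18.2-expressing tumor
#'   fraction (immunotherapy patients only).
#' @return An `si_sim_config` list.
#' @export
sim_config <- function(
    n_per_group = 40,
    rois_per_patient = 3,
    normal_rois_per_patient = 1,
    roi_width = 930,
    roi_height = 700,
    tumor_density = 0.0015,
    immune_density = 0.0010,
    other_density = 0.0010,
    lineage_probs = list(
      positive = c(CD8T = 0.30, CD4T = 0.28, B = 0.10, Neutrophil = 0.18, Macrophage = 0.14),
      negative = c(CD8T = 0.30, CD4T = 0.30, B = 0.11, Neutrophil = 0.13, Macrophage = 0.16)
    ),
    checkpoint_probs = list(
      positive = c(pd1_cd8 = 0.545, lag3_cd8 = 0.42, tim3_cd8 = 0.48,
                   foxp3_cd4 = 0.18, ctla4_cd4 = 0.15, pdl1_cd4 = 0.20, m1_mac = 0.50),
      negative = c(pd1_cd8 = 0.70, lag3_cd8 = 0.59, tim3_cd8 = 0.63,
                   foxp3_cd4 = 0.20, ctla4_cd4 = 0.15, pdl1_cd4 = 0.25, m1_mac = 0.50)
    ),
    cldn_intensity_dist = list(
      positive = c(0.20, 0.20, 0.35, 0.25),
      negative = c(0.45, 0.35, 0.15, 0.05)
    ),
    cldn_patient_logit_sd = 0.4,
    attraction = list(positive = c(CD8T = 0.15), negative = c()),
    attraction_radius = 15,
    survival_model = list(
      os_rate = c(positive = log(2) / 23.33, negative = log(2) / 36.6),
      iros_rate = c(positive = log(2) / 10.03, negative = log(2) / 20.13),
      irpfs_rate = c(positive = log(2) / 3.5, negative = log(2) / 5.5),
      censor_rate = log(2) / 48,
      immunotherapy_prob = 0.5
    ),
    response_coef = c(intercept = 1.2, slope = -4)) {
  cfg <- list(
    n_per_group = n_per_group, rois_per_patient = rois_per_patient,
    normal_rois_per_patient = normal_rois_per_patient,
    roi_width = roi_width, roi_height = roi_height,
    tumor_density = tumor_density, immune_density = immune_density,
    other_density = other_density,
    lineage_probs = lineage_probs, checkpoint_probs = checkpoint_probs,
    cldn_intensity_dist = cldn_intensity_dist,
    cldn_patient_logit_sd = cldn_patient_logit_sd,
    attraction = attraction, attraction_radius = attraction_radius,
    survival_model = survival_model, response_coef = response_coef
  )
  validate_sim_config(cfg)
  structure(cfg, class = "si_sim_config")
}

validate_sim_config <- function(cfg) {
  pos_num <- c("n_per_group", "roi_width", "roi_height")
  for (f in pos_num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) abort(sprintf("invalid config field: %s", f))
  }
  for (f in c("tumor_density", "immune_density", "other_density",
              "rois_per_patient", "normal_rois_per_patient",
              "cldn_patient_logit_sd", "attraction_radius")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) abort(sprintf("invalid config field: %s", f))
  }
  for (g in c("positive", "negative")) {
    lp <- cfg$lineage_probs[[g]]
    if (is.null(lp) || abs(sum(lp) - 1) > 1e-9 || any(lp < 0)) {
      abort(sprintf("invalid config field: lineage_probs$%s", g))
    }
    cd <- cfg$cldn_intensity_dist[[g]]
    if (length(cd) != 4L || abs(sum(cd) - 1) > 1e-9 || any(cd < 0)) {
      abort(sprintf("invalid config field: cldn_intensity_dist$%s", g))
    }
    if (any(cfg$attraction[[g]] < 0)) {
      abort(sprintf("invalid config field: attraction$%s", g))
    }
  }
  invisible(cfg)
}

LINEAGES <- c("CD8T", "CD4T", "B", "Neutrophil", "Macrophage")
SIM_MARKERS <- c("CD8", "PD-1", "LAG-3", "TIM-3", "CD4", "FoxP3", "CTLA-4",
                 "PD-L1", "CD20", "CD66b", "CD68", "CD163", "HLA-DR", "CLDN18.2")

#' Generate a synthetic m-IHC cohort
#'
#' Draws a full cohort under [sim_config()]: per patient, tumor-core and
#' normal fields with homogeneous-Poisson cell counts, cell positions
#' (uniform, or anchored near tumor cells under the attraction model),
#' nested marker co-expression, group-dependent CLDN18.2 intensities, and
#' exponential survival with censoring. All randomness flows from `seed`
#' through one derived stream per patient, so any subset of patients is
#' reproducible independently of the others.
#'
#' @param config An `si_sim_config`.
#' @param seed Integer seed.
#' @return An `si_cohort`: list with `cells` (one row per cell, the
#'   [read_cell_table()] schema), `patients` (one row per patient), and the
#'   generating `config` and `seed`.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  groups <- rep(c("positive", "negative"), each = config$n_per_group)
  ids <- sprintf("P%03d", seq_along(groups))
  cells <- vector("list", length(ids))
  patients <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(patient_seed(seed, i))
    sim <- simulate_patient(ids[i], groups[i], config)
    cells[[i]] <- sim$cells
    patients[[i]] <- sim$patient
  }
  structure(
    list(cells = bind_rows(cells), patients = bind_rows(patients),
         config = config, seed = seed),
    class = "si_cohort"
  )
}

# One 32-bit stream seed per patient, derived from the master seed.
patient_seed <- function(seed, i) {
  ((as.numeric(seed) %% 1048573) * 1009 + i * 7919) %% 2147483647
}

simulate_patient <- function(pid, group, cfg) {
  area <- cfg$roi_width * cfg$roi_height
  # per-patient probability that a tumor cell stains >= 2+
  dist_g <- cfg$cldn_intensity_dist[[group]]
  p_high <- sum(dist_g[3:4])
  if (cfg$cldn_patient_logit_sd > 0 && p_high > 0 && p_high < 1) {
    p_high <- stats::plogis(stats::qlogis(p_high) +
                              stats::rnorm(1, 0, cfg$cldn_patient_logit_sd))
  }
  idist <- cldn_dist_for(dist_g, p_high)
  # normal tissue skews somewhat higher, mirroring the trend in gastric mucosa
  idist_n <- cldn_dist_for(dist_g, min(p_high + 0.10, 1))

  roi_cells <- list()
  k <- 0L
  for (r in seq_len(cfg$rois_per_patient)) {
    k <- k + 1L
    roi_cells[[k]] <- simulate_roi(
      sprintf("%s-TC%d", pid, r), pid, "TC", group, cfg, idist,
      immune_scale = 1
    )
  }
  for (r in seq_len(cfg$normal_rois_per_patient)) {
    k <- k + 1L
    roi_cells[[k]] <- simulate_roi(
      sprintf("%s-N%d", pid, r), pid, "N", group, cfg, idist_n,
      immune_scale = 0.7
    )
  }
  cells <- if (k == 0L) empty_cell_tibble() else bind_rows(roi_cells)

  sm <- cfg$survival_model
  os_t <- rexp(1, sm$os_rate[[group]])
  os_c <- rexp(1, sm$censor_rate)
  io <- runif(1) < sm$immunotherapy_prob
  tc_tumor <- cells$region == "TC" & cells$cell_class == "tumor"
  cldn_prop <- if (any(tc_tumor)) mean(cells$`CLDN18.2`[tc_tumor] >= 2) else NA_real_
  patient <- tibble(
    patient_id = pid,
    group = group,
    stage = sample(c("II", "III", "IV"), 1,
                   prob = if (group == "positive") c(0.2, 0.45, 0.35) else c(0.35, 0.4, 0.25)),
    her2 = sample(c("positive", "negative"), 1, prob = c(0.27, 0.73)),
    immunotherapy = io,
    os_months = min(os_t, os_c),
    os_event = as.integer(os_t <= os_c)
  )
  if (io) {
    iros_t <- rexp(1, sm$iros_rate[[group]])
    iros_c <- rexp(1, sm$censor_rate)
    irpfs_t <- rexp(1, sm$irpfs_rate[[group]])
    patient$iros_months <- min(iros_t, iros_c)
    patient$iros_event <- as.integer(iros_t <= iros_c)
    patient$irpfs_months <- min(irpfs_t, iros_c)
    patient$irpfs_event <- as.integer(irpfs_t <= iros_c)
    p_resp <- stats::plogis(cfg$response_coef[["intercept"]] +
                              cfg$response_coef[["slope"]] * cldn_prop)
    patient$response <- if (is.na(p_resp)) NA_character_ else {
      if (runif(1) < p_resp) "responder" else "non_responder"
    }
  } else {
    patient$iros_months <- NA_real_; patient$iros_event <- NA_integer_
    patient$irpfs_months <- NA_real_; patient$irpfs_event <- NA_integer_
    patient$response <- NA_character_
  }
  list(cells = cells, patient = patient)
}

# Rescale a 0..3 intensity distribution so that P(intensity >= 2) == p_high,
# keeping the conditional shapes within {0,1} and {2,3}.
cldn_dist_for <- function(base, p_high) {
  lo <- base[1:2] / sum(base[1:2])
  hi <- base[3:4] / sum(base[3:4])
  c(lo * (1 - p_high), hi * p_high)
}

empty_cell_tibble <- function() {
  out <- tibble(
    cell_id = character(0), roi_id = character(0), patient_id = character(0),
    region = character(0), x_um = numeric(0), y_um = numeric(0),
    cell_class = character(0)
  )
  for (m in SIM_MARKERS) out[[m]] <- integer(0)
  out
}

simulate_roi <- function(roi_id, pid, region, group, cfg, cldn_dist,
                         immune_scale = 1) {
  W <- cfg$roi_width; H <- cfg$roi_height; area <- W * H
  n_tum <- rpois(1, cfg$tumor_density * area)
  n_imm <- rpois(1, cfg$immune_density * immune_scale * area)
  n_oth <- rpois(1, cfg$other_density * area)

  tx <- runif(n_tum, 0, W); ty <- runif(n_tum, 0, H)
  lineage <- sample(LINEAGES, n_imm, replace = TRUE,
                    prob = cfg$lineage_probs[[group]])
  theta <- cfg$attraction[[group]]
  ix <- runif(n_imm, 0, W); iy <- runif(n_imm, 0, H)
  if (length(theta) > 0L && n_tum > 0L && n_imm > 0L) {
    for (ln in names(theta)) {
      sel <- which(lineage == ln & runif(n_imm) < min(theta[[ln]], 1))
      for (j in sel) {
        repeat {
          anchor <- sample.int(n_tum, 1)
          ang <- runif(1, 0, 2 * pi)
          rad <- cfg$attraction_radius * sqrt(runif(1))
          x <- tx[anchor] + rad * cos(ang); y <- ty[anchor] + rad * sin(ang)
          if (x >= 0 && x <= W && y >= 0 && y <= H) break
        }
        ix[j] <- x; iy[j] <- y
      }
    }
  }
  ox <- runif(n_oth, 0, W); oy <- runif(n_oth, 0, H)

  n <- n_tum + n_imm + n_oth
  out <- tibble(
    cell_id = sprintf("%s-c%04d", roi_id, seq_len(n)),
    roi_id = roi_id, patient_id = pid, region = region,
    x_um = c(tx, ix, ox), y_um = c(ty, iy, oy),
    cell_class = rep(c("tumor", "immune", "other"), c(n_tum, n_imm, n_oth))
  )
  for (m in SIM_MARKERS) out[[m]] <- 0L
  if (n_tum > 0L) {
    out$`CLDN18.2`[seq_len(n_tum)] <- sample(0:3, n_tum, replace = TRUE,
                                             prob = cldn_dist)
  }
  if (n_imm > 0L) {
    idx <- n_tum + seq_len(n_imm)
    cp <- cfg$checkpoint_probs[[group]]
    is_cd8 <- lineage == "CD8T"
    is_cd4 <- lineage == "CD4T"
    is_mac <- lineage == "Macrophage"
    out$CD8[idx] <- as.integer(is_cd8)
    out$`PD-1`[idx] <- as.integer(is_cd8 & runif(n_imm) < cp[["pd1_cd8"]])
    out$`LAG-3`[idx] <- as.integer(is_cd8 & runif(n_imm) < cp[["lag3_cd8"]])
    out$`TIM-3`[idx] <- as.integer(is_cd8 & runif(n_imm) < cp[["tim3_cd8"]])
    out$CD4[idx] <- as.integer(is_cd4)
    out$FoxP3[idx] <- as.integer(is_cd4 & runif(n_imm) < cp[["foxp3_cd4"]])
    out$`CTLA-4`[idx] <- as.integer(is_cd4 & runif(n_imm) < cp[["ctla4_cd4"]])
    out$`PD-L1`[idx] <- as.integer(is_cd4 & runif(n_imm) < cp[["pdl1_cd4"]])
    out$CD20[idx] <- as.integer(lineage == "B")
    out$CD66b[idx] <- as.integer(lineage == "Neutrophil")
    out$CD68[idx] <- as.integer(is_mac)
    is_m1 <- is_mac & runif(n_imm) < cp[["m1_mac"]]
    out$`HLA-DR`[idx] <- as.integer(is_m1)
    out$CD163[idx] <- as.integer(is_mac & !is_m1)
  }
  out
}

#' @export
print.si_cohort <- function(x, ...) {
  cat(sprintf("<si_cohort> %d patients, %d fields, %d cells (seed %s)\n",
              nrow(x$patients), dplyr::n_distinct(x$cells$roi_id),
              nrow(x$cells), format(x$seed)))
  invisible(x)
}

#' A tiny hand-placed field for worked examples
#'
#' Twelve cells at fixed coordinates — four tumor cells (CLDN18.2
#' intensities 3, 2, 1, 0), six CD8 T cells (one PD-1+), one CD4 T cell and
#' one "other" cell — whose 20-micrometer neighbor graph, effective score
#' and percent, and phenotype rates can be counted by hand.
#'
#' @return A cell tibble for one tumor-core field.
#' @export
generate_worked_roi <- function() {
  cells <- tibble(
    cell_id = c("T1", "T2", "T3", "T4",
                "I1", "I2", "I3", "I4", "I5", "I6", "I7", "O1"),
    roi_id = "WORKED-1",
    patient_id = "PW1",
    region = "TC",
    x_um = c(100, 150, 300, 500, 110, 100, 160, 320, 600, 150, 505, 400),
    y_um = c(100, 100, 300, 500, 100, 115, 100, 300, 600, 110, 500, 200),
    cell_class = c(rep("tumor", 4), rep("immune", 7), "other")
  )
  for (m in SIM_MARKERS) cells[[m]] <- 0L
  cells$CD8[5:10] <- 1L          # I1..I6
  cells$`PD-1`[10] <- 1L         # I6
  cells$CD4[11] <- 1L            # I7
  cells$`CLDN18.2`[1:4] <- c(3L, 2L, 1L, 0L)
  cells
}

#' Write a cohort's tables to disk
#'
#' Emits `cells.csv` and `patients.csv` in the exact schemas read back by
#' [read_cell_table()] and [read_patient_table()], plus `panel.yaml` with
#' the default panel.
#'
#' @param cohort An `si_cohort` (or a list with `cells` and `patients`).
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report_table(cohort$cells, file.path(dir, "cells.csv"))
  pts <- cohort$patients
  write_report_table(pts, file.path(dir, "patients.csv"))
  write_panel_config(default_gc_panel(), file.path(dir, "panel.yaml"))
  invisible(dir)
}
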