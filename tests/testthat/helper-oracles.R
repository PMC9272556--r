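# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# textbook formulas.

# O(n^2) all-pairs fixed-radius bipartite edges, as sorted "central|peripheral"
# keys for exact comparison.
bf_edge_keys <- function(central, peripheral, radius) {
  if (nrow(central) == 0L || nrow(peripheral) == 0L) return(character(0))
  d <- sqrt(outer(central$x_um, peripheral$x_um, "-")^2 +
              outer(central$y_um, peripheral$y_um, "-")^2)
  hit <- which(d <= radius, arr.ind = TRUE)
  sort(paste(central$cell_id[hit[, 1]], peripheral$cell_id[hit[, 2]], sep = "|"))
}

graph_edge_keys <- function(g) {
  sort(paste(g$edges$central_id, g$edges$peripheral_id, sep = "|"))
}

# Per-cell, per-rule re-evaluation of a phenotype gate with explicit loops.
bf_phenotype_hit <- function(cell_row, phen) {
  if (phen$cell_class != "any" && cell_row$cell_class != phen$cell_class) {
    return(FALSE)
  }
  for (m in names(phen$positive)) {
    if (cell_row[[m]] < phen$positive[[m]]) return(FALSE)
  }
  for (m in names(phen$negative)) {
    if (cell_row[[m]] > phen$negative[[m]]) return(FALSE)
  }
  TRUE
}

# Textbook pooled two-sample t statistic and two-tailed p.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p_value = 2 * pt(-abs(t), df = na + nb - 2))
}

# Pearson r from the covariance / sigma-sigma definition.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# AUC by brute-force pair counting, ties scoring 1/2.
auc_pair_oracle <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Mantel-Cox log-rank chi-square from the observed-minus-expected table,
# computed with an explicit loop over distinct event times.
logrank_oracle <- function(times_a, events_a, times_b, events_b) {
  tt <- sort(unique(c(times_a[events_a == 1], times_b[events_b == 1])))
  O_a <- 0; E_a <- 0; V <- 0
  for (t in tt) {
    n_a <- sum(times_a >= t); n_b <- sum(times_b >= t)
    d_a <- sum(times_a == t & events_a == 1)
    d_b <- sum(times_b == t & events_b == 1)
    n <- n_a + n_b; d <- d_a + d_b
    O_a <- O_a + d_a
    E_a <- E_a + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  (O_a - E_a)^2 / V
}

# Uniform random bipartite ROI for spatial tests.
random_roi_cells <- function(n_central, n_peripheral, width = 930, height = 700) {
  list(
    central = tibble::tibble(
      cell_id = sprintf("c%04d", seq_len(n_central)),
      x_um = runif(n_central, 0, width), y_um = runif(n_central, 0, height)
    ),
    peripheral = tibble::tibble(
      cell_id = sprintf("p%04d", seq_len(n_peripheral)),
      x_um = runif(n_peripheral, 0, width), y_um = runif(n_peripheral, 0, height)
    )
  )
}

# Minimal two-marker panel for focused gating tests.
tiny_panel <- function() {
  panel(
    markers = c("CD8", "PD-1", "CLDN18.2"),
    phenotypes = list(
      phenotype_def("CD8+", positive = "CD8"),
      phenotype_def("CD8+PD-1-", positive = "CD8", negative = "PD-1"),
      phenotype_def("CD8+PD-1+", positive = c("CD8", "PD-1"))
    )
  )
}

# Bare-bones valid cell tibble; markers default to 0.
make_cells <- function(n, roi_id = "R1", patient_id = "P1", region = "TC",
                       cell_class = "immune", markers = c("CD8", "PD-1", "CLDN18.2"),
                       width = 930, height = 700) {
  d <- tibble::tibble(
    cell_id = sprintf("%s-%03d", roi_id, seq_len(n)),
    roi_id = roi_id, patient_id = patient_id, region = region,
    x_um = runif(n, 0, width), y_um = runif(n, 0, height),
    cell_class = cell_class
  )
  for (m in markers) d[[m]] <- 0L
  d
}
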