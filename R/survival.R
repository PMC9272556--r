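#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator via [survival::survfit()]. The median is the
#' first time at which the survival probability drops to 0.5 or below;
#' when the curve never reaches 0.5 the median is not reached (`NA`).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group Optional label carried into the summary.
#' @return An `si_km` object; see [tidy.si_km()] for the step curve and
#'   [glance.si_km()] for n, events and median.
#' @export
km_estimate <- function(times, events, group = NA_character_) {
  if (length(times) == 0L) abort("km_estimate needs at least one observation")
  if (length(times) != length(events)) abort("times and events must have equal length")
  if (any(is.na(times)) || any(is.na(events))) abort("missing times or events")
  if (any(times < 0)) abort("negative survival time")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  med <- if (any(curve$survival <= 0.5)) min(curve$time[curve$survival <= 0.5]) else NA_real_
  structure(
    list(curve = curve, n = length(times), events = sum(events),
         median_months = med, group = group, fit = fit),
    class = "si_km"
  )
}

#' @export
print.si_km <- function(x, ...) {
  cat(sprintf("<si_km> n = %d, events = %d, median = %s months\n",
              x$n, x$events,
              if (is.na(x$median_months)) "not reached" else format(x$median_months)))
  invisible(x)
}

#' Tidy the Kaplan-Meier step curve
#'
#' @param x An `si_km`.
#' @param ... Unused.
#' @return A tibble of curve steps: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (non-increasing, starting from 1 at time 0).
#' @method tidy si_km
#' @export
tidy.si_km <- function(x, ...) x$curve

#' One-row summary of a Kaplan-Meier fit
#'
#' @param x An `si_km`.
#' @param ... Unused.
#' @return A tibble: `group`, `n`, `events`, `median_months` (`NA` when the
#'   median is not reached).
#' @method glance si_km
#' @export
glance.si_km <- function(x, ...) {
  tibble(group = x$group, n = x$n, events = x$events,
         median_months = x$median_months)
}

#' Log-rank comparison of two survival curves with hazard ratio
#'
#' Mantel-Cox log-rank test ([survival::survdiff()], chi-squared with 1 df,
#' two-tailed) plus the hazard ratio of group B relative to group A from a
#' single-covariate proportional-hazards fit ([survival::coxph()], Efron tie
#' handling) with its 95% confidence interval. When the two samples are
#' identical the statistic is 0, p = 1, and HR = 1.
#'
#' @param times_a,events_a Follow-up times and event flags for group A.
#' @param times_b,events_b Same for group B.
#' @param group_a,group_b Labels carried into the result.
#' @return An `si_logrank`; `tidy()`/`glance()` return the one-row summary.
#' @export
logrank_compare <- function(times_a, events_a, times_b, events_b,
                            group_a = "A", group_b = "B") {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    abort("both groups must be non-empty")
  }
  if (any(c(times_a, times_b) < 0, na.rm = TRUE)) abort("negative survival time")
  ev_a <- as.integer(as.logical(events_a))
  ev_b <- as.integer(as.logical(events_b))
  if (sum(ev_a) + sum(ev_b) == 0L) abort("no events in either group")
  dat <- tibble(
    time = c(times_a, times_b),
    event = c(ev_a, ev_b),
    grp = factor(rep(c(group_a, group_b), c(length(times_a), length(times_b))),
                 levels = c(group_a, group_b))
  )
  identical_groups <- length(times_a) == length(times_b) &&
    isTRUE(all.equal(sort(times_a), sort(times_b))) &&
    sum(ev_a) == sum(ev_b) &&
    isTRUE(all.equal(sort(times_a[ev_a == 1]), sort(times_b[ev_b == 1])))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  chisq <- unname(sd_fit$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (identical_groups) {
    hr <- 1; ci <- c(NA_real_, NA_real_)
    cox <- NULL
  } else {
    cox <- survival::coxph(survival::Surv(time, event) ~ grp, data = dat,
                           ties = "efron")
    beta <- unname(stats::coef(cox))
    se <- sqrt(unname(stats::vcov(cox)[1, 1]))
    hr <- exp(beta)
    ci <- exp(beta + c(-1, 1) * qnorm(0.975) * se)
  }
  structure(
    list(statistic = chisq, p_value = p, hazard_ratio = hr,
         ci_lo = ci[1], ci_hi = ci[2],
         group_a = group_a, group_b = group_b,
         n_a = length(times_a), n_b = length(times_b),
         events_a = sum(ev_a), events_b = sum(ev_b), cox = cox),
    class = "si_logrank"
  )
}

#' @export
print.si_logrank <- function(x, ...) {
  cat(sprintf("<si_logrank> chisq = %.3f (1 df), p = %.4g; HR (%s vs %s) = %.3f [%.3f, %.3f]\n",
              x$statistic, x$p_value, x$group_b, x$group_a,
              x$hazard_ratio, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' @method tidy si_logrank
#' @export
tidy.si_logrank <- function(x, ...) {
  tibble(
    group_a = x$group_a, group_b = x$group_b,
    n_a = x$n_a, n_b = x$n_b, events_a = x$events_a, events_b = x$events_b,
    statistic = x$statistic, p_value = x$p_value,
    hazard_ratio = x$hazard_ratio, ci_lo = x$ci_lo, ci_hi = x$ci_hi
  )
}

#' @method glance si_logrank
#' @export
glance.si_logrank <- function(x, ...) tidy(x)

#' Extract survival endpoints from a patient table
#'
#' Returns one row per available endpoint per patient. OS runs from
#' diagnosis to death or last follow-up; irOS and irPFS run from the start
#' of immunotherapy to death (irOS) or progression (irPFS) or last
#' follow-up, and are present only for patients who received immunotherapy.
#' Endpoints whose time or event flag is missing are omitted rather than
#' imputed.
#'
#' @param patients A patient tibble (see [read_patient_table()]).
#' @return A tibble: `patient_id`, `endpoint` (`"OS"`, `"irOS"`,
#'   `"irPFS"`), `time_months`, `event`.
#' @export
derive_endpoints <- function(patients) {
  spec <- c(OS = "os", irOS = "iros", irPFS = "irpfs")
  out <- purrr::imap(spec, function(prefix, ep) {
    tcol <- paste0(prefix, "_months"); ecol <- paste0(prefix, "_event")
    if (!tcol %in% names(patients) || !ecol %in% names(patients)) return(NULL)
    t <- as.numeric(patients[[tcol]])
    if (any(t < 0, na.rm = TRUE)) abort(sprintf("negative %s", tcol))
    keep <- !is.na(t) & !is.na(patients[[ecol]])
    tibble(
      patient_id = patients$patient_id[keep],
      endpoint = ep,
      time_months = t[keep],
      event = as.integer(as.logical(patients[[ecol]][keep]))
    )
  })
  bind_rows(out)
}

#' Survival report by patient group
#'
#' For each endpoint present in the patient table, fits per-group
#' Kaplan-Meier curves and compares the two groups with the log-rank test
#' and a single-covariate hazard ratio.
#'
#' @param patients A patient tibble with a grouping column.
#' @param group_var Name of the two-level grouping column (default
#'   `"cldn_status"`).
#' @return A list with `summary` (one row per endpoint x group: n, events,
#'   median, plus the test columns repeated per endpoint) and `curves`
#'   (per-endpoint, per-group KM steps).
#' @export
survival_report <- function(patients, group_var = "cldn_status") {
  if (!group_var %in% names(patients)) {
    abort(sprintf("patient table lacks grouping column '%s'", group_var))
  }
  ep <- derive_endpoints(patients) %>%
    left_join(patients %>% select("patient_id", dplyr::all_of(group_var)),
              by = "patient_id") %>%
    rename(group = dplyr::all_of(group_var)) %>%
    filter(!is.na(.data$group))
  groups <- sort(unique(ep$group))
  if (length(groups) != 2L) {
    abort(sprintf("survival_report needs exactly 2 groups, found %d", length(groups)))
  }
  summaries <- list(); curves <- list()
  for (e in unique(ep$endpoint)) {
    d <- ep %>% filter(.data$endpoint == e)
    da <- d %>% filter(.data$group == groups[1])
    db <- d %>% filter(.data$group == groups[2])
    if (nrow(da) < 2L || nrow(db) < 2L) next
    lr <- logrank_compare(da$time_months, da$event, db$time_months, db$event,
                          group_a = groups[1], group_b = groups[2])
    for (g in groups) {
      dg <- if (g == groups[1]) da else db
      km <- km_estimate(dg$time_months, dg$event, group = g)
      summaries[[paste(e, g)]] <- glance(km) %>%
        mutate(endpoint = e, .before = 1) %>%
        mutate(hazard_ratio = lr$hazard_ratio, ci_lo = lr$ci_lo,
               ci_hi = lr$ci_hi, logrank_p = lr$p_value)
      curves[[paste(e, g)]] <- tidy(km) %>%
        mutate(endpoint = e, group = g, .before = 1)
    }
  }
  list(summary = bind_rows(summaries), curves = bind_rows(curves))
}
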