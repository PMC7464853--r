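#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' events and `n_i` at risk at `t_i`. Computed via [survival::survfit()];
#' the returned table is restricted to distinct event times.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return A `km_curve`: data frame `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    surv = fit$surv[keep])
  structure(out, class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' @param times_a,events_a Follow-up and 0/1 event indicator, group A.
#' @param times_b,events_b Same for group B.
#' @return List `chi2` (1-df statistic) and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("log-rank undefined with zero events")
  }
  g <- factor(rep(c("a", "b"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(c(times_a, times_b),
                                          c(events_a, events_b)) ~ g)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit on a binary grouping
#'
#' Partial-likelihood fit (Efron tie handling) of event hazard on a
#' two-level group. The first factor level is the reference, so with
#' levels `c("low", "high")` an HR below 1 means the high group fares
#' better. Reports the hazard ratio with Wald 95% CI and p, plus the
#' log-rank p and per-group Kaplan-Meier curves.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param group Two-level factor (or coercible); both levels must be
#'   present and each must contribute at least one event (otherwise the
#'   partial likelihood is monotone and the fit is refused).
#' @return A `survival_fit`: list with `hr`, `ci` (lower, upper), `beta`,
#'   `se`, `p_wald`, `p_logrank`, `n` (per group), `events` (per group),
#'   `km` (named list of [km_estimate()] curves), `reference`.
#' @export
cox_univariate <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) < 2L) stop("degenerate dichotomization: only one group present")
  if (nlevels(g) > 2L) stop("group must have exactly two levels")
  if (sum(events) == 0) stop("no events in the pooled data")
  ev_by_g <- tapply(events, g, sum)
  if (any(ev_by_g == 0)) {
    stop("monotone partial likelihood: group '",
         names(ev_by_g)[ev_by_g == 0], "' has zero events; the hazard ",
         "ratio is not estimable — pool groups or use exact small-sample methods")
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ g, ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  lr <- logrank_test(times[g == levels(g)[1]], events[g == levels(g)[1]],
                     times[g == levels(g)[2]], events[g == levels(g)[2]])
  km <- lapply(levels(g), function(lv) {
    km_estimate(times[g == lv], events[g == lv])
  })
  names(km) <- levels(g)
  structure(list(hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 beta = beta, se = se,
                 p_wald = 2 * stats::pnorm(-abs(beta / se)),
                 p_logrank = lr$p,
                 n = as.vector(table(g)), events = as.vector(ev_by_g),
                 group_levels = levels(g), reference = levels(g)[1],
                 km = km),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s vs %s [ref]): HR %.3g (95%% CI %.3g-%.3g), Wald p = %.3g, log-rank p = %.3g\n",
              x$group_levels[2], x$reference, x$hr, x$ci[1], x$ci[2],
              x$p_wald, x$p_logrank))
  cat(sprintf("n = %d/%d, events = %d/%d (%s/%s)\n", x$n[1], x$n[2],
              x$events[1], x$events[2], x$group_levels[1], x$group_levels[2]))
  invisible(x)
}

#' Survival comparison of signature-high vs signature-low samples
#'
#' Joins per-sample signature scores ([score_samples()]) to the clinical
#' table (optionally restricted to one subtype first) and runs
#' [cox_univariate()] with the low group as reference.
#'
#' @param ch A [cohort()] (its clinical table is used).
#' @param scores Data frame from [score_samples()] / [joint_gene_score()].
#' @param time_col,event_col Clinical endpoint columns (default
#'   `time`/`event`; point at RFS/OS-specific columns when present).
#' @param subtype Optional subtype label; samples are filtered to it
#'   before the comparison.
#' @param min_coverage Minimum fraction of clinical samples the scores
#'   must cover (default 0.9).
#' @return A `survival_fit`.
#' @export
survival_by_signature <- function(ch, scores, time_col = "time",
                                  event_col = "event", subtype = NULL,
                                  min_coverage = 0.9) {
  clin <- if (inherits(ch, "cohort")) ch$clinical else ch
  stopifnot(inherits(clin, "clinical_table"))
  if (!all(c(time_col, event_col) %in% names(clin))) {
    stop("clinical table lacks endpoint column(s): ",
         paste(setdiff(c(time_col, event_col), names(clin)), collapse = ", "))
  }
  if (!is.null(subtype)) {
    if (!"subtype" %in% names(clin)) stop("clinical table has no subtype column")
    clin <- clin[!is.na(clin$subtype) & clin$subtype == subtype, , drop = FALSE]
    if (nrow(clin) == 0L) stop("subtype filter '", subtype, "' selects zero samples")
  }
  hit <- clin$sample_id %in% scores$sample_id
  if (mean(hit) < min_coverage) {
    stop(sprintf("scores cover only %.0f%% of clinical samples (need >= %.0f%%)",
                 100 * mean(hit), 100 * min_coverage))
  }
  if (any(!hit)) message("survival_by_signature: dropped ", sum(!hit),
                         " clinical sample(s) without scores")
  clin <- clin[hit, , drop = FALSE]
  idx <- match(clin$sample_id, scores$sample_id)
  time <- clin[[time_col]]
  event <- clin[[event_col]]
  ok <- !is.na(time) & !is.na(event)
  if (any(!ok)) message("survival_by_signature: dropped ", sum(!ok),
                        " sample(s) with missing time/event")
  grp <- factor(as.character(scores$group[idx]), levels = c("low", "high"))
  cox_univariate(time[ok], event[ok], grp[ok])
}
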