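# Summary statistics publications report, recomputed from (reconstructed)
# IPD: product-limit survival with Greenwood-based confidence intervals,
# median survival, and the two-arm Cox hazard ratio. All fitting is
# delegated to the survival package (survfit / coxph), the standard
# environment for these estimators; this module fixes the conventions
# (log-scale CI, Efron ties) and returns plain vectors.

km_fit <- function(ipd, conf_type = "log") {
  stopifnot(nrow(ipd) >= 1L)
  survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1,
                    conf.type = conf_type, conf.int = 0.95)
}

#' Kaplan-Meier survival probability at given times
#'
#' Evaluates the product-limit estimate from IPD at the requested times
#' (right-continuous step function), with 95% confidence limits from the
#' Greenwood variance on the log-survival scale (`conf_type = "log"`, the
#' common default) or the complementary log-log scale
#' (`conf_type = "log-log"`).
#'
#' @param ipd data frame with `time` and `event` columns (one arm).
#' @param times numeric vector of evaluation times, `>= 0`.
#' @param conf_type `"log"` or `"log-log"`.
#' @return Data frame `time, estimate, lo95, hi95, truncated`; `truncated`
#'   flags times beyond the last observed follow-up, where the estimate is
#'   carried forward from the last observation.
#' @export
surv_prob <- function(ipd, times, conf_type = "log") {
  stopifnot(all(times >= 0))
  fit <- km_fit(ipd, conf_type)
  s <- summary(fit, times = times, extend = TRUE)
  out <- data.frame(time = times,
                    estimate = s$surv,
                    lo95 = s$lower,
                    hi95 = s$upper,
                    truncated = times > max(ipd$time))
  # before the first event the estimate is exactly 1 with no sampling error
  pre <- out$estimate >= 1
  out$lo95[pre] <- 1
  out$hi95[pre] <- 1
  out
}

#' Median survival time with confidence interval
#'
#' The median is the smallest observed event time at which the survival
#' estimate drops to 0.5 or below; its confidence limits are the smallest
#' times at which the 95% confidence bounds cross 0.5 (the standard
#' product-limit convention). With heavy censoring the median or its upper
#' limit can be undefined and is returned as `NA`.
#'
#' @inheritParams surv_prob
#' @return Named numeric vector `estimate, lo95, hi95` (possibly `NA`).
#' @export
median_surv <- function(ipd, conf_type = "log") {
  fit <- km_fit(ipd, conf_type)
  ev <- fit$n.event > 0
  tt <- fit$time[ev]
  first_at_or_below <- function(v) {
    hit <- which(!is.na(v) & v <= 0.5)
    if (length(hit)) tt[hit[1]] else NA_real_
  }
  c(estimate = first_at_or_below(fit$surv[ev]),
    lo95 = first_at_or_below(fit$lower[ev]),
    hi95 = first_at_or_below(fit$upper[ev]))
}

#' Two-arm Cox proportional-hazards ratio
#'
#' Maximizes the partial likelihood for a single binary treatment
#' covariate, with the Efron correction for tied event times (the reference
#' default; Breslow available for cross-checks). The 95% CI is
#' `exp(logHR +/- 1.96 se)` with the standard error from the observed
#' information.
#'
#' @param ipd data frame with `time`, `event` and `arm` columns containing
#'   exactly two arm labels.
#' @param ref arm label to use as the reference (denominator) group;
#'   defaults to the first label in sort order.
#' @param ties `"efron"` or `"breslow"`.
#' @return Named numeric vector `hr, lo95, hi95, log_hr, se_log_hr`.
#' @export
hazard_ratio <- function(ipd, ref = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  arms <- sort(unique(ipd$arm))
  if (length(arms) != 2L)
    stop("hazard_ratio needs exactly two arms; got ",
         paste(arms, collapse = ", "), call. = FALSE)
  if (sum(ipd$event) < 1L)
    stop("no events in either arm", call. = FALSE)
  ref <- ref %||% arms[1]
  ipd$.group <- factor(ipd$arm, levels = c(ref, setdiff(arms, ref)))
  per_arm_events <- tapply(ipd$event, ipd$.group, sum)
  fit <- survival::coxph(survival::Surv(time, event) ~ .group, data = ipd,
                         ties = ties)
  b <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (any(per_arm_events == 0))
    warning("no events in one arm: hazard ratio is unbounded", call. = FALSE)
  c(hr = exp(b), lo95 = exp(b - 1.96 * se), hi95 = exp(b + 1.96 * se),
    log_hr = b, se_log_hr = se)
}

#' Summary table for one or two reconstructed arms
#'
#' Mirrors the layout publications use: survival probability at requested
#' times per arm, median survival per arm, and (for two arms) the hazard
#' ratio with its CI.
#'
#' @param ipd IPD data frame (`time`, `event`, `arm`) for one or two arms.
#' @param at_times times at which to report survival probabilities.
#' @param conf_type CI transformation for the survival curve, see
#'   [surv_prob()].
#' @return List with per-arm components `surv` and `median`, and `hr` when
#'   two arms are present; class `km_summary_table` with a print method.
#' @export
surv_summary_table <- function(ipd, at_times = numeric(0), conf_type = "log") {
  arms <- sort(unique(ipd$arm))
  per_arm <- lapply(arms, function(a) {
    sub <- ipd[ipd$arm == a, ]
    list(surv = if (length(at_times)) surv_prob(sub, at_times, conf_type),
         median = median_surv(sub, conf_type))
  })
  names(per_arm) <- arms
  out <- list(arms = per_arm,
              hr = if (length(arms) == 2L) hazard_ratio(ipd),
              at_times = at_times)
  class(out) <- "km_summary_table"
  out
}

#' @export
print.km_summary_table <- function(x, digits = 3, ...) {
  for (a in names(x$arms)) {
    cat("Arm '", a, "'\n", sep = "")
    s <- x$arms[[a]]$surv
    if (!is.null(s))
      for (i in seq_len(nrow(s)))
        cat(sprintf("  survival at t=%g: %.*f (%.*f; %.*f)%s\n",
                    s$time[i], digits, s$estimate[i], digits, s$lo95[i],
                    digits, s$hi95[i],
                    if (s$truncated[i]) " [beyond follow-up]" else ""))
    m <- x$arms[[a]]$median
    cat(sprintf("  median survival: %s (%s; %s)\n",
                format(m[["estimate"]], digits = digits),
                format(m[["lo95"]], digits = digits),
                format(m[["hi95"]], digits = digits)))
  }
  if (!is.null(x$hr))
    cat(sprintf("Hazard ratio: %.*f (%.*f; %.*f), se(log HR) = %.*f\n",
                digits, x$hr[["hr"]], digits, x$hr[["lo95"]],
                digits, x$hr[["hi95"]], digits, x$hr[["se_log_hr"]]))
  invisible(x)
}
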