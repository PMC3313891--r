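# Simulated trials with fully known truth, plus a perfect "digitizer",
# so the whole reconstruction pipeline can be validated end to end without
# any published figure. A perfectly digitized curve has a coordinate at
# time zero and at every distinct event time, carrying the exact
# product-limit value -- what an ideal analyst would click.

#' Distribution specifications for simulated trials
#'
#' Small constructors for the event- and censoring-time distributions
#' [simulate_trial()] accepts.
#'
#' @param rate,shape,scale strictly positive parameters.
#' @param max upper bound of the uniform censoring window.
#' @return A list describing the distribution.
#' @name trial_dists
NULL

#' @rdname trial_dists
#' @export
dist_exponential <- function(rate) {
  stopifnot(rate > 0)
  list(dist = "exponential", rate = rate)
}

#' @rdname trial_dists
#' @export
dist_weibull <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  list(dist = "weibull", shape = shape, scale = scale)
}

#' @rdname trial_dists
#' @export
censor_uniform <- function(max) {
  stopifnot(max > 0)
  list(dist = "uniform", max = max)
}

#' @rdname trial_dists
#' @export
censor_exponential <- function(rate) {
  stopifnot(rate > 0)
  list(dist = "exponential", rate = rate)
}

draw_times <- function(n, spec) {
  switch(spec$dist,
         exponential = rexp(n, rate = spec$rate),
         weibull = rweibull(n, shape = spec$shape, scale = spec$scale),
         uniform = runif(n, 0, spec$max),
         stop("unknown distribution '", spec$dist, "'", call. = FALSE))
}

#' Simulate a randomized trial with right-censored event times
#'
#' Event times are drawn per arm from exponential or Weibull distributions;
#' censoring is independent (uniform or exponential), optionally combined
#' with an administrative cutoff. The observed time is the minimum of the
#' event time, the censoring time and the cutoff.
#'
#' @param n_per_arm patients per arm, `>= 2`.
#' @param event_dist a named list of one distribution spec per arm (see
#'   [dist_exponential()], [dist_weibull()]), or a single spec for a
#'   one-arm study.
#' @param censor_dist a censoring spec ([censor_uniform()],
#'   [censor_exponential()]) or `NULL` for no loss to follow-up.
#' @param admin_cutoff administrative end of follow-up (default none).
#' @param seed integer seed; all randomness flows from it.
#' @return List with `ipd` (data frame `time`, `event`, `arm`) and
#'   `counts` (true events and censorings per distinct time and arm).
#' @export
simulate_trial <- function(n_per_arm, event_dist, censor_dist = NULL,
                           admin_cutoff = Inf, seed = NULL) {
  stopifnot(n_per_arm >= 2)
  if (!is.null(event_dist$dist)) event_dist <- list(arm1 = event_dist)
  if (!is.null(seed)) set.seed(seed)
  ipd <- do.call(rbind, lapply(names(event_dist), function(a) {
    ev <- draw_times(n_per_arm, event_dist[[a]])
    cn <- if (is.null(censor_dist)) rep(Inf, n_per_arm)
          else draw_times(n_per_arm, censor_dist)
    cn <- pmin(cn, admin_cutoff)
    data.frame(time = pmin(ev, cn), event = as.integer(ev <= cn), arm = a)
  }))
  rownames(ipd) <- NULL
  counts <- do.call(rbind, lapply(split(ipd, ipd$arm), function(d) {
    tt <- sort(unique(d$time))
    data.frame(arm = d$arm[1], time = tt,
               events = vapply(tt, function(t)
                 sum(d$time == t & d$event == 1L), integer(1)),
               censored = vapply(tt, function(t)
                 sum(d$time == t & d$event == 0L), integer(1)))
  }))
  rownames(counts) <- NULL
  list(ipd = ipd, counts = counts)
}

#' Perfectly digitize a Kaplan-Meier curve from IPD
#'
#' Produces the coordinates an ideal digitizer would extract from the KM
#' plot of one arm: (0, 1), one point per distinct event time carrying the
#' exact product-limit value, and a closing point at the end of follow-up.
#' Additional times (e.g. the times at which numbers at risk will be
#' reported) can be forced into the coordinate list; they carry the
#' step-function value at that time.
#'
#' @param ipd one arm's records (`time`, `event`).
#' @param include_times times that must appear among the coordinates.
#' @param arm arm label for the curve.
#' @return A [km_curve()].
#' @export
exact_digitize <- function(ipd, include_times = NULL, arm = "arm") {
  stopifnot(nrow(ipd) >= 1L)
  fit <- km_fit(ipd)
  ev <- fit$time[fit$n.event > 0]
  sv <- fit$surv[fit$n.event > 0]
  tt <- c(0, ev)
  ss <- c(1, sv)
  tmax <- max(ipd$time)
  extra <- unique(c(include_times, tmax))
  extra <- extra[!vapply(extra, function(t) any(abs(tt - t) < 1e-9),
                         logical(1))]
  # step-function value at each inserted time, read off the event grid
  s_extra <- vapply(extra, function(t) ss[max(which(tt <= t + 1e-9))],
                    numeric(1))
  ord <- order(c(tt, extra))
  km_curve(c(tt, extra)[ord], c(ss, s_extra)[ord], arm = arm)
}

#' Add digitization noise to a curve
#'
#' Emulates human click error: Gaussian jitter on times and survival
#' values, and random dropping of interior steps. The (0, 1) origin is
#' never perturbed, and times listed in `keep_times` (typically the
#' risk-table times) are neither jittered nor dropped. The jittered
#' coordinates are re-sorted and re-monotonized via [repair_curve()]. This
#' is a stand-in noise model: real digitization error is not Gaussian and
#' depends on figure quality.
#'
#' @param curve a [km_curve()].
#' @param time_jitter_sd,prob_jitter_sd standard deviations of the jitter
#'   on times (axis units) and survival probabilities.
#' @param drop_step_prob probability of dropping each interior coordinate.
#' @param keep_times times that must survive unperturbed.
#' @param seed integer seed.
#' @return A repaired [km_curve()].
#' @export
perturb_curve <- function(curve, time_jitter_sd = 0, prob_jitter_sd = 0,
                          drop_step_prob = 0, keep_times = numeric(0),
                          seed = NULL) {
  stopifnot(inherits(curve, "km_curve"),
            time_jitter_sd >= 0, prob_jitter_sd >= 0,
            drop_step_prob >= 0, drop_step_prob < 1)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(curve)
  tm <- curve$time; sv <- curve$surv
  fixed <- c(1L, N, which(vapply(tm, function(t)
    any(abs(keep_times - t) < 1e-9), logical(1))))
  keep <- rep(TRUE, N)
  if (drop_step_prob > 0) {
    keep <- runif(N) >= drop_step_prob
    keep[fixed] <- TRUE
  }
  jit <- setdiff(which(keep), fixed)
  if (length(jit)) {
    tm[jit] <- pmax(0, tm[jit] + rnorm(length(jit), 0, time_jitter_sd))
    sv[jit] <- sv[jit] + rnorm(length(jit), 0, prob_jitter_sd)
  }
  out <- km_curve(tm[keep][order(tm[keep])],
                  sv[keep][order(tm[keep])], arm = attr(curve, "arm"))
  suppressWarnings(repair_curve(out))
}

#' Build the published-style risk table for a simulated arm
#'
#' Computes what the publication would print: the number of subjects still
#' at risk at each requested time, plus the coordinate-row bounds of each
#' reporting interval on the digitized curve, and the true total number of
#' events.
#'
#' @param ipd one arm's true records.
#' @param times reporting times, starting at 0, strictly increasing; each
#'   must appear among the curve's coordinates (pass them to
#'   [exact_digitize()]'s `include_times`).
#' @param curve the digitized curve of the same arm.
#' @return List with `risk` (a [km_risk()]) and `tot_events`.
#' @export
make_risk_table <- function(ipd, times, curve) {
  stopifnot(inherits(curve, "km_curve"))
  if (abs(times[1]) > 1e-9)
    stop("risk times must start at 0", call. = FALSE)
  N <- nrow(curve)
  lower <- vapply(times, function(t) {
    k <- which(abs(curve$time - t) < 1e-9)
    if (!length(k))
      stop("risk time ", t, " is not a curve coordinate; include it when ",
           "digitizing (see exact_digitize(include_times = ))", call. = FALSE)
    as.integer(k[1])
  }, integer(1))
  upper <- c(lower[-1] - 1L, N)
  nrisk <- vapply(times, function(t) sum(ipd$time >= t - 1e-9), integer(1))
  list(risk = km_risk(times, lower, upper, nrisk),
       tot_events = sum(ipd$event))
}
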