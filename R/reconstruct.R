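# Core inversion of the product-limit equations.
#
# The published KM plot is a picture of the underlying KM data: per event
# time, the number at risk n_k, events d_k and censorings cen_k, linked by
# the accounting identity n_{k+1} = n_k - d_k - cen_k and the product-limit
# recursion S_k = S_last * (1 - d_k / n_k). Given digitized coordinates
# (T_k, S_k) and the published numbers at risk, the algorithm guesses a
# censoring count per reporting interval, spreads the censor times uniformly
# (non-informative censoring at constant rate within the interval), solves
# the inverted recursion for integer event counts, and iteratively adjusts
# the censoring count until the implied number at risk at the start of the
# next interval matches the published one. The reported total number of
# events, when available, pins down censoring in the final interval where no
# closing number at risk exists.

#' Initial censoring guess for one reporting interval
#'
#' Under no censoring the number at risk at the start of the next interval
#' would be `nrisk_i` scaled by the conditional survival across the
#' interval; the initial guess for the number censored is the surplus of
#' that over the published `nrisk_{i+1}`, floored at zero (a risk set cannot
#' grow).
#'
#' @param nrisk number at risk at the interval start.
#' @param s_next,s_cur digitized survival at the start of the next and of
#'   the current interval.
#' @param nrisk_next published number at risk at the start of the next
#'   interval.
#' @return Non-negative integer censoring count.
#' @keywords internal
censor_initial_guess <- function(nrisk, s_next, s_cur, nrisk_next) {
  if (s_cur <= 0)
    stop("survival is 0 at the interval start: degenerate curve", call. = FALSE)
  raw <- round_int(s_next / s_cur * nrisk) - as.integer(nrisk_next)
  if (raw < 0L) {
    warning("initial censoring guess ", raw, " clamped to 0", call. = FALSE)
    raw <- 0L
  }
  raw
}

#' Spread censor times evenly over an interval
#'
#' Places `ncensor` times strictly inside `(t_lo, t_hi)` at equal spacing
#' `(t_hi - t_lo) / (ncensor + 1)`, the constant-rate censoring assumption.
#'
#' @param ncensor non-negative count.
#' @param t_lo,t_hi interval endpoints, `t_hi > t_lo`.
#' @return Numeric vector of length `ncensor`.
#' @keywords internal
spread_censor_times <- function(ncensor, t_lo, t_hi) {
  if (ncensor <= 0L) return(numeric(0))
  if (t_hi <= t_lo) stop("censoring interval has non-positive width", call. = FALSE)
  t_lo + seq_len(ncensor) * (t_hi - t_lo) / (ncensor + 1)
}

# Count censor times per coordinate bin [T_k, T_{k+1}), half-open so shared
# endpoints are never double counted; the final bin of the curve is
# right-unbounded. Returns counts plus the times grouped per bin.
bin_censor_times <- function(cen_times, time, k_lo, k_hi) {
  counts <- integer(k_hi - k_lo + 1L)
  groups <- vector("list", k_hi - k_lo + 1L)
  for (j in seq_along(counts)) groups[[j]] <- numeric(0)
  if (length(cen_times)) {
    for (tt in cen_times) {
      j <- findInterval(tt, time[k_lo:k_hi])  # 0 if before T_{k_lo}
      if (j < 1L) j <- 1L
      counts[j] <- counts[j] + 1L
      groups[[j]] <- c(groups[[j]], tt)
    }
  }
  list(counts = counts, times = groups)
}

# Solve the inverted product-limit recursion over coordinates k_lo..k_hi.
# Entry state: n at k_lo, the KM estimate at the most recent event
# coordinate (s_last), and the interval's censoring counts per bin.
# d_hat_k = round(n_k * (1 - S_k / s_last)), clamped to [0, n_k]; the KM
# estimate updates only when events occur. Returns the slice and exit state.
propagate_interval <- function(time, surv, k_lo, k_hi, n_start, cen, s_last) {
  m <- k_hi - k_lo + 1L
  d <- integer(m); nn <- integer(m); skm <- numeric(m)
  cen <- as.integer(cen)
  n_cur <- as.integer(n_start)
  warn <- character(0)
  for (j in seq_len(m)) {
    k <- k_lo + j - 1L
    nn[j] <- n_cur
    if (s_last <= 0 || n_cur <= 0L) {
      if (n_cur <= 0L && surv[k] < s_last - 1e-12)
        warn <- c(warn, sprintf(
          "row %d: risk set exhausted while the curve still falls", k))
      dk <- 0L
    } else {
      dk <- round_int(n_cur * (1 - surv[k] / s_last))
      if (dk < 0L) dk <- 0L
      if (dk > n_cur) dk <- n_cur
    }
    if (dk > 0L) s_last <- s_last * (1 - dk / n_cur)
    d[j] <- dk
    skm[j] <- s_last
    ck <- cen[j]
    if (ck > n_cur - dk) {       # cannot censor more than remain
      warn <- c(warn, sprintf("row %d: censoring count reduced from %d to %d",
                              k, ck, max(0L, n_cur - dk)))
      ck <- max(0L, n_cur - dk)
      cen[j] <- ck
    }
    n_cur <- n_cur - dk - ck
  }
  list(d = d, cen = cen, n = nn, skm = skm,
       n_exit = n_cur, s_last = s_last, warnings = warn)
}

# Steps 2-3 for one interval: spread ncensor times over [t_lo, t_hi), bin
# them, and propagate from the entry state.
run_interval_once <- function(time, surv, k_lo, k_hi, t_hi, n_start,
                              ncensor, s_last) {
  ct <- spread_censor_times(ncensor, time[k_lo], t_hi)
  b <- bin_censor_times(ct, time, k_lo, k_hi)
  pr <- propagate_interval(time, surv, k_lo, k_hi, n_start, b$counts, s_last)
  # propagation may clamp a bin's censoring; keep the stored times in step
  tms <- b$times
  for (j in seq_along(tms))
    if (length(tms[[j]]) > pr$cen[j]) tms[[j]] <- tms[[j]][seq_len(pr$cen[j])]
  pr$cen_times <- tms
  pr
}

# Step 4: iterate the censoring count until the implied number at risk at
# the start of the next interval equals the published one.
fit_interval <- function(time, surv, k_lo, k_hi, t_next, n_start,
                         nrisk_next, ncensor0, s_last, max_iter = 1000L) {
  ncensor <- max(0L, as.integer(ncensor0))
  seen <- integer(0)
  best <- NULL; best_gap <- Inf
  iters <- 0L
  converged <- FALSE
  repeat {
    pr <- run_interval_once(time, surv, k_lo, k_hi, t_next, n_start,
                            ncensor, s_last)
    gap <- pr$n_exit - as.integer(nrisk_next)
    if (abs(gap) < best_gap) { best <- pr; best_gap <- abs(gap); best$ncensor <- ncensor }
    if (gap == 0L) { converged <- TRUE; break }
    iters <- iters + 1L
    if (iters >= max_iter) break
    nxt <- ncensor + gap
    if (nxt < 0L) nxt <- 0L
    if (nxt == ncensor || nxt %in% seen) break  # stalled or cycling
    seen <- c(seen, ncensor)
    ncensor <- nxt
  }
  best$converged <- converged
  best$iterations <- iters
  best$residual <- best_gap
  if (!converged)
    best$warnings <- c(best$warnings, sprintf(
      "interval ending at t=%g: at-risk target %d missed by %d after %d pass(es)",
      t_next, nrisk_next, as.integer(best_gap), iters))
  best
}

# Step 6 censoring count for the closing interval, where no number at risk
# is published at the end: prior censoring total scaled by the span of the
# last interval relative to the time already elapsed, capped at the number
# still at risk entering the interval.
last_interval_censor <- function(time, lower, upper, nint, prior_censor_total,
                                 nrisk_last) {
  span_last <- time[upper[nint]] - time[lower[nint]]
  elapsed <- time[upper[nint - 1L]] - time[lower[1L]]
  raw <- if (elapsed <= 0) 0 else span_last / elapsed * prior_censor_total
  min(round_int(raw), as.integer(nrisk_last))
}

#' Reconstruct Kaplan-Meier data from a digitized published curve
#'
#' Fits the inverted product-limit model to digitized curve coordinates and
#' the published risk information, recovering integer event and censoring
#' counts at every coordinate. Four information levels are supported,
#' matching what publications actually report:
#'
#' * `"all"`: numbers at risk at two or more times *and* the total number
#'   of events. The censoring count in each reporting interval is adjusted
#'   iteratively until the implied number at risk matches the published one;
#'   the final interval is then re-adjusted until the event total matches
#'   `tot_events`.
#' * `"no_totevents"`: numbers at risk only; the final interval's censoring
#'   is extrapolated from the earlier intervals' censoring rate.
#' * `"no_nrisk"`: only the number randomized (one risk row at time 0) plus
#'   `tot_events`; censoring is assumed constant over the whole curve and
#'   adjusted against the event total.
#' * `"neither"`: only the number randomized; no censoring is assumed.
#'
#' With `level = "auto"` (default) the most informative level the inputs
#' support is chosen.
#'
#' @param curve a [km_curve()]; run [repair_curve()] first (done
#'   automatically here, with warnings, unless `repair = FALSE`).
#' @param risk a [km_risk()] table.
#' @param tot_events total number of events in the arm, if published.
#' @param level information level, see Details; `"auto"` picks from the
#'   supplied inputs.
#' @param max_iter cap on censoring re-adjustment passes per interval.
#' @param repair whether to run [repair_curve()] on the inputs first.
#' @return An object of class `km_recon`: a list with components
#'   \describe{
#'     \item{km}{data frame `k, time, n_hat, d_hat, cen_hat, S_km`.}
#'     \item{censor_times}{list of estimated censor times per coordinate.}
#'     \item{intervals}{per-interval summary: censoring count fitted,
#'       iterations, target and achieved numbers at risk.}
#'     \item{level, tot_events, arm}{the inputs used.}
#'     \item{diagnostics}{character vector of warnings accumulated.}
#'   }
#' @examples
#' path <- system.file("extdata", "lrc-rt-curve-0-10.csv", package = "kmrecon")
#' rpath <- system.file("extdata", "lrc-rt-risk-0-10.csv", package = "kmrecon")
#' fit <- km_reconstruct(read_km_curve(path, arm = "rt"), read_risk_table(rpath))
#' fit
#' head(km_ipd(fit))
#' @export
km_reconstruct <- function(curve, risk, tot_events = NULL,
                           level = c("auto", "all", "no_nrisk",
                                     "no_totevents", "neither"),
                           max_iter = 1000L, repair = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(curve, "km_curve"), inherits(risk, "km_risk"))
  if (repair) curve <- repair_curve(curve, risk)
  nint <- nrow(risk)
  if (level == "auto") {
    level <- if (nint >= 2L) {
      if (!is.null(tot_events)) "all" else "no_totevents"
    } else {
      if (!is.null(tot_events)) "no_nrisk" else "neither"
    }
  }
  if (level %in% c("all", "no_nrisk") && is.null(tot_events))
    stop("level '", level, "' needs tot_events", call. = FALSE)
  if (level %in% c("all", "no_totevents") && nint < 2L)
    stop("level '", level, "' needs numbers at risk at two or more times",
         call. = FALSE)
  if (level %in% c("no_nrisk", "neither") && nint != 1L)
    stop("level '", level, "' uses a single risk row (time 0 only); got ",
         nint, call. = FALSE)
  if (!is.null(tot_events) && tot_events < 0)
    stop("tot_events must be non-negative", call. = FALSE)

  tm <- curve$time; sv <- curve$surv
  N <- nrow(curve)
  if (risk$upper[nint] != N)
    stop("the last risk-table interval must close at the final coordinate (row ",
         N, "); got upper = ", risk$upper[nint], call. = FALSE)

  d <- integer(N); cen <- integer(N); nn <- integer(N); skm <- numeric(N)
  cen_times <- rep(list(numeric(0)), N)
  diag_msgs <- character(0)
  iv_summary <- data.frame(interval = risk$interval, time = risk$time,
                           ncensor = 0L, iterations = 0L,
                           nrisk_target = c(risk$nrisk[-1], NA),
                           nrisk_achieved = NA_integer_)

  put_slice <- function(pr, k_lo, k_hi) {
    idx <- k_lo:k_hi
    d[idx] <<- pr$d; cen[idx] <<- pr$cen; nn[idx] <<- pr$n; skm[idx] <<- pr$skm
    cen_times[idx] <<- pr$cen_times
    diag_msgs <<- c(diag_msgs, pr$warnings)
  }

  n_entry <- as.integer(risk$nrisk[1])
  s_last <- 1
  ncensor_fit <- integer(nint)

  if (level %in% c("all", "no_totevents")) {
    for (i in seq_len(nint - 1L)) {
      k_lo <- risk$lower[i]; k_hi <- risk$upper[i]
      k_next <- risk$lower[i + 1L]
      guess <- suppressWarnings(
        censor_initial_guess(n_entry, sv[k_next], sv[k_lo], risk$nrisk[i + 1L]))
      fi <- fit_interval(tm, sv, k_lo, k_hi, tm[k_next], n_entry,
                         risk$nrisk[i + 1L], guess, s_last, max_iter)
      put_slice(fi, k_lo, k_hi)
      ncensor_fit[i] <- fi$ncensor
      iv_summary$ncensor[i] <- fi$ncensor
      iv_summary$iterations[i] <- fi$iterations
      iv_summary$nrisk_achieved[i] <- fi$n_exit
      n_entry <- fi$n_exit
      s_last <- fi$s_last
    }
    # closing interval: no published number at risk at its end
    k_lo <- risk$lower[nint]; k_hi <- risk$upper[nint]
    nc_last <- if (k_hi > k_lo) {
      last_interval_censor(tm, risk$lower, risk$upper, nint,
                           sum(ncensor_fit[seq_len(nint - 1L)]), n_entry)
    } else 0L
    entry_last <- list(n = n_entry, s = s_last)
    pr <- run_interval_once(tm, sv, k_lo, k_hi, tm[k_hi], n_entry,
                            if (k_hi > k_lo) nc_last else 0L, s_last)
    put_slice(pr, k_lo, k_hi)
    ncensor_fit[nint] <- if (k_hi > k_lo) nc_last else 0L
    iv_summary$ncensor[nint] <- ncensor_fit[nint]

    if (level == "all") {
      res <- match_total_events(tm, sv, risk, tot_events, entry_last,
                                ncensor_fit[nint], d, max_iter)
      if (!is.null(res)) {
        put_slice(res, k_lo, k_hi)
        ncensor_fit[nint] <- res$ncensor
        iv_summary$ncensor[nint] <- res$ncensor
        iv_summary$iterations[nint] <- res$iterations
      }
    }
  } else {
    # single interval spanning the whole curve
    k_lo <- 1L; k_hi <- N
    nc <- 0L
    pr <- run_interval_once(tm, sv, k_lo, k_hi, tm[N], n_entry, nc, s_last)
    if (level == "no_nrisk") {
      res <- adjust_censor_to_events(
        function(ncen) run_interval_once(tm, sv, k_lo, k_hi, tm[N], n_entry,
                                         ncen, s_last),
        nc, tot_events, offset_events = 0L, max_iter = max_iter)
      pr <- res
      nc <- res$ncensor
      iv_summary$iterations[1] <- res$iterations
    }
    put_slice(pr, k_lo, k_hi)
    ncensor_fit[1] <- nc
    iv_summary$ncensor[1] <- nc
  }

  if (!is.null(tot_events) && level %in% c("all", "no_nrisk")) {
    if (sum(d) != tot_events)
      diag_msgs <- c(diag_msgs, sprintf(
        "event total %d does not meet reported %d (censoring exhausted)",
        sum(d), as.integer(tot_events)))
  }

  out <- list(km = data.frame(k = seq_len(N), time = tm, n_hat = nn,
                              d_hat = d, cen_hat = cen, S_km = skm),
              censor_times = cen_times,
              intervals = iv_summary,
              level = level,
              tot_events = if (is.null(tot_events)) NA_integer_
                           else as.integer(tot_events),
              arm = attr(curve, "arm") %||% "arm",
              curve = curve, risk = risk,
              diagnostics = diag_msgs)
  class(out) <- "km_recon"
  out
}

# Shared Step-8 loop: adjust a censoring count until the implied event total
# matches the reported one, or censoring hits zero, or the iteration cap.
# run_fn(ncensor) performs Steps 2-3 and returns a propagate result;
# offset_events is the event count accrued before the segment run_fn covers.
adjust_censor_to_events <- function(run_fn, ncensor0, tot_events,
                                    offset_events, max_iter = 1000L) {
  ncensor <- max(0L, as.integer(ncensor0))
  tot_events <- as.integer(tot_events)
  seen <- integer(0)
  best <- NULL; best_gap <- Inf
  iters <- 0L; converged <- FALSE
  repeat {
    pr <- run_fn(ncensor)
    total <- offset_events + sum(pr$d)
    gap <- total - tot_events
    if (abs(gap) < best_gap) { best <- pr; best_gap <- abs(gap); best$ncensor <- ncensor }
    if (gap == 0L) { converged <- TRUE; break }
    if (gap < 0L && ncensor == 0L) break  # short of events, nothing to free
    iters <- iters + 1L
    if (iters >= max_iter) break
    nxt <- ncensor + gap
    if (nxt < 0L) nxt <- 0L
    if (nxt == ncensor || nxt %in% seen) break
    seen <- c(seen, ncensor)
    ncensor <- nxt
  }
  best$converged <- converged
  best$iterations <- iters
  best$residual <- best_gap
  if (!converged)
    best$warnings <- c(best$warnings, sprintf(
      "event total off by %d after %d adjustment pass(es)",
      as.integer(best_gap), iters))
  best
}

# Steps 7-8 for the 'all information' level: returns a refit slice for the
# last interval (zeroed out when events accrued earlier already reach the
# reported total).
match_total_events <- function(time, surv, risk, tot_events, entry_last,
                               ncensor_last, d_full, max_iter = 1000L) {
  nint <- nrow(risk)
  k_lo <- risk$lower[nint]; k_hi <- risk$upper[nint]
  before <- sum(d_full[seq_len(k_lo - 1L)])
  if (before >= tot_events) {
    # Step 7: no more events or censoring in the last interval
    m <- k_hi - k_lo + 1L
    pr <- list(d = integer(m), cen = integer(m),
               n = rep(as.integer(entry_last$n), m),
               skm = rep(entry_last$s, m),
               n_exit = as.integer(entry_last$n), s_last = entry_last$s,
               cen_times = rep(list(numeric(0)), m),
               warnings = if (before > tot_events) sprintf(
                 "events before the last interval (%d) already exceed the reported total (%d)",
                 before, as.integer(tot_events)) else character(0))
    pr$ncensor <- 0L; pr$iterations <- 0L; pr$converged <- TRUE
    return(pr)
  }
  adjust_censor_to_events(
    function(ncen) run_interval_once(time, surv, k_lo, k_hi, time[k_hi],
                                     entry_last$n, ncen, entry_last$s),
    ncensor_last, tot_events, offset_events = before, max_iter = max_iter)
}

#' Derive individual patient data from a reconstruction
#'
#' Emits one record per patient: `d_hat_k` event records at each coordinate
#' time, censoring records at their estimated censor times, and the patients
#' still at risk after the final coordinate censored there (administrative
#' end of follow-up), so the records account for every randomized patient.
#'
#' @param x a `km_recon` fit.
#' @return Data frame with columns `time`, `event` (1 event / 0 censored),
#'   `arm`; `nrow` equals the number at risk at time 0.
#' @export
km_ipd <- function(x) {
  stopifnot(inherits(x, "km_recon"))
  km <- x$km
  ev_t <- rep(km$time, km$d_hat)
  cn_t <- unlist(x$censor_times, use.names = FALSE)
  if (is.null(cn_t)) cn_t <- numeric(0)
  N <- nrow(km)
  left <- km$n_hat[N] - km$d_hat[N] - km$cen_hat[N]
  out <- data.frame(
    time = c(ev_t, cn_t, rep(km$time[N], left)),
    event = c(rep(1L, length(ev_t)), rep(0L, length(cn_t) + left)),
    arm = x$arm)
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  out
}
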