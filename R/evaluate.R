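# Accuracy and reproducibility machinery: mean error (systematic bias),
# mean absolute error (magnitude of error, with Monte-Carlo predictive
# intervals), and a gauge-R&R-style variance decomposition of
# reconstructed-minus-reference differences into exemplar, observer and
# residual components. Survival probabilities are compared on the natural
# scale; medians, hazard ratios and their standard errors on the log scale.

#' Mean error with normal-theory confidence interval
#'
#' @param diffs numeric vector of reconstructed-minus-reference
#'   differences, length `>= 2`.
#' @return Named vector `me, lo95, hi95`.
#' @export
mean_error <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("mean_error needs at least 2 differences", call. = FALSE)
  me <- mean(diffs)
  se <- sd(diffs) / sqrt(length(diffs))
  c(me = me, lo95 = me - 1.96 * se, hi95 = me + 1.96 * se)
}

#' Mean absolute error with Monte-Carlo interval
#'
#' The point estimate is the mean of `|diffs|`. The interval is predictive:
#' assuming errors are normal with the observed mean and variance, `n_mc`
#' draws are taken, folded to absolute values, and the 2.5th/97.5th
#' percentiles reported -- so 97.5% of individual errors are expected to
#' fall below the upper limit.
#'
#' @inheritParams mean_error
#' @param n_mc number of Monte-Carlo draws.
#' @param seed integer seed for the draws.
#' @return Named vector `mae, lo95, hi95`.
#' @export
mean_abs_error <- function(diffs, n_mc = 150000L, seed = NULL) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("mean_abs_error needs at least 2 differences", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- abs(rnorm(n_mc, mean(diffs), sd(diffs)))
  q <- quantile(draws, c(0.025, 0.975), names = FALSE)
  c(mae = mean(abs(diffs)), lo95 = q[1], hi95 = q[2])
}

#' Variance components of a balanced exemplar-by-observer layout
#'
#' Fits the two-way random-effects ANOVA (exemplar, observer, their
#' interaction, within-cell error) to the differences and solves the
#' expected-mean-square equations for the variance components. When the
#' interaction F-test is not significant at `pool_p` (or when there is a
#' single replicate per cell) the interaction is pooled into the error
#' term. Negative moment estimates are clamped to zero. *Reproducibility*
#' is the error a single observer's single reconstruction carries:
#' `sigma_r^2` = within + between-observer (+ interaction when unpooled).
#'
#' Confidence intervals come from Monte-Carlo resampling: for each source,
#' degrees of freedom are drawn from the chi-square distribution with the
#' source's df, mean squares are re-formed as SS / df*, and the components
#' re-solved `n_mc` times; the 2.5th/97.5th percentiles are reported.
#'
#' @param data data frame with columns `exemplar`, `observer`, `value`
#'   (equal replicate counts in every exemplar-by-observer cell).
#' @param pool_p p-value threshold above which the interaction is pooled
#'   into error (default 10%).
#' @inheritParams mean_abs_error
#' @return Object of class `km_varcomp`: list with `sigma_r` and `sigma_e`
#'   (each `estimate, lo95, hi95`), the per-source `components`
#'   (variances), `pooled`, `p_interaction` and the `anova` table.
#' @export
variance_components <- function(data, pool_p = 0.10, n_mc = 150000L,
                                seed = NULL) {
  stopifnot(all(c("exemplar", "observer", "value") %in% names(data)))
  ex <- factor(data$exemplar)
  ob <- factor(data$observer)
  cells <- table(ex, ob)
  if (length(unique(as.vector(cells))) != 1L || any(cells == 0)) {
    bad <- which(cells != as.vector(cells)[1], arr.ind = TRUE)[1, ]
    stop("unbalanced layout: cell (exemplar ", rownames(cells)[bad[1]],
         ", observer ", colnames(cells)[bad[2]], ") has ",
         cells[bad[1], bad[2]], " replicate(s)", call. = FALSE)
  }
  a <- nlevels(ex); b <- nlevels(ob); r <- as.vector(cells)[1]
  if (a < 2L || b < 1L)
    stop("need at least 2 exemplars", call. = FALSE)

  fit <- aov(value ~ ex * ob, data = data.frame(value = data$value, ex, ob))
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  rn <- trimws(rownames(tab))
  ss_e <- ss[rn == "ex"]; df_e <- df[rn == "ex"]
  ss_o <- if (b > 1L) ss[rn == "ob"] else 0
  df_o <- if (b > 1L) df[rn == "ob"] else 0L
  ss_i <- if (b > 1L) ss[rn == "ex:ob"] else 0
  df_i <- if (b > 1L) df[rn == "ex:ob"] else 0L
  ss_w <- if (any(rn == "Residuals")) ss[rn == "Residuals"] else 0
  df_w <- if (any(rn == "Residuals")) df[rn == "Residuals"] else 0L
  # with r = 1 aov labels the interaction stratum "Residuals"
  if (r == 1L && b > 1L) { ss_i <- ss_w; df_i <- df_w; ss_w <- 0; df_w <- 0L }

  p_int <- if (df_i > 0L && df_w > 0L)
    pf((ss_i / df_i) / (ss_w / df_w), df_i, df_w, lower.tail = FALSE)
  else NA_real_
  pooled <- is.na(p_int) || p_int > pool_p

  solve_comp <- function(ms_e, ms_o, ms_i, ms_w, ms_pool) {
    if (pooled) {
      v_w <- ms_pool
      v_i <- 0
      v_o <- if (b > 1L) (ms_o - ms_pool) / (a * r) else 0
      v_e <- (ms_e - ms_pool) / (b * r)
    } else {
      v_w <- ms_w
      v_i <- (ms_i - ms_w) / r
      v_o <- (ms_o - ms_i) / (a * r)
      v_e <- (ms_e - ms_i) / (b * r)
    }
    pmax(c(exemplar = v_e, observer = v_o, interaction = v_i, within = v_w), 0)
  }

  ss_pool <- ss_i + ss_w; df_pool <- df_i + df_w
  comp <- solve_comp(ss_e / df_e,
                     if (df_o > 0L) ss_o / df_o else 0,
                     if (df_i > 0L) ss_i / df_i else 0,
                     if (df_w > 0L) ss_w / df_w else 0,
                     if (df_pool > 0L) ss_pool / df_pool else 0)
  sigma_r_hat <- sqrt(comp[["within"]] + comp[["observer"]] +
                        comp[["interaction"]])
  sigma_e_hat <- sqrt(comp[["exemplar"]])

  if (!is.null(seed)) set.seed(seed)
  ms_draw <- function(ss_s, df_s) {
    if (df_s <= 0L) return(rep(0, n_mc))
    ss_s / rchisq(n_mc, df_s)
  }
  d_e <- ms_draw(ss_e, df_e); d_o <- ms_draw(ss_o, df_o)
  d_i <- ms_draw(ss_i, df_i); d_w <- ms_draw(ss_w, df_w)
  d_p <- ms_draw(ss_pool, df_pool)
  sig_r <- numeric(n_mc); sig_e <- numeric(n_mc)
  for (s in seq_len(n_mc)) {
    cs <- solve_comp(d_e[s], d_o[s], d_i[s], d_w[s], d_p[s])
    sig_r[s] <- sqrt(cs[["within"]] + cs[["observer"]] + cs[["interaction"]])
    sig_e[s] <- sqrt(cs[["exemplar"]])
  }
  qr_ <- quantile(sig_r, c(0.025, 0.975), names = FALSE)
  qe_ <- quantile(sig_e, c(0.025, 0.975), names = FALSE)

  out <- list(sigma_r = c(estimate = sigma_r_hat, lo95 = qr_[1], hi95 = qr_[2]),
              sigma_e = c(estimate = sigma_e_hat, lo95 = qe_[1], hi95 = qe_[2]),
              components = comp, pooled = pooled, p_interaction = p_int,
              anova = data.frame(source = c("exemplar", "observer",
                                            "interaction", "within"),
                                 ss = c(ss_e, ss_o, ss_i, ss_w),
                                 df = c(df_e, df_o, df_i, df_w)),
              layout = c(exemplars = a, observers = b, replicates = r))
  class(out) <- "km_varcomp"
  out
}

#' @export
print.km_varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components (%d exemplars x %d observers x %d replicates)\n",
              x$layout[1], x$layout[2], x$layout[3]))
  cat(sprintf("  interaction %s (p = %s)\n",
              if (x$pooled) "pooled into error" else "kept",
              format(x$p_interaction, digits = 3)))
  cat(sprintf("  sigma_r (reproducibility): %.*f (%.*f; %.*f)\n",
              digits, x$sigma_r[1], digits, x$sigma_r[2], digits, x$sigma_r[3]))
  cat(sprintf("  sigma_e (exemplar):        %.*f (%.*f; %.*f)\n",
              digits, x$sigma_e[1], digits, x$sigma_e[2], digits, x$sigma_e[3]))
  invisible(x)
}

# ---- full-pipeline recovery study ------------------------------------------

risk_inputs_for_level <- function(level, risk, tot_events, N, n0) {
  switch(level,
         all = list(risk = risk, tot = tot_events),
         no_totevents = list(risk = risk, tot = NULL),
         no_nrisk = list(risk = km_risk(0, 1, N, n0), tot = tot_events),
         neither = list(risk = km_risk(0, 1, N, n0), tot = NULL),
         stop("unknown level '", level, "'", call. = FALSE))
}

reconstruct_arm_at_level <- function(level, curve, risk, tot_events) {
  inp <- risk_inputs_for_level(level, risk, tot_events, nrow(curve),
                               risk$nrisk[1])
  lev <- switch(level, all = "all", no_totevents = "no_totevents",
                no_nrisk = "no_nrisk", neither = "neither")
  suppressWarnings(
    km_reconstruct(curve, inp$risk, tot_events = inp$tot, level = lev,
                   repair = FALSE))
}

#' Run the accuracy/reproducibility study on simulated trials
#'
#' For each simulated two-arm trial ("exemplar") and each emulated observer
#' (a digitization-noise replicate), the full pipeline runs at every
#' requested information level: perfect digitization (+ optional noise),
#' risk-table construction, reconstruction, IPD derivation, and
#' recomputation of survival probabilities, medians, hazard ratio and its
#' log-scale standard error. Differences against the statistics computed
#' from the true IPD are summarised per (level, statistic) as mean error
#' and mean absolute error, with variance components when two or more
#' observers are emulated. The human observers of a manual-digitization
#' study are emulated here by independent noise seeds; with `noise = NULL`
#' every "observer" is identical.
#'
#' @param n_exemplars number of simulated trials.
#' @param trial arguments for [simulate_trial()] shared by all exemplars
#'   (a list: `n_per_arm`, `event_dist`, `censor_dist`, `admin_cutoff`).
#' @param info_levels subset of
#'   `c("all", "no_nrisk", "no_totevents", "neither")`.
#' @param at_fracs quantiles of each trial's observed times at which
#'   survival probabilities are compared.
#' @param n_risk_times number of risk-table reporting times (including 0).
#' @param observers number of emulated observers.
#' @param noise `NULL`, or a list of [perturb_curve()] arguments
#'   (`time_jitter_sd`, `prob_jitter_sd`, `drop_step_prob`).
#' @param n_mc Monte-Carlo draws for the MAE intervals.
#' @param seed master seed; every random element derives from it.
#' @return Object of class `recovery_report`: list with `report` (one row
#'   per level x statistic: n, ME and MAE with intervals, sigma_r, sigma_e)
#'   and `diffs` (the long per-comparison table).
#' @export
recovery_study <- function(n_exemplars = 6,
                           trial = list(n_per_arm = 150,
                                        event_dist = list(
                                          a = dist_exponential(0.10),
                                          b = dist_exponential(0.06)),
                                        censor_dist = censor_uniform(6),
                                        admin_cutoff = Inf),
                           info_levels = c("all", "no_nrisk",
                                           "no_totevents", "neither"),
                           at_fracs = c(0.25, 0.5),
                           n_risk_times = 6,
                           observers = 1,
                           noise = NULL,
                           n_mc = 10000L,
                           seed = 1L) {
  set.seed(seed)
  ex_seeds <- sample.int(.Machine$integer.max - 1L, n_exemplars)
  ob_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                n_exemplars * observers),
                     nrow = n_exemplars)
  rows <- list()
  for (e in seq_len(n_exemplars)) {
    sim <- do.call(simulate_trial, c(trial, list(seed = ex_seeds[e])))
    ipd <- sim$ipd
    arms <- sort(unique(ipd$arm))
    at_times <- unname(quantile(ipd$time, at_fracs))
    for (o in seq_len(observers)) {
      digitized <- lapply(arms, function(a) {
        tru <- ipd[ipd$arm == a, ]
        rts <- unname(quantile(tru$time,
                               seq(0, 0.9, length.out = n_risk_times)))
        rts[1] <- 0
        cv <- exact_digitize(tru, include_times = rts, arm = a)
        if (!is.null(noise))
          cv <- do.call(perturb_curve,
                        c(list(curve = cv, keep_times = rts,
                               seed = ob_seeds[e, o]), noise))
        c(list(curve = cv), make_risk_table(tru, rts, cv))
      })
      recon_by_level <- lapply(info_levels, function(lv) {
        do.call(rbind, lapply(digitized, function(dg) {
          km_ipd(reconstruct_arm_at_level(lv, dg$curve, dg$risk,
                                          dg$tot_events))
        }))
      })
      names(recon_by_level) <- info_levels
      ref <- compare_stats(ipd, at_times)
      for (lv in info_levels) {
        rec <- compare_stats(recon_by_level[[lv]], at_times)
        m <- merge(ref, rec, by = c("statistic", "item"),
                   suffixes = c("_ref", "_rec"))
        m$diff <- ifelse(m$statistic == "survprob",
                         m$value_rec - m$value_ref,
                         log(m$value_rec) - log(m$value_ref))
        rows[[length(rows) + 1L]] <-
          data.frame(exemplar = e, observer = o, level = lv,
                     statistic = m$statistic, item = m$item,
                     reference = m$value_ref, reconstructed = m$value_rec,
                     diff = m$diff)
      }
    }
  }
  diffs <- do.call(rbind, rows)
  report <- summarize_recovery(diffs, n_mc = n_mc, seed = seed,
                               observers = observers)
  structure(list(report = report, diffs = diffs), class = "recovery_report")
}

# One arm-level statistic set: survival probabilities at the given times,
# medians per arm, HR and se(log HR) across the two arms.
compare_stats <- function(ipd, at_times) {
  arms <- sort(unique(ipd$arm))
  out <- list()
  for (a in arms) {
    sub <- ipd[ipd$arm == a, ]
    sp <- surv_prob(sub, at_times)
    out[[length(out) + 1L]] <-
      data.frame(statistic = "survprob",
                 item = paste0(a, "@t", seq_along(at_times)),
                 value = sp$estimate)
    med <- median_surv(sub)[["estimate"]]
    out[[length(out) + 1L]] <-
      data.frame(statistic = "median", item = a, value = med)
  }
  if (length(arms) == 2L && sum(ipd$event) > 0) {
    hr <- suppressWarnings(hazard_ratio(ipd))
    out[[length(out) + 1L]] <-
      data.frame(statistic = c("hr", "se_log_hr"), item = "a_vs_b",
                 value = c(hr[["hr"]], hr[["se_log_hr"]]))
  }
  do.call(rbind, out)
}

summarize_recovery <- function(diffs, n_mc, seed, observers) {
  out <- list()
  for (lv in unique(diffs$level)) {
    for (st in unique(diffs$statistic)) {
      d <- diffs[diffs$level == lv & diffs$statistic == st, ]
      v <- d$diff[is.finite(d$diff)]
      if (length(v) < 2L) next
      me <- mean_error(v)
      mae <- mean_abs_error(v, n_mc = n_mc, seed = seed)
      sr <- c(NA_real_, NA_real_); se_ <- c(NA_real_, NA_real_)
      if (observers >= 2L) {
        vc <- try(variance_components(
          data.frame(exemplar = paste(d$exemplar, d$item),
                     observer = d$observer, value = d$diff),
          n_mc = n_mc, seed = seed), silent = TRUE)
        if (!inherits(vc, "try-error")) {
          sr <- c(vc$sigma_r[["estimate"]], NA_real_)
          se_ <- c(vc$sigma_e[["estimate"]], NA_real_)
        }
      }
      out[[length(out) + 1L]] <-
        data.frame(level = lv, statistic = st, n = length(v),
                   me = me[["me"]], me_lo = me[["lo95"]], me_hi = me[["hi95"]],
                   mae = mae[["mae"]], mae_lo = mae[["lo95"]],
                   mae_hi = mae[["hi95"]],
                   sigma_r = sr[1], sigma_e = se_[1])
    }
  }
  do.call(rbind, out)
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat("Reconstruction recovery study\n")
  print(format(x$report, digits = digits), row.names = FALSE)
  invisible(x)
}
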