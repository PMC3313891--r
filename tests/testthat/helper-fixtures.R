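# Shared fixtures and independent oracles.

# The published worked example: digitized radiotherapy-arm coordinates over
# the first risk interval (0-10 months) and the matching risk rows.
we_curve <- function() {
  read_km_curve(system.file("extdata", "lrc-rt-curve-0-10.csv",
                            package = "kmrecon"), arm = "rt")
}

we_risk <- function() {
  read_risk_table(system.file("extdata", "lrc-rt-risk-0-10.csv",
                              package = "kmrecon"))
}

we_risk_full <- function() {
  read_risk_table(system.file("extdata", "lrc-rt-risk-full.csv",
                              package = "kmrecon"))
}

# Simulate one arm, perfectly digitize it with risk times at the given
# quantiles, and reconstruct at the requested information level.
pipeline_arm <- function(tru, level, probs = seq(0, 0.9, length.out = 6)) {
  rts <- unname(quantile(tru$time, probs))
  rts[1] <- 0
  cv <- exact_digitize(tru, include_times = rts, arm = tru$arm[1])
  rt <- make_risk_table(tru, rts, cv)
  kmrecon:::reconstruct_arm_at_level(level, cv, rt$risk, rt$tot_events)
}

# Independent brute-force product-limit estimator: loops over distinct
# event times, no survfit anywhere.
brute_km <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ev))
  for (i in seq_along(ev)) {
    n_at <- sum(time >= ev[i])
    d <- sum(time == ev[i] & event == 1)
    s <- s * (1 - d / n_at)
    surv[i] <- s
  }
  list(time = ev, surv = surv)
}

brute_km_at <- function(time, event, t) {
  bk <- brute_km(time, event)
  if (!length(bk$time) || t < bk$time[1]) return(1)
  bk$surv[max(which(bk$time <= t))]
}

# Hand-written two-group Cox partial log-likelihood (untied data) and a
# golden-section maximizer, the 1-D oracle for hazard_ratio().
cox_pl <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[at_risk])))
  }
  ll
}

cox_grid_mle <- function(time, event, z, lo = -8, hi = 8, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- cox_pl(x1, time, event, z); f2 <- cox_pl(x2, time, event, z)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- cox_pl(x2, time, event, z)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- cox_pl(x1, time, event, z)
    }
  }
  (a + b) / 2
}

# Random small IPD with distinct times (so Efron and the untied oracle
# coincide).
random_ipd <- function(n, arm = "a") {
  data.frame(time = round(sort(runif(n, 0.1, 20)) + seq_len(n) * 1e-4, 6),
             event = rbinom(n, 1, 0.7),
             arm = arm)
}

# Closed-form expected-mean-square solution for a balanced two-way random
# layout, computed from raw cell means (independent of aov).
ems_oracle <- function(df, pool_p = 0.10) {
  ex <- factor(df$exemplar); ob <- factor(df$observer); y <- df$value
  a <- nlevels(ex); b <- nlevels(ob); r <- nrow(df) / (a * b)
  g <- mean(y)
  mi <- tapply(y, ex, mean); mj <- tapply(y, ob, mean)
  mij <- tapply(y, list(ex, ob), mean)
  ss_e <- b * r * sum((mi - g)^2)
  ss_o <- a * r * sum((mj - g)^2)
  ss_i <- r * sum((mij - outer(mi, rep(1, b)) - outer(rep(1, a), mj) + g)^2)
  ss_w <- sum((y - mij[cbind(ex, ob)])^2)
  df_e <- a - 1; df_o <- b - 1; df_i <- (a - 1) * (b - 1); df_w <- a * b * (r - 1)
  p_int <- if (df_w > 0) pf((ss_i / df_i) / (ss_w / df_w), df_i, df_w,
                            lower.tail = FALSE) else NA_real_
  pooled <- is.na(p_int) || p_int > pool_p
  if (pooled) {
    ms_p <- (ss_i + ss_w) / (df_i + df_w)
    v_w <- ms_p; v_i <- 0
    v_o <- (ss_o / df_o - ms_p) / (a * r)
    v_e <- (ss_e / df_e - ms_p) / (b * r)
  } else {
    ms_w <- ss_w / df_w; ms_i <- ss_i / df_i
    v_w <- ms_w; v_i <- (ms_i - ms_w) / r
    v_o <- (ss_o / df_o - ms_i) / (a * r)
    v_e <- (ss_e / df_e - ms_i) / (b * r)
  }
  comp <- pmax(c(exemplar = v_e, observer = v_o, interaction = v_i,
                 within = v_w), 0)
  list(components = comp, pooled = pooled, p_interaction = p_int,
       sigma_r = sqrt(comp[["within"]] + comp[["observer"]] +
                        comp[["interaction"]]),
       sigma_e = sqrt(comp[["exemplar"]]))
}

# Conservation identities every reconstruction must satisfy.
expect_conservation <- function(fit) {
  km <- fit$km
  N <- nrow(km)
  expect_identical(km$n_hat[-1],
                   (km$n_hat - km$d_hat - km$cen_hat)[-N])
  left <- km$n_hat[N] - km$d_hat[N] - km$cen_hat[N]
  expect_gte(left, 0)
  expect_identical(sum(km$d_hat) + sum(km$cen_hat) + left, km$n_hat[1])
  ipd <- km_ipd(fit)
  expect_identical(nrow(ipd), km$n_hat[1])
}
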