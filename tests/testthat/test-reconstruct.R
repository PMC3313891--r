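test_that("initial censoring guess inverts the no-censoring risk projection", {
  # worked-example interval 1: round(0.608 * 213) - 122 = 8
  expect_identical(kmrecon:::censor_initial_guess(213, 0.608, 1.0, 122), 8L)
  # survival drop fully explains the risk-set change
  expect_identical(kmrecon:::censor_initial_guess(100, 0.5, 1.0, 50), 0L)
  # negative raw guess is clamped at zero with a warning
  expect_warning(g <- kmrecon:::censor_initial_guess(100, 0.9, 1.0, 95),
                 "clamped")
  expect_identical(g, 0L)
  expect_error(kmrecon:::censor_initial_guess(100, 0.5, 0, 50), "degenerate")
})

test_that("censor times are spread evenly and strictly inside the interval", {
  expect_equal(kmrecon:::spread_censor_times(1, 0, 10), 5)
  expect_equal(kmrecon:::spread_censor_times(3, 0, 10), c(2.5, 5, 7.5))
  expect_equal(kmrecon:::spread_censor_times(8, 0, 10), 10 * (1:8) / 9)
  expect_length(kmrecon:::spread_censor_times(0, 0, 10), 0)
  expect_error(kmrecon:::spread_censor_times(2, 5, 5), "width")
})

test_that("censor times are counted per half-open coordinate bin", {
  b <- kmrecon:::bin_censor_times(5.0, c(0, 4, 6, 10), 1, 3)
  expect_identical(b$counts, c(0L, 1L, 0L))
  # half-open convention: a time equal to a coordinate joins that bin
  b2 <- kmrecon:::bin_censor_times(c(2.5, 5, 7.5), c(0, 5, 10), 1, 2)
  expect_identical(b2$counts, c(1L, 2L))
  expect_identical(sum(b2$counts), 3L)
  b3 <- kmrecon:::bin_censor_times(numeric(0), c(0, 5, 10), 1, 2)
  expect_identical(b3$counts, c(0L, 0L))
})

test_that("event propagation inverts the product-limit recursion", {
  cv <- we_curve()
  # hand arithmetic on the first three printed coordinates, 213 at risk:
  # d1 = 0; d2 = round(213*(1-0.994)) = 1, S = 212/213;
  # d3 = round(212*(1-0.989/(212/213))) = 1
  pr <- kmrecon:::propagate_interval(cv$time, cv$surv, 1, 3, 213,
                                     c(0L, 0L, 0L), 1)
  expect_identical(pr$d, c(0L, 1L, 1L))
  expect_equal(pr$skm[2], 212 / 213)

  # flat segment: no events, n falls only by censoring
  pr2 <- kmrecon:::propagate_interval(c(0, 1, 2, 3), c(1, 1, 1, 1), 1, 4, 50,
                                      c(0L, 2L, 1L, 0L), 1)
  expect_identical(pr2$d, rep(0L, 4))
  expect_identical(pr2$n, c(50L, 50L, 48L, 47L))

  # a drop to exactly (n-1)/n is one event
  pr3 <- kmrecon:::propagate_interval(c(0, 1), c(1, 19 / 20), 1, 2, 20,
                                      c(0L, 0L), 1)
  expect_identical(pr3$d, c(0L, 1L))
})

test_that("interval fitting converges the at-risk count to the published target", {
  # flat survival and constant nrisk: zero censoring, no adjustment passes
  tm <- c(0, 1, 2, 3, 4); sv <- c(1, 1, 1, 1, 1)
  fi <- kmrecon:::fit_interval(tm, sv, 1, 2, tm[3], 40, 40, 0, 1)
  expect_true(fi$converged)
  expect_identical(fi$iterations, 0L)
  expect_identical(fi$ncensor, 0L)

  # synthetic interval with known censoring converges to the exact target
  set.seed(11)
  sim <- simulate_trial(120, dist_exponential(0.15), censor_uniform(10),
                        seed = 11)
  fit <- pipeline_arm(sim$ipd, "no_totevents")
  iv <- fit$intervals
  expect_true(all(iv$nrisk_achieved[-nrow(iv)] == iv$nrisk_target[-nrow(iv)]))
})

test_that("the closing interval extrapolates censoring from elapsed time", {
  tm <- c(0, 50, 55, 65)
  # span 10 over 50 elapsed, 20 prior censorings -> 4; capped by nrisk
  expect_identical(kmrecon:::last_interval_censor(tm, c(1L, 3L), c(2L, 4L),
                                                  2L, 20, 30), 4L)
  expect_identical(kmrecon:::last_interval_censor(tm, c(1L, 3L), c(2L, 4L),
                                                  2L, 0, 30), 0L)
  tm2 <- c(0, 10, 10.1, 20.1)
  expect_identical(kmrecon:::last_interval_censor(tm2, c(1L, 3L), c(2L, 4L),
                                                  2L, 200, 10), 10L)
})

test_that("the reported event total is honored when attainable", {
  set.seed(21)
  for (s in 1:5) {
    sim <- simulate_trial(100, dist_exponential(0.12), censor_uniform(9),
                          seed = s)
    fit <- pipeline_arm(sim$ipd, "all")
    expect_identical(sum(fit$km$d_hat), sum(sim$ipd$event))
  }
})

test_that("a zero event total empties the final interval", {
  cv <- we_curve(); rk <- we_risk()
  fit <- suppressWarnings(km_reconstruct(cv, rk, tot_events = 0,
                                         level = "all"))
  last <- rk$lower[2]:rk$upper[2]
  expect_true(all(fit$km$d_hat[last] == 0))
  expect_true(all(fit$km$cen_hat[last] == 0))
  # earlier events exist, so the impossibility is reported
  expect_true(any(grepl("exceed", fit$diagnostics)))
})

test_that("no_totevents equals all information when the event total is a no-op", {
  # the re-adjustment against the reported total only becomes a fixed point
  # when the final interval still contains events; require such a case
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_trial(80, dist_exponential(0.1), censor_uniform(10),
                          seed = s + 100)
    tru <- sim$ipd
    rts <- unname(quantile(tru$time, seq(0, 0.9, length.out = 5)))
    rts[1] <- 0
    cv <- exact_digitize(tru, include_times = rts, arm = "a")
    rt <- make_risk_table(tru, rts, cv)
    base <- km_reconstruct(cv, rt$risk, level = "no_totevents", repair = FALSE)
    last <- rt$risk$lower[nrow(rt$risk)]:rt$risk$upper[nrow(rt$risk)]
    if (sum(base$km$d_hat[last]) == 0) next
    withall <- km_reconstruct(cv, rt$risk, tot_events = sum(base$km$d_hat),
                              level = "all", repair = FALSE)
    expect_identical(withall$km, base$km)
    hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("uncensored trials are recovered exactly by the neither case", {
  for (s in 1:10) {
    sim <- simulate_trial(60, dist_exponential(0.1), seed = s)
    tru <- sim$ipd
    cv <- exact_digitize(tru, arm = "a")
    fit <- km_reconstruct(cv, km_risk(0, 1, nrow(cv), nrow(tru)),
                          level = "neither", repair = FALSE)
    ipd <- km_ipd(fit)
    expect_equal(sort(ipd$time[ipd$event == 1]),
                 sort(tru$time[tru$event == 1]))
    expect_identical(sum(ipd$event == 0), 0L)
  }
})

test_that("conservation identities hold at every coordinate for every level", {
  cfgs <- expand.grid(level = c("all", "no_nrisk", "no_totevents", "neither"),
                      censored = c(TRUE, FALSE), seed = 1:3,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cfgs))) {
    sim <- simulate_trial(70, dist_exponential(0.1),
                          censor_dist = if (cfgs$censored[i]) censor_uniform(8),
                          seed = cfgs$seed[i])
    fit <- pipeline_arm(sim$ipd, cfgs$level[i])
    expect_conservation(fit)
  }
})

test_that("reconstruction tracks the digitized curve within one event step", {
  # integer rounding bound for the levels whose propagation is not
  # overridden by an external event total
  for (lv in c("neither", "no_nrisk", "no_totevents")) {
    for (s in 1:15) {
      sim <- simulate_trial(90, dist_exponential(0.1), censor_uniform(12),
                            seed = s)
      fit <- pipeline_arm(sim$ipd, lv, probs = seq(0, 0.9, length.out = 5))
      km <- fit$km
      use <- km$n_hat > 0
      expect_lte(max(abs(km$S_km[use] - fit$curve$surv[use])),
                 1 / min(km$n_hat[use]))
    }
  }
})

test_that("derived IPD reproduces the reconstructed curve and accounts everyone", {
  # two-patient toy: one event at 0.18, the survivor censored at follow-up end
  cv <- km_curve(c(0, 0.18), c(1, 0.5))
  fit <- km_reconstruct(cv, km_risk(0, 1, 2, 2), level = "neither")
  ipd <- km_ipd(fit)
  expect_equal(nrow(ipd), 2)
  expect_equal(ipd$time[ipd$event == 1], 0.18)
  expect_equal(ipd$time[ipd$event == 0], 0.18)

  # round trip: the product-limit curve of the derived IPD equals S_km at
  # every coordinate
  for (s in c(3, 14)) {
    sim <- simulate_trial(80, dist_exponential(0.1), censor_uniform(10),
                          seed = s)
    fit <- pipeline_arm(sim$ipd, "all")
    ipd <- km_ipd(fit)
    km <- fit$km
    for (k in seq_len(nrow(km)))
      expect_equal(brute_km_at(ipd$time, ipd$event, km$time[k]), km$S_km[k],
                   tolerance = 1e-12)
  }
})

test_that("information levels demand the inputs they need", {
  cv <- we_curve(); rk <- we_risk()
  expect_error(km_reconstruct(cv, rk, level = "all"), "tot_events")
  expect_error(km_reconstruct(cv, km_risk(0, 1, 31, 213),
                              level = "no_totevents"), "two or more")
  expect_error(km_reconstruct(cv, rk, level = "neither"), "single risk row")
  # auto picks the richest level the inputs support
  expect_identical(km_reconstruct(cv, rk)$level, "no_totevents")
  expect_identical(km_reconstruct(cv, km_risk(0, 1, 31, 213))$level, "neither")
})
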