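test_that("mean error behaves like a mean with a normal-theory interval", {
  me <- mean_error(c(0.1, -0.1))
  expect_equal(me[["me"]], 0)

  cst <- mean_error(rep(0.3, 5))
  expect_equal(cst[["me"]], 0.3)
  expect_equal(cst[["lo95"]], 0.3)  # zero-width interval
  expect_equal(cst[["hi95"]], 0.3)

  set.seed(41)
  for (i in 1:20) {
    v <- rnorm(sample(3:40, 1))
    me <- mean_error(v)
    expect_equal(me[["me"]], mean(v))
    expect_equal(me[["hi95"]] - me[["lo95"]],
                 2 * 1.96 * sd(v) / sqrt(length(v)))
  }
  expect_error(mean_error(0.5), "at least 2")
})

test_that("mean absolute error dominates the mean error and folds correctly", {
  expect_equal(mean_abs_error(c(0.1, -0.1), n_mc = 100, seed = 1)[["mae"]],
               0.1)
  set.seed(43)
  for (i in 1:50) {
    v <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 2))
    expect_gte(mean_abs_error(v, n_mc = 10, seed = i)[["mae"]],
               abs(mean_error(v)[["me"]]))
  }

  # standard-normal errors: the 97.5th percentile of |Z| is 2.2414
  z <- as.numeric(scale(rnorm(500)))  # exact mean 0, sd 1
  mae <- mean_abs_error(z, n_mc = 150000, seed = 7)
  expect_equal(mae[["hi95"]], qnorm(0.9875), tolerance = 0.02)
})

test_that("variance components match the closed-form expected-mean-square algebra", {
  set.seed(47)
  for (i in 1:10) {
    a <- sample(3:6, 1); b <- sample(2:4, 1); r <- sample(2:3, 1)
    df <- expand.grid(exemplar = paste0("e", 1:a),
                      observer = paste0("o", 1:b),
                      rep = 1:r)
    df$value <- rnorm(nrow(df)) +
      rnorm(a)[as.integer(df$exemplar)] * runif(1, 0, 2) +
      rnorm(b)[as.integer(df$observer)] * runif(1, 0, 2)
    vc <- variance_components(df, n_mc = 10, seed = 1)
    or <- ems_oracle(df)
    expect_identical(vc$pooled, or$pooled)
    expect_equal(unname(vc$components), unname(or$components),
                 tolerance = 1e-10)
    expect_equal(vc$sigma_r[["estimate"]], or$sigma_r, tolerance = 1e-10)
    expect_equal(vc$sigma_e[["estimate"]], or$sigma_e, tolerance = 1e-10)
  }
})

test_that("identical values yield zero components and unbalanced layouts fail", {
  df <- expand.grid(exemplar = paste0("e", 1:3), observer = paste0("o", 1:2),
                    rep = 1:2)
  df$value <- 1.5
  vc <- variance_components(df, n_mc = 10, seed = 1)
  expect_equal(unname(vc$components), rep(0, 4))
  expect_equal(vc$sigma_r[["estimate"]], 0)

  expect_error(variance_components(df[-1, ], n_mc = 10), "unbalanced")
})

test_that("interaction pooling triggers exactly at the stated p-value threshold", {
  set.seed(53)
  seen <- c(pooled = FALSE, kept = FALSE)
  for (i in 1:30) {
    a <- 4; b <- 3; r <- 2
    df <- expand.grid(exemplar = paste0("e", 1:a),
                      observer = paste0("o", 1:b), rep = 1:r)
    # dial the interaction strength up and down across repeats
    inter <- matrix(rnorm(a * b, sd = runif(1, 0, 1.5)), a, b)
    df$value <- rnorm(nrow(df), sd = 0.5) +
      inter[cbind(as.integer(df$exemplar), as.integer(df$observer))]
    vc <- variance_components(df, n_mc = 10, seed = i)
    or <- ems_oracle(df)
    expect_equal(vc$p_interaction, or$p_interaction, tolerance = 1e-10)
    expect_identical(vc$pooled, or$p_interaction > 0.10)
    seen[if (vc$pooled) "pooled" else "kept"] <- TRUE
  }
  expect_true(all(seen))  # both branches exercised
})

test_that("known variance components are recovered on average", {
  set.seed(59)
  s_e <- 0.2; s_o <- 0.1; s_w <- 0.05
  a <- 6; b <- 3; r <- 2
  acc <- matrix(0, 300, 2)
  for (i in 1:300) {
    df <- expand.grid(exemplar = paste0("e", 1:a),
                      observer = paste0("o", 1:b), rep = 1:r)
    df$value <- rnorm(a, sd = s_e)[as.integer(df$exemplar)] +
      rnorm(b, sd = s_o)[as.integer(df$observer)] +
      rnorm(nrow(df), sd = s_w)
    vc <- variance_components(df, n_mc = 2, seed = i)
    acc[i, ] <- c(vc$components[["exemplar"]], vc$components[["within"]])
  }
  expect_lt(abs(mean(acc[, 1]) - s_e^2), 0.15 * s_e^2)
  expect_lt(abs(mean(acc[, 2]) - s_w^2), 0.15 * s_w^2)
})

test_that("monte-carlo intervals are reproducible and bracket the estimate", {
  df <- expand.grid(exemplar = paste0("e", 1:5), observer = paste0("o", 1:3),
                    rep = 1:2)
  set.seed(61)
  df$value <- rnorm(nrow(df))
  v1 <- variance_components(df, n_mc = 5000, seed = 3)
  v2 <- variance_components(df, n_mc = 5000, seed = 3)
  expect_identical(v1$sigma_r, v2$sigma_r)
  expect_lte(v1$sigma_r[["lo95"]], v1$sigma_r[["hi95"]])
})

test_that("the recovery study reports every requested level and statistic", {
  r <- recovery_study(n_exemplars = 2,
                      trial = list(n_per_arm = 60,
                                   event_dist = list(
                                     a = dist_exponential(0.10),
                                     b = dist_exponential(0.06)),
                                   censor_dist = censor_uniform(15)),
                      info_levels = c("all", "neither"),
                      n_mc = 500, seed = 13)
  rep <- r$report
  expect_setequal(unique(rep$level), c("all", "neither"))
  expect_setequal(unique(rep$statistic),
                  c("survprob", "median", "hr", "se_log_hr"))
  expect_true(all(rep$mae >= abs(rep$me) - 1e-12))

  # uncensored trials: survival probabilities recovered exactly at all levels
  r0 <- recovery_study(n_exemplars = 2,
                       trial = list(n_per_arm = 60,
                                    event_dist = list(
                                      a = dist_exponential(0.10),
                                      b = dist_exponential(0.06))),
                       info_levels = c("all", "neither"),
                       n_mc = 500, seed = 13)
  sp <- r0$diffs[r0$diffs$statistic == "survprob", ]
  expect_equal(max(abs(sp$diff)), 0)
})
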