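test_that("variance decomposition follows the ratio closed forms", {
  set.seed(2)
  d <- data.frame(x = rlnorm(400, log(7), 0.6))
  fit0 <- fit_usual_intake(x ~ 1, d, ratio = 0)
  expect_equal(fit0$shrinkage, 1)
  expect_equal(fit0$var_between_t, fit0$var_obs_t)
  expect_equal(predict(fit0), d$x)  # observed = usual when r = 0

  fit <- fit_usual_intake(x ~ 1, d, ratio = 0.61)
  expect_equal(fit$shrinkage, sqrt(1 / 1.61))
  expect_equal(fit$var_between_t + fit$var_within_t, fit$var_obs_t)
  expect_equal(fit$var_within_t / fit$var_between_t, 0.61)
})

test_that("between-person variance is recovered from generated data", {
  cfg <- one_stratum_config(n = 10000, log_sd = 0.5, seed = 31L,
                            ratios = ratio_table(zinc_adult = 0.89,
                                                 folate_adult = 0.89))
  pop <- generate_population(cfg)
  fit <- fit_usual_intake(zinc_day_mg_d ~ 1, pop, ratio = 0.89)
  expect_lt(abs(fit$var_between_t - 0.25), 0.02)
})

test_that("known recall-day effects are estimated and removed", {
  set.seed(4)
  n <- 5000
  d <- data.frame(weekend = runif(n) < 2 / 7,
                  sick = runif(n) < 0.1)
  d$x <- exp(log(7) + 0.3 * d$weekend + rnorm(n, 0, 0.5))
  fit <- fit_usual_intake(x ~ weekend + sick, d, ratio = 0.61)
  expect_lt(abs(coef(fit)[["weekendTRUE"]] - 0.3), 0.05)

  # adjusted intakes no longer depend on weekend
  expect_lt(abs(mean(fit$y_adj[d$weekend]) - mean(fit$y_adj[!d$weekend])), 0.05)

  # adding a zero-effect covariate leaves estimates essentially unchanged
  fit2 <- fit_usual_intake(x ~ weekend, d, ratio = 0.61)
  expect_equal(predict(fit), predict(fit2), tolerance = 1e-2)
})

test_that("constant covariates adjust nothing", {
  set.seed(5)
  d <- data.frame(x = rlnorm(100, 2, 0.4), weekend = FALSE)
  expect_warning(fit <- fit_usual_intake(x ~ weekend, d, ratio = 0.5),
                 "aliased")
  plain <- fit_usual_intake(x ~ 1, d, ratio = 0.5)
  expect_equal(predict(fit), predict(plain))
})

test_that("shrinkage fixes the stratum mean and preserves rank order", {
  set.seed(6)
  d <- data.frame(x = rlnorm(300, log(5), 0.5))
  fit <- fit_usual_intake(x ~ 1, d, ratio = 0.61)
  usual <- predict(fit)
  # person exactly at the transformed mean is a fixed point
  at_mean <- data.frame(x = exp(fit$mu_t))
  expect_equal(predict(fit, at_mean), exp(fit$mu_t))
  expect_equal(order(usual), order(d$x))
  # exact identity: var of transformed usual = shrinkage^2 * var_obs
  expect_equal(var(predict(fit, type = "transformed")),
               fit$shrinkage^2 * fit$var_obs_t)
  expect_lt(var(log(usual)), var(log(d$x)))
})

test_that("estimated usual tracks true usual better than the single recall", {
  cfg <- one_stratum_config(n = 4000, seed = 17L)
  pop <- generate_population(cfg)
  fit <- fit_usual_intake(zinc_day_mg_d ~ 1, pop, ratio = 0.61)
  usual <- predict(fit)
  truth <- pop$zinc_usual_true_mg_d
  expect_gt(cor(usual, truth), cor(pop$zinc_day_mg_d, truth))
  expect_lt(sqrt(mean((usual - truth)^2)),
            sqrt(mean((pop$zinc_day_mg_d - truth)^2)))
})

test_that("lognormal generation reproduces closed-form tail fractions", {
  cfg <- one_stratum_config(n = 30000, median_zinc = 6.9, log_sd = 0.5,
                            seed = 23L)
  pop <- generate_population(cfg)
  fit <- fit_usual_intake(zinc_day_mg_d ~ 1, pop, ratio = 0.61)
  usual <- predict(fit)
  for (thr in c(4, 7, 10)) {
    expect_lt(abs(100 * mean(usual < thr) -
                    lognormal_cutpoint(thr, log(6.9), 0.5)), 1.5)
  }
})

test_that("small strata and non-positive intakes are routed to policy", {
  d <- data.frame(x = rlnorm(10, 1, 0.3))
  expect_error(fit_usual_intake(x ~ 1, d, ratio = 0.5), "pool")
  d2 <- data.frame(x = c(rlnorm(40, 1, 0.3), 0))
  expect_message(fit <- fit_usual_intake(x ~ 1, d2, ratio = 0.5), "replaced")
  expect_true(all(is.finite(predict(fit))))
  expect_error(fit_usual_intake(x ~ 1, d2, ratio = 0.5, zero_policy = "error"),
               "non-positive")
})

test_that("population-level estimation pools under-sized strata", {
  cfg <- small_config(seed = 8L)
  pop <- generate_population(cfg)
  expect_message(res <- estimate_usual_population(pop), "pooling")
  expect_equal(nrow(res$estimates), 2L * nrow(pop))
  expect_true(all(res$estimates$usual_intake > 0))
  # men were pooled across regions: one model, not two
  expect_true("zinc.man_19_45y.pooled" %in% names(res$models))
})

test_that("Box-Cox transform round-trips through predict", {
  set.seed(9)
  d <- data.frame(x = rlnorm(200, 2, 0.4))
  fit <- fit_usual_intake(x ~ 1, d, ratio = 0, transform = "boxcox")
  expect_equal(predict(fit), d$x, tolerance = 1e-8)
})
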