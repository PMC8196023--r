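# Stage-2 hierarchical measurement-error model: interval and convergence
# utilities, sampler behavior on controlled inputs, invariances.

test_that("equal-tailed intervals are symmetric posterior quantiles", {
  set.seed(1)
  z <- rnorm(1e6)
  eti <- compute_eti(z, 0.90)
  expect_equal(unname(eti), c(-1.645, 1.645), tolerance = 0.01)
  expect_equal(unname(compute_eti(rep(3.2, 10), 0.95)), c(3.2, 3.2))
  # symmetric draws give an interval symmetric about 0
  zs <- c(z, -z)
  e <- compute_eti(zs, 0.95)
  expect_equal(e[["lower"]], -e[["upper"]], tolerance = 1e-9)
  expect_error(compute_eti(1, 0.9))
})

test_that("split R-hat separates converged from divergent chains", {
  set.seed(2)
  c1 <- rnorm(5000)
  c2 <- rnorm(5000)
  r <- gelman_rubin(list(c1, c2))
  expect_lt(abs(r - 1), 0.01)
  # chains centered far apart
  r2 <- gelman_rubin(list(c1, c2 + 10))
  expect_gt(r2, 5)
  # affine invariance
  r3 <- gelman_rubin(list(3 * c1 + 7, 3 * (c2 + 10) + 7))
  expect_equal(unname(r3), unname(r2), tolerance = 1e-9)
  # within-chain drift is caught by splitting
  trend <- seq(0, 5, length.out = 5000)
  r4 <- gelman_rubin(list(c1 + trend, c2 + trend))
  expect_gt(r4, 1.1)
  expect_error(gelman_rubin(list(c1)), "2 chains")
})

test_that("split R-hat agrees with the coda diagnostic on iid chains", {
  set.seed(3)
  ch <- lapply(1:2, function(i) coda::mcmc(cbind(a = rnorm(4000),
                                                 b = rexp(4000))))
  ours <- gelman_rubin(coda::mcmc.list(ch))
  theirs <- coda::gelman.diag(coda::mcmc.list(ch))$psrf[, 1]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.01)
})

test_that("effect summaries back-transform to days and flag intervals", {
  # constant draws: -0.24 standardized x SD 10 -> -2.4 days
  f <- fake_fit(beta_draws = rep(-0.24, 100), scale = 10)
  s <- summarize_effects(f)
  expect_equal(s$estimate, -2.4)
  expect_equal(s$parameter, "OTC")

  # interval strictly below zero at 90%: flagged
  set.seed(4)
  d <- rnorm(4000, -0.249, 0.06)  # days: -2.49 +/- 0.6
  s2 <- summarize_effects(fake_fit(d))
  expect_true(s2$effect_90)
  expect_lt(s2$eti90_high, 0)

  # interval straddling zero: no effect at either level
  d3 <- rnorm(4000, -0.084, 0.058)  # days: -0.84 +/- 0.58
  s3 <- summarize_effects(fake_fit(d3))
  expect_false(s3$effect_95)
  expect_equal(s3$effect_90, unname(s3$eti90_high < 0 | s3$eti90_low > 0))

  expect_error(summarize_effects(
    structure(list(draws = cbind(beta = 1), phenophase = "flowering",
                   scaling = NULL), class = "posterior_fit")), "scaling")
})

test_that("beta posterior matches weighted least squares when groups are flat", {
  # no group variation in truth: the hierarchical model should shrink group
  # SDs and reproduce the measurement-error WLS estimate of beta
  reps <- fake_replicates(n_species = 8, n_sites = 4, n_years = 2,
                          beta = -0.3, se = 0.15, sd_noise = 0, seed = 5)
  fit <- suppressWarnings(fit_treatment_model(reps, test_spec(seed = 2)))
  trt <- as.numeric(reps$treatment == "OTC")
  w <- 1 / reps$se_mu^2
  wls <- lm(mu ~ trt, data = reps, weights = w)
  expect_equal(mean(fit$draws[, "beta"]), unname(coef(wls)[2]),
               tolerance = 0.05)
  expect_equal(mean(fit$draws[, "alpha"]), unname(coef(wls)[1]),
               tolerance = 0.05)
})

test_that("inflating replicate SEs widens the beta posterior", {
  reps <- fake_replicates(n_species = 6, n_sites = 3, beta = -0.3,
                          se = 0.1, sd_noise = 0.1, seed = 6)
  reps10 <- reps
  reps10$se_mu <- reps10$se_mu * 10
  f1 <- suppressWarnings(fit_treatment_model(reps, test_spec(seed = 3)))
  f2 <- suppressWarnings(fit_treatment_model(reps10, test_spec(seed = 3)))
  expect_gt(sd(f2$draws[, "beta"]), sd(f1$draws[, "beta"]))
})

test_that("fits are invariant to replicate row order", {
  reps <- fake_replicates(seed = 7)
  perm <- reps[sample(nrow(reps)), ]
  attr(perm, "scaling") <- attr(reps, "scaling")
  f1 <- suppressWarnings(fit_treatment_model(reps, test_spec(seed = 4)))
  f2 <- suppressWarnings(fit_treatment_model(perm, test_spec(seed = 4)))
  expect_identical(f1$draws[, "beta"], f2$draws[, "beta"])
  expect_identical(f1$rhat, f2$rhat)
})

test_that("a constant predictor reduces to the treatment-only model", {
  reps <- fake_replicates(seed = 8)
  reps$years_of_warming <- 1L  # constant
  expect_message(
    f_int <- suppressWarnings(
      fit_interaction_model(reps, "years", test_spec(seed = 5))),
    "constant")
  f_trt <- suppressWarnings(fit_treatment_model(reps, test_spec(seed = 5)))
  expect_identical(f_int$draws[, "beta"], f_trt$draws[, "beta"])
  expect_false("b3_years_of_warming" %in% colnames(f_int$draws))
})

test_that("a moisture-by-warming interaction is recovered", {
  # warmed-plot timing at moist sites shifted +0.13 standardized units
  # (+1.3 days at SD 10) relative to dry
  set.seed(9)
  reps <- fake_replicates(n_species = 6, n_sites = 6, n_years = 2,
                          beta = -0.24, se = 0.12, sd_noise = 0.05, seed = 9)
  moist_lookup <- setNames(rep(c("dry", "moist"), 3),
                           sprintf("k%02d", 1:6))
  reps$moisture <- moist_lookup[reps$site]
  trt <- as.numeric(reps$treatment == "OTC")
  reps$mu <- reps$mu + 0.13 * trt * (reps$moisture == "moist")
  fit <- suppressWarnings(
    fit_interaction_model(reps, "moisture", test_spec(seed = 6,
                                                      iter = 2000,
                                                      warmup = 1000)))
  s <- summarize_effects(fit)
  b3 <- s[s$parameter == "OTC x moisture_moist", ]
  expect_gt(b3$estimate, 0)
  expect_lt(abs(b3$estimate - 1.3), 2 * b3$std_error)
})
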