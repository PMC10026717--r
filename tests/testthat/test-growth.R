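test_that("growth curves evaluate their closed forms at landmark ages", {
  p <- c(TL_inf = 105.0, rate = 0.216, t0 = 3.99)
  expect_equal(predict_length("von_bertalanffy", p, 3.99), 0)
  expect_equal(predict_length("gompertz", p, 3.99), 105.0 / exp(1))
  expect_equal(predict_length("gompertz", p, 3.99), 38.62734, tolerance = 1e-6)
  expect_equal(predict_length("logistic", p, 3.99), 105.0 / 2)
  expect_error(predict_length("richards", p, 1))
})

test_that("all growth curves increase in age and approach the asymptote", {
  t <- seq(0.1, 60, by = 0.1)
  for (fam in growth_families()) {
    p <- c(TL_inf = 105.0, rate = 0.3, t0 = 2)
    y <- predict_length(fam, p, t)
    expect_true(all(diff(y) > 0), info = fam)
    expect_equal(predict_length(fam, p, 1e4), 105.0, tolerance = 1e-6,
                 info = fam)
  }
})

test_that("noiseless Gompertz data give exact parameter recovery", {
  fish <- simulate_population(noiseless_config(n = 60))
  fit <- fit_growth_model(fish, "gompertz")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(105.0, 0.216, 3.99), tolerance = 1e-6)
  expect_lt(fit$RSS, 1e-8)
})

test_that("parameter CIs reach nominal coverage on noisy replicates", {
  # 60 replicates of n = 800, sigma_TL = 3; 95% CIs should cover the truth
  # in roughly 95% of cases per parameter
  hits <- matrix(0, 60, 3)
  for (r in 1:60) {
    cfg <- synthetic_config(n = 800, seed = 1000 + r,
                            growth = list(TL_inf = 105.0, G = 0.216, t0 = 3.99,
                                          sigma_TL = 3))
    fit <- fit_growth_model(simulate_population(cfg), "gompertz")
    truth <- c(105.0, 0.216, 3.99)
    hits[r, ] <- fit$ci["lower", ] <= truth & truth <= fit$ci["upper", ]
  }
  expect_true(all(colMeans(hits) >= 0.85))
})

test_that("AICc comparison ranks, weights and sums correctly", {
  fish <- simulate_population(synthetic_config(n = 250, seed = 17))
  fits <- suppressWarnings(
    lapply(growth_families(), function(f) fit_growth_model(fish, f))
  )
  cmp <- compare_models_aicc(fits)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_equal(min(cmp$delta_AICc), 0)
  expect_true(all(diff(cmp$AICc) >= 0))
  expect_identical(attr(cmp, "best"), cmp$family[1])
  # mismatched n across fits is an error
  small <- fit_growth_model(dplyr::slice_head(fish, n = 100), "gompertz")
  expect_error(compare_models_aicc(list(fits[[1]], small)),
               class = "sizeage_data_error")
})

test_that("Akaike weights follow the closed form and its invariances", {
  # frozen: evaluated weight formula at AICc = {100, 102, 110}
  expect_equal(aicc_weights(c(100, 102, 110)),
               c(0.7274752, 0.2676232, 0.0049017), tolerance = 1e-6)
  expect_equal(aicc_weights(c(100, 102, 110)),
               aicc_weights(c(100, 102, 110) + 57.3), tolerance = 1e-12)
  expect_equal(aicc_weights(c(50, 50)), c(0.5, 0.5))
  expect_equal(sum(aicc_weights(rnorm(7, 200, 20))), 1)
})

test_that("AMGR is the Gompertz slope at the inflection", {
  fish <- simulate_population(noiseless_config(n = 60))
  fit <- fit_growth_model(fish, "gompertz")
  expect_equal(amgr(fit), 0.216 * 105.0 / exp(1), tolerance = 1e-6)
  # finite-difference oracle: max d TL/dt over a fine grid equals AMGR at t0
  t <- seq(0.01, 12, by = 0.001)
  y <- predict_length("gompertz", fit$estimates, t)
  slopes <- diff(y) / diff(t)
  expect_equal(max(slopes), amgr(fit), tolerance = 1e-4)
  expect_equal(t[which.max(slopes)], fit$estimates[["t0"]], tolerance = 0.01)
  # linear in TL_inf
  double_fit <- fit
  double_fit$estimates[["TL_inf"]] <- 2 * fit$estimates[["TL_inf"]]
  expect_equal(amgr(double_fit), 2 * amgr(fit))
  vb <- fit_growth_model(fish, "von_bertalanffy")
  expect_error(amgr(vb), class = "sizeage_domain_error")
})

test_that("an implausibly large asymptote triggers a warning, not suppression", {
  # near-linear length-at-age data push the von Bertalanffy asymptote far out
  fish <- fish_tbl(TL = seq(10, 60, length.out = 25) + rep(c(-.2, .2), length.out = 25),
                   age = seq(0.5, 6.5, length.out = 25))
  expect_warning(fit <- fit_growth_model(fish, "von_bertalanffy"),
                 class = "sizeage_implausible_TL_inf")
  expect_true(fit$converged)
  expect_gt(fit$estimates[["TL_inf"]], 140)
})

test_that("sensitivity refit measures the pull of the largest fish", {
  # flat-ish age structure so old fish are plentiful and the asymptote is
  # well identified; no outliers, so dropping 3 fish barely moves it
  fish <- simulate_population(synthetic_config(n = 1000, seed = 23, Z_true = 0.3))
  fit <- fit_growth_model(fish, "gompertz")
  # drop_k = 0 reproduces the fit
  s0 <- sensitivity_refit(fish, fit, drop_k = 0L)
  expect_equal(s0$relative_change, 0, tolerance = 1e-6)
  expect_true(s0$pass)
  # well-behaved synthetic data: dropping 3 fish moves TL_inf by far less than 10%
  s3 <- sensitivity_refit(fish, fit, drop_k = 3L)
  expect_lt(s3$relative_change, 0.10)
  expect_true(s3$pass)
  expect_equal(s3$fit$n, fit$n - 3)
  expect_error(sensitivity_refit(dplyr::slice_head(fish, n = 2), fit, drop_k = 5L))
})
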