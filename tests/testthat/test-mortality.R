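test_that("catch curves tabulate counts, gaps, and the peak class", {
  fish <- fish_tbl(TL = rep(20, 4), age = c(0.5, 1.5, 1.6, 2.5))
  curve <- build_catch_curve(fish)
  expect_equal(curve$n, c(1L, 2L, 1L))
  expect_equal(attr(curve, "peak_class"), 1L)
  # empty intermediate classes are kept as zeros
  gappy <- fish_tbl(TL = rep(20, 5), age = c(0.5, 1.5, 1.6, 4.5, 4.6))
  expect_equal(build_catch_curve(gappy)$n, c(1L, 2L, 0L, 0L, 2L))
  expect_error(build_catch_curve(fish_tbl(TL = rep(20, 3), age = c(2.1, 2.5, 2.9))),
               class = "sizeage_degenerate_curve")
})

test_that("descending limb recodes ages above the peak", {
  fish <- fish_tbl(TL = rep(20, 20),
                   age = rep(c(0.5, 1.5, 2.5, 3.5), c(5, 9, 4, 2)))
  curve <- build_catch_curve(fish)
  limb <- select_descending_limb(curve)
  expect_equal(limb$age_class, c(2L, 3L))
  expect_equal(limb$x, c(0L, 1L))
  expect_equal(attr(limb, "n_included"), 6L)
  expect_equal(attr(limb, "T_sum"), 2L)
  with_peak <- select_descending_limb(curve, mode = "include_peak")
  expect_equal(with_peak$age_class, 1:3)
  expect_equal(attr(with_peak, "n_included"), 15L)
})

test_that("descending limb stops at max_class and before internal gaps", {
  # classes 0..10 with a peak at 2, a gap at 7-8 and stragglers at 9-10
  counts <- c(10, 30, 40, 25, 12, 6, 3, 0, 0, 2, 1)
  ages <- rep(0:10 + 0.5, counts)
  curve <- build_catch_curve(fish_tbl(TL = rep(20, length(ages)), age = ages))
  limb <- select_descending_limb(curve, max_class = 6)
  expect_equal(limb$age_class, 3:6)
  expect_equal(attr(limb, "n_included"), sum(counts[4:7]))
  # without max_class, the gap at class 7 still truncates the limb
  expect_equal(select_descending_limb(curve)$age_class, 3:6)
  expect_error(select_descending_limb(
    build_catch_curve(fish_tbl(TL = rep(20, 3), age = c(0.5, 0.6, 1.5)))),
    class = "sizeage_insufficient_data")
})

test_that("Chapman-Robson reproduces hand-computed survival and Z", {
  limb <- tibble::tibble(x = c(0, 1, 2), n = c(4, 2, 1))
  cr <- chapman_robson(limb)
  expect_equal(cr$S_hat, 0.4)
  expect_equal(chapman_robson(limb, correct = FALSE)$Z, -log(0.4))
  expect_equal(chapman_robson(limb, correct = FALSE)$Z, 0.9162907, tolerance = 1e-6)
  # corrected: -ln(0.4) - 6*5 / (7*5*10)
  expect_equal(cr$Z, 0.9162907 - 30 / 350, tolerance = 1e-6)
  expect_true(cr$ci_Z[1] < cr$Z && cr$Z < cr$ci_Z[2])
  expect_error(chapman_robson(tibble::tibble(x = 0, n = 5)),
               class = "sizeage_degenerate_curve")
})

test_that("bias correction always shrinks Z below -log(S)", {
  set.seed(4)
  for (i in 1:25) {
    n_cls <- sample(3:6, 1)
    limb <- tibble::tibble(x = 0:(n_cls - 1),
                           n = sample(1:30, n_cls, replace = TRUE))
    corr <- chapman_robson(limb)
    uncorr <- chapman_robson(limb, correct = FALSE)
    expect_lt(corr$Z, uncorr$Z)
    expect_equal(corr$S_hat, uncorr$S_hat)
  }
})

test_that("Chapman-Robson S converges to the brute-force geometric MLE", {
  # The CR statistic T/(n+T-1) is the *unbiased* estimator; the geometric
  # MLE is T/(n+T). They differ by T/((n+T)(n+T-1)) — visible in small
  # samples, below 1e-4 once n + T is a few thousand.
  limb <- tibble::tibble(x = c(0, 1, 2), n = c(4, 2, 1)) # n + T = 11
  cr <- chapman_robson(limb)
  mle_small <- 4 / (7 + 4)
  expect_equal(cr$S_hat - mle_small, 4 / (11 * 10), tolerance = 1e-12)

  set.seed(9)
  big <- sample(0:7, 3000, replace = TRUE, prob = exp(-0.9 * (0:7)))
  limb_big <- dplyr::count(tibble::tibble(x = big), x, name = "n")
  cr_big <- chapman_robson(limb_big)
  # brute-force grid over the geometric likelihood on the recoded ages
  S_grid <- seq(1e-4, 1 - 1e-4, by = 1e-5)
  n <- sum(limb_big$n); T_sum <- sum(limb_big$x * limb_big$n)
  ll <- n * log(1 - S_grid) + T_sum * log(S_grid)
  expect_lt(abs(cr_big$S_hat - S_grid[which.max(ll)]), 1e-4)
})

test_that("rate conversions and the longevity M estimator evaluate exactly", {
  expect_equal(annual_rate(0), 0)
  expect_equal(annual_rate(log(2)), 0.5)
  expect_equal(annual_rate(0.924), 0.6030719, tolerance = 1e-6)
  expect_error(annual_rate(-0.1), class = "sizeage_domain_error")
  # monotone onto [0, 1)
  r <- sort(runif(50, 0, 10))
  a <- annual_rate(r)
  expect_true(all(diff(a) > 0) && all(a >= 0 & a < 1))

  expect_equal(natural_mortality_tmax(5.109), 1)
  expect_equal(natural_mortality_tmax(10), 0.5109)
  expect_equal(natural_mortality_tmax(11), 0.4644545, tolerance = 1e-6)
  expect_error(natural_mortality_tmax(0))
})

test_that("mortality partitioning satisfies its identities", {
  p <- partition_mortality(0.8, 0.4)
  expect_equal(p$F_, 0.4)
  expect_equal(p$E, 0.5) # E = 0.5 exactly when F = M
  expect_equal(p$A_Z, annual_rate(0.8))
  expect_true(p$A_Z >= p$A_M)
  pz <- partition_mortality(0.6, 0.6)
  expect_equal(pz$F_, 0)
  expect_equal(pz$E, 0)
  expect_warning(pf <- partition_mortality(0.4, 0.6), class = "sizeage_F_floored")
  expect_equal(pf$F_, 0)
  expect_true(pf$F_floored)
  expect_error(partition_mortality(0, 0.1))
  # E in [0, 1] across random valid inputs
  set.seed(2)
  Z <- runif(40, 0.05, 2); M <- runif(40) * Z
  E <- purrr::map2_dbl(Z, M, ~ partition_mortality(.x, .y)$E)
  expect_true(all(E >= 0 & E <= 1))
})

test_that("the full chain recovers the generator's mortality", {
  cfg <- synthetic_config(n = 1e5, seed = 3, Z_true = 0.9,
                          full_recruit_age = 0L, ascending_catchability = numeric(0))
  fish <- simulate_population(cfg)
  curve <- build_catch_curve(fish)
  expect_equal(attr(curve, "peak_class"), 0L) # geometric mode at 0
  limb <- select_descending_limb(curve, mode = "include_peak")
  cr <- chapman_robson(limb)
  expect_equal(cr$Z, 0.9, tolerance = 0.01 / 0.9)
})
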