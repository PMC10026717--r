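rp105 <- reference_points(105.0)

test_that("catch classification matches a hand-worked example", {
  cls <- classify_catch(c(30, 45, 68, 85), mll_policy(40), rp105)
  expect_equal(cls$retained, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.character(cls$category),
               c(NA, "immature", "within_slot", "mature_outside_slot"))
  expect_equal(cls$megaspawner, c(FALSE, FALSE, FALSE, TRUE))
  # an MLL of zero retains everything
  expect_true(all(classify_catch(c(5, 50, 90), mll_policy(0), rp105)$retained))
  # slot policy: only the 68-cm fish falls inside
  slot_cls <- classify_catch(c(30, 45, 68, 85), slot_policy(61.1, 74.7), rp105)
  expect_equal(sum(slot_cls$retained), 1)
  expect_equal(slot_cls$TL[slot_cls$retained], 68)
  expect_error(classify_catch(numeric(0), mll_policy(40), rp105),
               class = "sizeage_data_error")
})

test_that("boundary fish are retainable under both policy kinds", {
  expect_true(classify_catch(40, mll_policy(40), rp105)$retained)
  expect_true(all(classify_catch(c(60, 70), slot_policy(60, 70), rp105)$retained))
  expect_false(any(classify_catch(c(59.99, 70.01), slot_policy(60, 70),
                                  rp105)$retained))
})

test_that("catch summaries aggregate counts and retained-based fractions", {
  s <- summarize_catch(classify_catch(c(30, 45, 68, 85), mll_policy(40), rp105))
  expect_equal(s$n_catch, 4)
  expect_equal(s$n_retained, 3)
  expect_equal(s$frac_retained, 0.75)
  expect_equal(s$frac_immature, 1 / 3)
  expect_equal(s$n_within_slot, 1)
  expect_equal(s$n_megaspawner, 1)
  # categories partition the retained catch
  expect_equal(s$n_immature + s$n_within_slot + s$n_mature_outside_slot,
               s$n_retained)
  expect_equal(s$frac_immature + s$frac_within_slot + s$frac_mature_outside_slot,
               1)
  # nothing retainable: fractions defined as 0, flagged
  s0 <- summarize_catch(classify_catch(c(10, 20), mll_policy(40), rp105))
  expect_equal(s0$n_retained, 0)
  expect_true(s0$empty_retained)
  expect_equal(s0$frac_immature, 0)
})

test_that("policy comparison reports the retained-catch contraction", {
  lengths <- c(30, 45, 68, 85)
  out <- compare_policies(lengths,
                          list(mll_policy(40), slot_policy(61.1, 74.7)), rp105)
  expect_equal(out$n_retained, c(3, 1))
  expect_equal(out$retained_ratio, c(1, 1 / 3))
  # identical policies give identical summaries
  twice <- compare_policies(lengths, list(mll_policy(40), mll_policy(40)), rp105)
  expect_equal(twice$n_retained[1], twice$n_retained[2])
  expect_equal(twice$frac_immature[1], twice$frac_immature[2])
})

test_that("raising the MLL never increases the retained count", {
  set.seed(6)
  lengths <- rlnorm(300, log(25), 0.45)
  retained <- vapply(seq(0, 80, by = 2.5), function(m) {
    summarize_catch(classify_catch(lengths, mll_policy(m), rp105))$n_retained
  }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("a slot's retained set is nested in the matching MLL's", {
  set.seed(7)
  lengths <- rlnorm(200, log(30), 0.5)
  slot <- slot_policy(61.1, 74.7)
  in_slot <- classify_catch(lengths, slot, rp105)$retained
  above_lower <- classify_catch(lengths, mll_policy(61.1), rp105)$retained
  expect_true(all(!in_slot | above_lower))
})

test_that("length-frequency bins are left-closed and complete", {
  lf <- length_frequency(c(10.0, 10.9, 11.0, 13.5))
  expect_equal(lf$bin_lower, 10:13)
  expect_equal(lf$n, c(2L, 1L, 0L, 1L))
  expect_equal(sum(lf$n), 4)
  lf5 <- length_frequency(c(12, 14, 21), binwidth = 5)
  expect_equal(lf5$bin_lower, c(10, 15, 20))
  expect_equal(lf5$n, c(2L, 0L, 1L))
})
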