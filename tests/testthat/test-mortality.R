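test_that("discretizing a tabulated curve recovers the reference d vector", {
  crv <- mortality_curve("table", table = data.frame(
    contamination = 0:4, d = c(0.1, 0.11, 0.2, 0.9, 1)))
  expect_equal(discretize_mortality(crv, 5), ref_d)
})

test_that("linear curves interpolate between d0 and 1", {
  expect_equal(discretize_mortality(mortality_curve("linear", d0 = 0.05), 5),
               c(0.05, 0.2875, 0.525, 0.7625, 1))
  # two classes: endpoints only
  expect_equal(discretize_mortality(mortality_curve("linear", d0 = 0.3), 2),
               c(0.3, 1))
  expect_equal(
    discretize_mortality(mortality_curve("sigmoid", d0 = 0.3,
                                         steepness = 2), 2),
    c(0.3, 1))
})

test_that("discretization enforces the model's endpoint and monotonicity", {
  flat <- mortality_curve("table",
    table = data.frame(contamination = 0:2, d = c(0.1, 0.5, 0.5)))
  expect_error(mortality_curve("table",
    table = data.frame(contamination = 0:2, d = c(0.5, 0.4, 1))),
    "non-decreasing")
  expect_error(discretize_mortality(flat, 3), "1")
  short <- mortality_curve("table",
    table = data.frame(contamination = 0:2, d = c(0.1, 0.5, 0.99)))
  expect_error(discretize_mortality(short, 3), "within tol")
  # within tolerance the top class is pinned to exactly 1
  near <- mortality_curve("table",
    table = data.frame(contamination = 0:2, d = c(0.1, 0.5, 1 - 1e-9)))
  expect_identical(discretize_mortality(near, 3)[3], 1)
  zero <- mortality_curve("table",
    table = data.frame(contamination = 0:2, d = c(0, 0.5, 1)))
  expect_error(discretize_mortality(zero, 3), "> 0")
})

test_that("discretization is order-preserving in the curve", {
  lo <- discretize_mortality(mortality_curve("linear", d0 = 0.05), 6)
  hi <- discretize_mortality(mortality_curve("linear", d0 = 0.3), 6)
  expect_true(all(hi >= lo))
  for (s in c(0.5, 1, 3)) {
    sg <- discretize_mortality(mortality_curve("sigmoid", d0 = 0.05,
                                               steepness = s), 6)
    # saturating curve dominates the linear one with the same endpoints
    expect_true(all(sg >= lo - 1e-12))
  }
})

test_that("toxic-unit scaling converts particle influx to effective influx", {
  expect_equal(effective_influx(5), 5)                 # potency 1: identity
  expect_equal(effective_influx(4.5, potency = 2), 9)
  expect_equal(effective_influx(68, potency = 0.5), 34)
  expect_error(effective_influx(-1), ">= 0")
  expect_error(effective_influx(1, potency = 0), "> 0")
})
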