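p5 <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))

test_that("body burden counts i-1 particles per class-i cell", {
  expect_equal(total_toxicant(c(100, 0, 0, 0, 0)), 0)
  expect_equal(total_toxicant(c(0, 0, 0, 0, 10)), 40)
  # at the low-exposure stationary state the burden plateaus near 7.6
  eq <- oracle_equilibrium(ref_b, ref_d, 1)
  expect_equal(total_toxicant(eq), 7.618461, tolerance = 1e-6)
})

test_that("cell loss is measured against the 100 % baseline", {
  expect_equal(percent_cell_loss(c(100, 0, 0, 0, 0), 100), 0)
  expect_equal(percent_cell_loss(50, 100), 50)
  expect_error(percent_cell_loss(50, 0), "> 0")
  expect_equal(percent_cell_loss(oracle_equilibrium(ref_b, ref_d, 9), 100),
               16.5602, tolerance = 1e-4)
  expect_equal(percent_cell_loss(oracle_equilibrium(ref_b, ref_d, 34), 100),
               65.8751, tolerance = 1e-4)
})

test_that("removal amount sums dying cells weighted by their load", {
  expect_equal(removal_amount(c(100, 0, 0, 0, 0), p5), 0)
  expect_equal(removal_amount(c(0, 10, 0, 0, 0), p5), 1.1)
  expect_equal(removal_amount(c(0, 10, 10, 0, 0), p5), 5.1)
})

test_that("elimination rate is the burden-weighted mean death probability", {
  expect_equal(elimination_rate(c(90, 10, 0, 0, 0), p5), 0.11)
  expect_equal(elimination_rate(c(0, 10, 10, 0, 0), p5), 0.17)
  expect_equal(elimination_rate(c(0, 0, 0, 0, 7), p5), 1)
  # undefined, not zero, when there is nothing to eliminate
  expect_true(is.na(elimination_rate(c(100, 0, 0, 0, 0), p5)))
  # k == removal / burden identically
  set.seed(11)
  for (rep in 1:20) {
    N <- runif(5, 0, 50)
    expect_equal(elimination_rate(N, p5),
                 removal_amount(N, p5) / total_toxicant(N))
  }
})

test_that("elimination rate is scale-invariant and bounded by d2 and 1", {
  set.seed(3)
  for (rep in 1:30) {
    N <- runif(5, 0, 40)
    k <- elimination_rate(N, p5)
    expect_equal(elimination_rate(N * runif(1, 0.01, 100), p5), k)
    expect_gte(k, p5$d[2])
    expect_lte(k, 1)
  }
})

test_that("class fractions normalize and reject an empty intestine", {
  expect_equal(class_fractions(c(100, 0, 0, 0, 0)), c(1, 0, 0, 0, 0))
  expect_equal(class_fractions(c(50, 50, 0, 0, 0)), c(0.5, 0.5, 0, 0, 0))
  expect_error(class_fractions(rep(0, 5)), "destroyed")
  eq <- oracle_equilibrium(ref_b, ref_d, 34)
  expect_equal(class_fractions(eq)[1], 0.29401, tolerance = 1e-4)
  set.seed(5)
  for (rep in 1:10) {
    q <- class_fractions(runif(5, 0.01, 10))
    expect_equal(sum(q), 1)
    expect_true(all(q >= 0))
  }
})

test_that("peak detection reports the earliest maximum over stored points", {
  tr <- get_preset("low")
  pk <- peak_toxicant(tr)
  # low exposure: the burden rises monotonically to its plateau
  expect_equal(pk$value, max(tr$C_int))
  expect_equal(pk$value, 7.6185, tolerance = 1e-3)
  mod <- peak_toxicant(get_preset("moderate"))
  expect_equal(mod$value, 43.7688, tolerance = 1e-4)
  expect_equal(mod$time, 18.19, tolerance = 0.02)
})
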