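p5 <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))

test_that("the stationary recursion reproduces hand-evaluated chains", {
  expect_equal(stationary_classes(p5, 0, 100), c(100, 0, 0, 0, 0))
  n99 <- stationary_classes(p5, 1, 99)
  expect_equal(n99[1:3], c(91.67, 7.00, 0.303), tolerance = 1e-2)
  n83 <- stationary_classes(p5, 9, 83.5)
  expect_equal(n83[1:4], c(50.8, 23.9, 8.0, 0.76), tolerance = 1e-2)
  # exact agreement with the independently coded recursion
  for (dc in c(0.5, 1, 9, 34)) {
    for (N in c(40, 83.5, 99))
      expect_equal(stationary_classes(p5, dc, N),
                   oracle_stationary(ref_b, ref_d, dc, N),
                   tolerance = 1e-12)
  }
})

test_that("the fixed-point solver agrees with a bracketing root search", {
  expect_equal(solve_equilibrium(p5, 0)$N, c(100, 0, 0, 0, 0))
  for (dc in c(1, 9, 34)) {
    eq <- solve_equilibrium(p5, dc)
    ref <- oracle_equilibrium(ref_b, ref_d, dc)
    expect_lt(max(abs(eq$N - ref) / pmax(ref, 1e-12)), 1e-7)
    # plugging the solution into the full right-hand side leaves no motion
    expect_lt(max(abs(tkcd_derivatives(eq$N, dc, p5))), 1e-8)
    expect_lt(eq$residual, 1e-8)
  }
})

test_that("equilibrated trajectories match the stationary solver per class", {
  for (dc in c(0, 1, 9, 34)) {
    eq <- solve_equilibrium(p5, dc)
    tr <- if (dc == 0)
      simulate_tkcd(p5, constant_exposure(0), opts = solver_options(t_max = 5))
    else get_precise(dc)
    expect_true(attr(tr, "equilibrated"))
    expect_lt(max(abs(final_state(tr) - eq$N) / pmax(eq$N, 1e-12)), 1e-6)
  }
})

test_that("equilibrium size falls and loss rises with exposure", {
  scan <- equilibrium_scan(p5, seq(0, 34, by = 2))
  expect_true(all(diff(scan$N_total) < 0))
  expect_true(all(diff(scan$loss_pct) > 0))
  expect_equal(scan$loss_pct[1], 0)
})

test_that("exposures beyond what the epithelium can absorb are rejected", {
  expect_error(solve_equilibrium(p5, 35), "admissible")
  expect_warning(scan <- equilibrium_scan(p5, c(9, 35)), "admissible")
  expect_true(is.na(scan$N_total[2]) && !is.na(scan$N_total[1]))
})
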