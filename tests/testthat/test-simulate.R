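test_that("the uncontaminated start stays put without exposure", {
  p <- tkcd_params(10, ref_d)
  tr <- simulate_tkcd(p, constant_exposure(0),
                      opts = solver_options(t_max = 5))
  expect_true(all(abs(tr$N_1 - 100) < 1e-12))
  expect_true(all(tr$C_int == 0))
  expect_true(all(is.na(tr$k)))  # no burden, no defined elimination rate
  expect_true(attr(tr, "equilibrated"))
})

test_that("halving the step changes the endpoint by less than 1e-6 relative", {
  p <- tkcd_params(10, ref_d)
  end <- function(dt) final_state(simulate_tkcd(
    p, constant_exposure(9),
    opts = solver_options(dt = dt, stride = 10L, t_max = 30, eps = 1e-15)))
  a <- end(0.01)
  b <- end(0.005)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-8)), 1e-6)
})

test_that("fixed-step and adaptive solvers agree", {
  p <- tkcd_params(10, ref_d)
  run <- function(m) final_state(simulate_tkcd(
    p, constant_exposure(9),
    opts = solver_options(method = m, stride = 10L, t_max = 30,
                          eps = 1e-15)))
  expect_lt(max(abs(run("rk4") - run("lsoda")) / pmax(run("lsoda"), 1e-8)),
            1e-6)
})

test_that("integration restarts exactly at schedule breakpoints", {
  p <- tkcd_params(10, ref_d)
  # breakpoint off the output grid on purpose
  sch <- exposure_schedule(c(0, 10.005), c(9, 0), horizon = 40)
  tr <- simulate_tkcd(p, sch, opts = solver_options(stride = 5L))
  expect_true(any(tr$t == 10.005))
  expect_equal(tr$delta_c[tr$t == 10.005], 0)  # half-open convention
  expect_equal(sort(unique(tr$delta_c)), c(0, 9))
  # depuration empties the gut again: burden decays (the slowest class
  # washes out at rate d2 = 0.11), cells recover
  expect_lt(tr$C_int[nrow(tr)], 0.05 * tr$C_int[tr$t == 10.005])
  expect_gt(tr$N_total[nrow(tr)], tr$N_total[tr$t == 10.005])
})

test_that("intestine size is monotone non-increasing under constant exposure", {
  for (name in c("low", "moderate", "high")) {
    tr <- get_preset(name)
    expect_true(all(diff(tr$N_total) <= 1e-10))
  }
})

test_that("preset runs equilibrate and match the stationary solver", {
  p <- tkcd_params(10, ref_d)
  for (name in c("low", "moderate", "high")) {
    tr <- get_preset(name)
    expect_true(attr(tr, "equilibrated"))
    expect_true(attr(tr, "admissible"))
    eq <- solve_equilibrium(p, c(low = 1, moderate = 9, high = 34)[[name]])
    # eps = 1e-9 on the rates puts the endpoint within ~1e-8 cells of the
    # fixed point; the tighter per-class relative check runs on the
    # eps = 1e-12 trajectories in test-equilibrium.R
    expect_lt(max(abs(final_state(tr) - eq$N)), 1e-6)
  }
  expect_error(run_preset("extreme"))
})

test_that("inadmissible exposure errors by default and clamps on request", {
  p <- tkcd_params(10, ref_d)
  expect_error(
    simulate_tkcd(p, constant_exposure(120),
                  opts = solver_options(t_max = 5)),
    "inadmissible")
  expect_warning(
    tr <- simulate_tkcd(p, constant_exposure(120),
                        opts = solver_options(t_max = 5), clamp = TRUE),
    "clamped")
  expect_false(attr(tr, "admissible"))
  expect_gt(attr(tr, "max_ratio"), 1)
})

test_that("balance identities hold along a simulated trajectory", {
  p <- tkcd_params(10, ref_d)
  tr <- get_preset("moderate")
  idx <- unique(round(seq(1, nrow(tr), length.out = 40)))
  w <- 0:4
  for (i in idx) {
    N <- as.numeric(tr[i, paste0("N_", 1:5)])
    dN <- tkcd_derivatives(N, tr$delta_c[i], p)
    # absolute comparison: near equilibrium both sides are ~0
    expect_lt(abs(sum(dN) - (p$b - sum(p$d * N))), 1e-8)
    r <- tr$delta_c[i] / sum(N)
    expect_lt(abs(sum(w * dN) -
                  (sum((1 - p$d[-5]) * r * N[-5]) - sum(p$d * N * w))),
              1e-8)
  }
})
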