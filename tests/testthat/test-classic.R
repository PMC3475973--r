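test_that("one-compartment closed form has the expected limits", {
  p <- one_compartment(k_a = 0.2, k_e = 0.1, C_ext = 10)
  expect_equal(one_compartment_solution(p, 0), 0)
  expect_equal(one_compartment_solution(p, 1e9), 0.2 / 0.1 * 10)
  # k_a = k_e: the asymptote is C_ext itself
  expect_equal(one_compartment_solution(
    one_compartment(0.3, 0.3, 7), 1e9), 7)
  # depuration: pure exponential decay
  dep <- one_compartment(0.2, 0.1, C_ext = 0, C0 = 5)
  expect_equal(one_compartment_solution(dep, c(0, 10)),
               c(5, 5 * exp(-1)))
  # degenerate k_e = 0: linear accumulation
  expect_equal(one_compartment_solution(
    one_compartment(0.2, 0, 10), c(0, 5)), c(0, 10))
})

test_that("closed form matches numerical integration of the linear ODE", {
  p <- one_compartment(k_a = 0.25, k_e = 0.08, C_ext = 12, C0 = 3)
  tt <- seq(0, 60, by = 0.5)
  num <- deSolve::ode(y = c(C = p$C0), times = tt,
                      func = function(t, y, parms)
                        list(p$k_a * p$C_ext - p$k_e * y),
                      rtol = 1e-12, atol = 1e-12)[, 2]
  expect_lt(max(abs(num - one_compartment_solution(p, tt))), 1e-8)
})

test_that("phase-switch constructors enforce the scenario orderings", {
  expect_error(phase_switch(1, k_a1 = 0.2, k_e1 = 0.2, k_e2 = 0.1,
                            switch_time = 5, C_ext = 10),
               "k_e1 < k_e2")
  expect_error(phase_switch(2, k_a1 = 0.1, k_a2 = 0.2, k_e1 = 0.1,
                            switch_time = 5, C_ext = 10),
               "k_a1 > k_a2")
  expect_error(phase_switch(1, k_a1 = 0.2, k_e1 = 0.1, k_e2 = 0.2,
                            C_ext = 10),
               "switch_time")
  expect_error(phase_switch(4, k_a1 = 0.2, k_e1 = 0.1, k_e2 = 0.2,
                            switch_time = 5, C_ext = 10),
               "variant")
})

test_that("an untriggered switch reduces to the one-compartment solution", {
  tt <- seq(0, 50, by = 0.25)
  ps <- phase_switch(1, k_a1 = 0.2, k_e1 = 0.1, k_e2 = 0.3,
                     switch_amount = 1e6, C_ext = 10)
  expect_equal(phase_switch_solution(ps, tt),
               one_compartment_solution(one_compartment(0.2, 0.1, 10), tt),
               tolerance = 1e-12)
})

test_that("scenario 1 rises, falls to a lower asymptote, then washes out", {
  tt <- seq(0, 200, by = 0.5)
  ps <- phase_switch(1, k_a1 = 0.2, k_e1 = 0.05, k_e2 = 0.2,
                     switch_time = 20, C_ext = 10, depuration_start = 120)
  C <- phase_switch_solution(ps, tt)
  pre <- C[tt < 20]
  mid <- C[tt >= 20 & tt < 120]
  expect_true(all(diff(pre) > 0))
  expect_true(all(diff(mid) < 0))
  # continuous at the switch and heading for the lower phase-2 asymptote
  expect_lt(abs(C[tt == 20] - max(pre) * 1), 0.5)
  expect_gt(min(mid), 0.2 / 0.2 * 10)
  # depuration washes out toward the pre-exposure level
  expect_lt(C[length(C)], 1e-5)
})

test_that("an amount trigger fires at the analytic crossing time", {
  # C(t) = 40 (1 - exp(-0.05 t)) reaches 20 at t = 20 ln 2
  ps <- phase_switch(1, k_a1 = 0.2, k_e1 = 0.05, k_e2 = 0.5,
                     switch_amount = 20, C_ext = 10)
  tstar <- 20 * log(2)
  tt <- c(tstar - 0.01, tstar + 0.01)
  C <- phase_switch_solution(ps, tt)
  expect_lt(C[1], 20)
  # just after the switch the faster elimination pulls the amount down
  expect_lt(C[2], 20.001)
  grid <- seq(0, 60, by = 0.005)
  Cg <- phase_switch_solution(ps, grid)
  expect_equal(grid[which.max(Cg)], tstar, tolerance = 0.01)
})

test_that("a single contaminated class yields a constant elimination rate", {
  # two classes: the only contaminated class is the top one (d = 1), the
  # degenerate case where classic constant-k kinetics are exact
  p2 <- tkcd_params(10, c(0.1, 1))
  tr <- simulate_tkcd(p2, constant_exposure(1),
                      opts = solver_options(t_max = 40))
  ks <- effective_k_series(tr, p2)
  expect_true(all(abs(ks$k[!is.na(ks$k)] - 1) < 1e-12))
})

test_that("the elimination-rate series starts at d2 and ends at equilibrium", {
  hi <- get_preset("high")
  ks <- effective_k_series(hi)
  expect_true(is.na(ks$k[1]))
  first <- ks$k[which(!is.na(ks$k))[1]]
  expect_lt(abs(first - 0.11), 1e-3)
  eq <- solve_equilibrium(tkcd_params(ref_b, ref_d), 34)
  expect_equal(ks$k[nrow(ks)], eq$k, tolerance = 1e-6)
  # k only ever grows along this monotone intoxication
  expect_true(all(diff(ks$k[!is.na(ks$k)]) > -1e-9))
})

test_that("the diagnostic least-squares overlay recovers known constants", {
  true <- one_compartment(k_a = 0.3, k_e = 0.12, C_ext = 8)
  tt <- seq(0, 60, by = 1)
  fit <- fit_one_compartment(tt, one_compartment_solution(true, tt),
                             C_ext = 8)
  expect_equal(fit$k_a, 0.3, tolerance = 1e-3)
  expect_equal(fit$k_e, 0.12, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-6)
})
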