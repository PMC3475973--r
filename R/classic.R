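#' Classic one-compartment toxicokinetic model
#'
#' The linear model `dC_int/dt = k_a * C_ext - k_e * C_int`: uptake at a
#' constant absorption rate `k_a` from food at concentration `C_ext`,
#' elimination at a constant rate `k_e`. This is the phenomenological model
#' the cell-demography system generalizes — it corresponds to a single
#' contaminated class, where the elimination rate is genuinely constant.
#'
#' @param k_a Absorption rate constant (per time unit, >= 0).
#' @param k_e Elimination rate constant (per time unit, >= 0).
#' @param C_ext External (food) concentration (>= 0).
#' @param C0 Initial internal amount (>= 0).
#' @return An object of class `one_compartment`.
#' @export
one_compartment <- function(k_a, k_e, C_ext, C0 = 0) {
  for (nm in c("k_a", "k_e", "C_ext", "C0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single finite number >= 0", nm),
           call. = FALSE)
  }
  structure(list(k_a = k_a, k_e = k_e, C_ext = C_ext, C0 = C0),
            class = "one_compartment")
}

#' Closed-form solution of the one-compartment model
#'
#' For `k_e > 0`,
#' `C(t) = (k_a/k_e) * C_ext * (1 - exp(-k_e t)) + C0 * exp(-k_e t)`;
#' for `k_e = 0` accumulation is linear, `C(t) = C0 + k_a * C_ext * t`.
#'
#' @param p A [one_compartment()] object.
#' @param t Time(s), >= 0 (vectorized).
#' @return Internal amount(s) at `t`.
#' @export
one_compartment_solution <- function(p, t) {
  if (!inherits(p, "one_compartment"))
    stop("`p` must be a `one_compartment` object", call. = FALSE)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  if (p$k_e == 0) return(p$C0 + p$k_a * p$C_ext * t)
  asym <- p$k_a / p$k_e * p$C_ext
  asym + (p$C0 - asym) * exp(-p$k_e * t)
}

#' Phase-switching variants of the one-compartment model
#'
#' Phenomenological extensions that reproduce a rise-then-fall internal
#' concentration under constant exposure by switching rate constants once
#' during intoxication:
#'
#' * variant 1 — one `k_a`, two elimination constants with
#'   `k_e1 < k_e2`: elimination speeds up after the switch, pulling the
#'   concentration down to a lower asymptote.
#' * variant 2 — two absorption constants with `k_a1 > k_a2`, one `k_e`:
#'   absorption slows after the switch.
#' * variant 3 — both pairs change (`k_e1 < k_e2` and `k_a1 > k_a2`).
#'
#' The switch is triggered either after a fixed time of intoxication
#' (`switch_time`) or when the internal amount first reaches a threshold
#' (`switch_amount`); exactly one trigger must be given. From
#' `depuration_start` onwards the external concentration is set to 0
#' (uncontaminated food) and the amount washes out exponentially.
#'
#' @param variant 1, 2 or 3.
#' @param k_a1,k_e1 Phase-1 absorption and elimination constants.
#' @param k_a2,k_e2 Phase-2 constants; default to the phase-1 values where
#'   the variant leaves them unchanged.
#' @param switch_time Time of the phase switch, or `NULL`.
#' @param switch_amount Internal amount triggering the switch, or `NULL`.
#' @param depuration_start Time at which exposure ends (`Inf` for none).
#' @inheritParams one_compartment
#' @return An object of class `phase_switch`.
#' @export
phase_switch <- function(variant, k_a1, k_e1, k_a2 = k_a1, k_e2 = k_e1,
                         switch_time = NULL, switch_amount = NULL,
                         C_ext, C0 = 0, depuration_start = Inf) {
  if (!variant %in% 1:3)
    stop("`variant` must be 1, 2 or 3", call. = FALSE)
  for (nm in c("k_a1", "k_e1", "k_a2", "k_e2", "C_ext", "C0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single finite number >= 0", nm),
           call. = FALSE)
  }
  if (variant %in% c(1, 3) && !(k_e1 < k_e2))
    stop("variant with two elimination constants requires k_e1 < k_e2",
         call. = FALSE)
  if (variant %in% c(2, 3) && !(k_a1 > k_a2))
    stop("variant with two absorption constants requires k_a1 > k_a2",
         call. = FALSE)
  if (is.null(switch_time) == is.null(switch_amount))
    stop("give exactly one of `switch_time` or `switch_amount`",
         call. = FALSE)
  if (!is.null(switch_time) &&
      (!is.numeric(switch_time) || switch_time < 0))
    stop("`switch_time` must be >= 0", call. = FALSE)
  if (!is.null(switch_amount) &&
      (!is.numeric(switch_amount) || switch_amount < 0))
    stop("`switch_amount` must be >= 0", call. = FALSE)
  if (!(is.numeric(depuration_start) && length(depuration_start) == 1L &&
        depuration_start >= 0))
    stop("`depuration_start` must be a single time >= 0", call. = FALSE)
  structure(list(variant = variant, k_a1 = k_a1, k_e1 = k_e1,
                 k_a2 = k_a2, k_e2 = k_e2, switch_time = switch_time,
                 switch_amount = switch_amount, C_ext = C_ext, C0 = C0,
                 depuration_start = depuration_start),
            class = "phase_switch")
}

# time at which C(t) = A + (C_start - A) exp(-ke (t - t0)) (or the linear
# ke = 0 form) first reaches `target`; Inf if never
crossing_time <- function(t0, C_start, k_a, k_e, C_ext, target) {
  if (k_e == 0) {
    slope <- k_a * C_ext
    if (target == C_start) return(t0)
    if (slope <= 0 || target < C_start) return(Inf)
    return(t0 + (target - C_start) / slope)
  }
  A <- k_a / k_e * C_ext
  if (target == C_start) return(t0)
  # monotone approach from C_start toward A
  if ((target > C_start) == (A > C_start) && abs(target - A) < abs(C_start - A))
    t0 - log((target - A) / (C_start - A)) / k_e
  else Inf
}

#' Piecewise solution of a phase-switching model
#'
#' Evaluates the internal amount on a time grid, stitching the closed-form
#' one-compartment solutions of the phases together so the series is
#' continuous at the switch and at depuration start. When the switch
#' trigger is never reached, the result is identical to
#' [one_compartment_solution()] with the phase-1 constants.
#'
#' @param p A [phase_switch()] object.
#' @param times Increasing time grid, >= 0.
#' @return Numeric vector of internal amounts along `times`.
#' @export
phase_switch_solution <- function(p, times) {
  if (!inherits(p, "phase_switch"))
    stop("`p` must be a `phase_switch` object", call. = FALSE)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) < 0))
    stop("`times` must be a non-decreasing grid of times >= 0",
         call. = FALSE)

  t_switch <- if (!is.null(p$switch_time)) p$switch_time
              else crossing_time(0, p$C0, p$k_a1, p$k_e1, p$C_ext,
                                 p$switch_amount)
  if (t_switch > p$depuration_start) t_switch <- Inf  # never triggered

  # breakpoints define up to three regimes; constants/C_ext per regime
  bps <- sort(unique(c(0, t_switch, p$depuration_start)))
  bps <- bps[is.finite(bps)]
  eval_from <- function(t0, C_start, tt) {
    post_switch <- t0 >= t_switch
    ka <- if (post_switch) p$k_a2 else p$k_a1
    ke <- if (post_switch) p$k_e2 else p$k_e1
    cext <- if (t0 >= p$depuration_start) 0 else p$C_ext
    one_compartment_solution(one_compartment(ka, ke, cext, C_start), tt - t0)
  }
  out <- numeric(length(times))
  C_start <- p$C0
  for (i in seq_along(bps)) {
    t0 <- bps[i]
    t1 <- if (i < length(bps)) bps[i + 1L] else Inf
    sel <- times >= t0 & times < t1
    if (any(sel)) out[sel] <- eval_from(t0, C_start, times[sel])
    if (is.finite(t1)) C_start <- eval_from(t0, C_start, t1)
  }
  out
}

#' Elimination-rate series along a trajectory
#'
#' Applies [elimination_rate()] at every stored point of a simulated
#' trajectory. While the burden is zero the rate is undefined (`NA`); the
#' first defined value equals `d[2]`, the death probability of the lowest
#' contaminated class, and the series then rises as contamination spreads
#' into more lethal classes, approaching its stationary value at
#' equilibrium. This state dependence is what the constant `k_e` of the
#' classic model cannot represent.
#'
#' @param traj A `tkcd_trajectory`.
#' @param params The parameter object; defaults to the one stored in the
#'   trajectory.
#' @return A data frame with columns `t` and `k`.
#' @export
effective_k_series <- function(traj, params = attr(traj, "params")) {
  if (!inherits(traj, "tkcd_trajectory"))
    stop("`traj` must be a `tkcd_trajectory`", call. = FALSE)
  params <- validate_params(params)
  Nmat <- as.matrix(traj[, paste0("N_", seq_len(params$l))])
  w <- seq_len(params$l) - 1
  burden <- as.numeric(Nmat %*% w)
  removal <- as.numeric(Nmat %*% (params$d * w))
  data.frame(t = traj$t,
             k = ifelse(burden > 0, removal / burden, NA_real_))
}

#' Least-squares overlay of a one-compartment model on a trajectory
#'
#' Diagnostic utility: finds the `(k_a, k_e)` of a classic one-compartment
#' model whose closed-form solution best matches a concentration series in
#' the least-squares sense. This is a descriptive overlay for plots and
#' residual inspection only — fitting the phenomenological constants of the
#' linear model to output of the mechanistic cell-demography model (or to
#' data it explains) does not yield scientifically interpretable parameter
#' estimates, because the underlying elimination rate is state-dependent.
#'
#' @param times,conc Observed time grid and concentration series.
#' @param C_ext External concentration held during the series.
#' @param C0 Initial internal amount.
#' @param start Optional starting values `c(k_a, k_e)`.
#' @return A list with `k_a`, `k_e`, `fitted`, `sse` and the `optim`
#'   convergence code.
#' @export
fit_one_compartment <- function(times, conc, C_ext, C0 = 0, start = NULL) {
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) != length(conc) || length(times) < 3L)
    stop("`times` and `conc` must be equal-length series (n >= 3)",
         call. = FALSE)
  if (is.null(start)) start <- c(k_a = 0.1, k_e = 0.1)
  obj <- function(lp) {
    p <- one_compartment(exp(lp[1L]), exp(lp[2L]), C_ext, C0)
    sum((one_compartment_solution(p, times) - conc)^2)
  }
  fit <- stats::optim(log(start), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  p <- one_compartment(unname(exp(fit$par[1L])), unname(exp(fit$par[2L])),
                       C_ext, C0)
  list(k_a = p$k_a, k_e = p$k_e,
       fitted = one_compartment_solution(p, times),
       sse = fit$value, convergence = fit$convergence)
}
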