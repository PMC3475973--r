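#' Solver options
#'
#' Numerical settings for [simulate_tkcd()]. The default is a fixed-step
#' classical Runge-Kutta integrator (`"rk4"`, step `dt = 0.01` time units),
#' which is cheap and accurate for this non-stiff system at realistic
#' parameter values; `"lsoda"` switches to an adaptive, stiffness-capable
#' method governed by `rtol`/`atol` for unusual parameter ranges.
#'
#' @param method `"rk4"` (fixed step) or `"lsoda"` (adaptive).
#' @param dt Integration step for `"rk4"`, in model time units.
#' @param stride Integer >= 1: store every `stride`-th step, i.e. output
#'   spacing `dt * stride`. Observables (and peak detection) are computed at
#'   stored points only.
#' @param rtol,atol Relative and absolute tolerances for `"lsoda"`.
#' @param eps Equilibrium detection threshold on `max(abs(dN/dt))`
#'   (cells per time unit): when all rates fall below `eps` in the last
#'   exposure segment, the run stops early and is flagged equilibrated.
#' @param t_max Default integration horizon (time units) when the exposure
#'   schedule does not carry its own.
#' @return An object of class `tkcd_solver_options`.
#' @export
solver_options <- function(method = c("rk4", "lsoda"), dt = 0.01,
                           stride = 1L, rtol = 1e-10, atol = 1e-12,
                           eps = 1e-9, t_max = 200) {
  method <- match.arg(method)
  for (nm in c("dt", "rtol", "atol", "eps", "t_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
  }
  if (!is.numeric(stride) || length(stride) != 1L || stride != round(stride) ||
      stride < 1)
    stop("`stride` must be a positive integer", call. = FALSE)
  structure(list(method = method, dt = dt, stride = as.integer(stride),
                 rtol = rtol, atol = atol, eps = eps, t_max = t_max),
            class = "tkcd_solver_options")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate the cell-demography system over an exposure schedule
#'
#' Numerically solves the contamination-class ODE system
#' ([tkcd_derivatives()]) from the uncontaminated steady state (or a
#' user-supplied state) over a piecewise-constant exposure schedule.
#' Integration restarts exactly at each schedule breakpoint, so step changes
#' in the influx are honoured without smearing. The run stops at the horizon
#' or, within the last exposure segment, as soon as all rates drop below the
#' equilibrium threshold `opts$eps` (flagged in the result).
#'
#' Observables are computed after integration at the stored points: total
#' intestine size, body burden `C_int`, percentage cell loss relative to the
#' size at the start of the run, the instantaneous elimination rate `k`
#' (`NA` while the burden is zero), and the class fractions `q_i`.
#'
#' The admissibility condition `delta_c/N <= 1` is checked at every
#' right-hand-side evaluation. By default a violation aborts the run;
#' `clamp = TRUE` clamps the absorption probability at 1 instead, records a
#' warning, and marks the trajectory inadmissible.
#'
#' @param params A [tkcd_params()] object.
#' @param schedule An [exposure_schedule()], or a single number for constant
#'   exposure.
#' @param state0 Starting class occupancies; defaults to
#'   [initial_state()]`(params)`.
#' @param opts [solver_options()].
#' @param clamp Clamp inadmissible absorption probabilities at 1 instead of
#'   erroring.
#' @return A data frame of class `tkcd_trajectory` with columns `t`,
#'   `N_1 ... N_l`, `N_total`, `C_int`, `loss_pct`, `k`, `q_1 ... q_l`,
#'   `delta_c`, and attributes `params`, `opts`, `equilibrated`,
#'   `admissible`, `max_ratio` and `baseline`.
#' @examples
#' p <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))
#' tr <- simulate_tkcd(p, constant_exposure(9), opts = solver_options(t_max = 50))
#' peak_toxicant(tr)
#' @export
simulate_tkcd <- function(params, schedule, state0 = NULL,
                          opts = solver_options(), clamp = FALSE) {
  params <- validate_params(params)
  schedule <- as_schedule(schedule)
  if (!inherits(opts, "tkcd_solver_options"))
    stop("`opts` must come from solver_options()", call. = FALSE)
  state0 <- if (is.null(state0)) initial_state(params)
            else check_state(state0, l = params$l)
  t_end <- schedule$horizon %||% opts$t_max
  if (t_end <= 0) stop("integration horizon must be positive", call. = FALSE)

  b <- params$b
  d <- params$d
  l <- params$l
  tracker <- new.env(parent = emptyenv())
  tracker$max_ratio <- 0
  tracker$clamped <- FALSE

  rhs <- function(t, y, parms) {
    if (any(!is.finite(y)))
      stop("non-finite state encountered during integration", call. = FALSE)
    dc <- parms
    if (dc > 0) {
      Ntot <- sum(y)
      if (Ntot <= 0)
        stop("intestine destroyed: N reached 0 under positive influx",
             call. = FALSE)
      r <- dc / Ntot
      if (r > tracker$max_ratio) tracker$max_ratio <- r
      if (r > 1 + 1e-12) {
        if (!clamp)
          stop(sprintf(
            "inadmissible exposure at t = %.4g: delta_c/N = %.6g exceeds 1",
            t, r), call. = FALSE)
        tracker$clamped <- TRUE
        r <- 1
      } else if (r > 1) r <- 1
    } else r <- 0
    list(c(b, (1 - d[-l]) * r * y[-l]) - (d + (1 - d) * r) * y)
  }

  deriv_now <- function(y, dc) {
    r <- if (dc > 0) min(dc / sum(y), 1) else 0
    c(b, (1 - d[-l]) * r * y[-l]) - (d + (1 - d) * r) * y
  }

  out_dt <- opts$dt * opts$stride
  starts <- schedule$times[schedule$times < t_end]
  levels <- schedule$levels[schedule$times < t_end]
  ends <- c(starts[-1L], t_end)

  integrate_piece <- function(y0, t0, t1, dc) {
    tt <- seq(t0, t1, by = out_dt)
    if (tt[length(tt)] < t1 - 1e-12) tt <- c(tt, t1)
    if (length(tt) < 2L) tt <- c(t0, t1)
    if (opts$method == "rk4") {
      deSolve::ode(y = y0, times = tt, func = rhs, parms = dc,
                   method = "rk4", hini = opts$dt)
    } else {
      deSolve::ode(y = y0, times = tt, func = rhs, parms = dc,
                   method = "lsoda", rtol = opts$rtol, atol = opts$atol)
    }
  }

  pieces <- list()
  piece_dc <- numeric(0)
  y <- state0
  equilibrated <- FALSE
  for (s in seq_along(starts)) {
    final_seg <- s == length(starts)
    # chunk the final segment so equilibration can stop the run early
    chunk <- if (final_seg) max(5, out_dt) else ends[s] - starts[s]
    t0 <- starts[s]
    while (t0 < ends[s] - 1e-12) {
      t1 <- min(t0 + chunk, ends[s])
      out <- integrate_piece(y, t0, t1, levels[s])
      y <- as.numeric(out[nrow(out), -1L])
      pieces[[length(pieces) + 1L]] <- out
      piece_dc <- c(piece_dc, levels[s])
      t0 <- t1
      if (final_seg && max(abs(deriv_now(y, levels[s]))) < opts$eps) {
        equilibrated <- TRUE
        break
      }
    }
    if (equilibrated) break
  }
  if (!equilibrated)
    equilibrated <- max(abs(deriv_now(y, levels[length(levels)]))) < opts$eps
  if (tracker$clamped)
    warning(sprintf(paste0("delta_c/N exceeded 1 during the run ",
                           "(max %.4g); absorption probability clamped, ",
                           "trajectory marked inadmissible"),
                    tracker$max_ratio), call. = FALSE)

  # stitch pieces: at a breakpoint keep the row of the later piece (its
  # delta_c follows the half-open segment convention)
  rows <- list()
  dc_col <- list()
  for (i in seq_along(pieces)) {
    m <- unclass(pieces[[i]])
    keep <- if (i < length(pieces)) seq_len(nrow(m) - 1L) else seq_len(nrow(m))
    rows[[i]] <- m[keep, , drop = FALSE]
    dc_col[[i]] <- rep(piece_dc[i], length(keep))
  }
  m <- do.call(rbind, rows)
  times <- m[, 1L]
  Nmat <- m[, -1L, drop = FALSE]
  if (any(!is.finite(Nmat)))
    stop("non-finite state in trajectory", call. = FALSE)
  if (any(Nmat < -1e-9))
    stop("negative class occupancy in trajectory", call. = FALSE)
  Nmat[Nmat < 0] <- 0

  baseline <- sum(state0)
  w <- seq_len(l) - 1
  Ntot <- rowSums(Nmat)
  Cint <- as.numeric(Nmat %*% w)
  removal <- as.numeric(Nmat %*% (d * w))
  k <- ifelse(Cint > 0, removal / Cint, NA_real_)
  qmat <- Nmat / Ntot
  loss <- if (baseline > 0) 100 * (1 - Ntot / baseline) else NA_real_

  traj <- data.frame(t = times, Nmat, N_total = Ntot, C_int = Cint,
                     loss_pct = loss, k = k, qmat,
                     delta_c = unlist(dc_col))
  names(traj) <- c("t", paste0("N_", seq_len(l)), "N_total", "C_int",
                   "loss_pct", "k", paste0("q_", seq_len(l)), "delta_c")
  rownames(traj) <- NULL
  structure(traj,
            class = c("tkcd_trajectory", "data.frame"),
            params = params, opts = opts, schedule = schedule,
            equilibrated = equilibrated,
            admissible = tracker$max_ratio <= 1 + 1e-12 && !tracker$clamped,
            max_ratio = tracker$max_ratio,
            baseline = baseline)
}

#' Built-in exposure scenarios
#'
#' Three reference scenarios at `b = 10`,
#' `d = (0.1, 0.11, 0.2, 0.9, 1)`, started from the uncontaminated
#' equilibrium of 100 cells: low (`delta_c = 1`), moderate (`delta_c = 9`)
#' and high (`delta_c = 34`) constant toxicity. Each run integrates to
#' equilibration (horizon 250 time units, which all three scenarios reach
#' with rates below the default threshold well before the end).
#'
#' @param name `"low"`, `"moderate"` or `"high"`.
#' @param opts [solver_options()]; the default extends the horizon to 250.
#' @return A `tkcd_trajectory` (see [simulate_tkcd()]).
#' @examples
#' \donttest{
#' tr <- run_preset("moderate")
#' peak_toxicant(tr)
#' }
#' @export
run_preset <- function(name = c("low", "moderate", "high"),
                       opts = solver_options(t_max = 250)) {
  name <- match.arg(name)
  dc <- c(low = 1, moderate = 9, high = 34)[[name]]
  simulate_tkcd(preset_params(), constant_exposure(dc), opts = opts)
}

#' @rdname run_preset
#' @export
preset_params <- function() {
  tkcd_params(b = 10, d = c(0.1, 0.11, 0.2, 0.9, 1))
}

#' @export
print.tkcd_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("TKCD trajectory: %d stored points, t in [%g, %g]\n",
              n, x$t[1L], x$t[n]))
  cat(sprintf("  equilibrated: %s  admissible: %s (max delta_c/N = %.4g)\n",
              attr(x, "equilibrated"), attr(x, "admissible"),
              attr(x, "max_ratio")))
  pk <- peak_toxicant(x)
  cat(sprintf("  final: N = %.6g cells, C_int = %.6g, loss = %.4g%%\n",
              x$N_total[n], x$C_int[n], x$loss_pct[n]))
  cat(sprintf("  peak C_int = %.6g at t = %.6g\n", pk$value, pk$time))
  invisible(x)
}
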