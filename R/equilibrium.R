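#' Stationary class occupancies for an assumed intestine size
#'
#' At constant influx `delta_c` the stationary states of the
#' contamination-class system satisfy a forward recursion in the class
#' index: writing `r = delta_c / N` for an assumed intestine size `N`,
#' \deqn{N_1 = \frac{b}{d_1 + (1 - d_1) r}, \qquad
#'       N_i = \frac{(1 - d_{i-1}) r}{d_i + (1 - d_i) r} N_{i-1},}
#' with the last class reducing to `N_l = (1 - d_{l-1}) r N_{l-1}` because
#' `d_l = 1`. These proportionality relations determine the composition of
#' the epithelium given its size; [solve_equilibrium()] closes the system by
#' requiring the sizes to be self-consistent.
#'
#' @param params A [tkcd_params()] object.
#' @param delta_c Constant influx (>= 0).
#' @param N Assumed intestine size (> 0).
#' @return Numeric vector of stationary class occupancies (length
#'   `params$l`). For `delta_c = 0` this is the uncontaminated steady state
#'   `(b/d1, 0, ..., 0)` regardless of `N`.
#' @export
stationary_classes <- function(params, delta_c, N) {
  params <- validate_params(params)
  if (!is.numeric(delta_c) || length(delta_c) != 1L || !is.finite(delta_c) ||
      delta_c < 0)
    stop("`delta_c` must be a single finite number >= 0", call. = FALSE)
  if (delta_c == 0) return(initial_state(params))
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("`N` must be a single number > 0", call. = FALSE)
  d <- params$d
  l <- params$l
  r <- delta_c / N
  out <- numeric(l)
  out[1L] <- params$b / (d[1L] + (1 - d[1L]) * r)
  for (i in 2:l)
    out[i] <- (1 - d[i - 1L]) * r * out[i - 1L] / (d[i] + (1 - d[i]) * r)
  out
}

#' Solve for the stationary intestine state at constant exposure
#'
#' Finds the self-consistent intestine size `N*` such that the stationary
#' class occupancies implied by `N*` ([stationary_classes()]) sum back to
#' `N*`. The primary method is damped fixed-point iteration
#' `N <- (1 - damping) * N + damping * sum(stationary_classes(N))` started
#' from the uncontaminated size `b/d1`; if it fails to converge, a
#' bracketing root search on `g(N) = sum(stationary_classes(N)) - N` over
#' `(0, b/d1]` is used instead. A coarse sign-change scan of `g` guards
#' against silently picking one of several stationary sizes; if more than
#' one root is found, all are reported in the error message.
#'
#' The solution is only accepted if it is admissible (`delta_c/N* <= 1`) and
#' if plugging it into the full right-hand side leaves residual rates below
#' `residual_tol`.
#'
#' @inheritParams stationary_classes
#' @param damping Damping factor of the fixed-point iteration, in (0, 1].
#' @param tol Relative convergence tolerance on the intestine size.
#' @param max_iter Maximum fixed-point iterations before falling back to the
#'   root search.
#' @param residual_tol Acceptance threshold on `max(abs(dN/dt))` at the
#'   solution.
#' @return An object of class `tkcd_equilibrium`: a list with the class
#'   vector `N`, the totals `N_total` and `C_int`, `loss_pct` (relative to
#'   `b/d1`), the elimination rate `k`, class fractions `q`, `delta_c`,
#'   `iterations` and the rate `residual`.
#' @examples
#' p <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))
#' solve_equilibrium(p, delta_c = 9)
#' @export
solve_equilibrium <- function(params, delta_c, damping = 0.5, tol = 1e-10,
                              max_iter = 1e5, residual_tol = 1e-8) {
  params <- validate_params(params)
  if (!is.numeric(delta_c) || length(delta_c) != 1L || !is.finite(delta_c) ||
      delta_c < 0)
    stop("`delta_c` must be a single finite number >= 0", call. = FALSE)
  N0 <- params$b / params$d[1L]

  if (delta_c == 0) {
    return(equilibrium_result(params, delta_c, initial_state(params),
                              iterations = 0L, residual_tol = residual_tol))
  }

  g <- function(N) sum(stationary_classes(params, delta_c, N)) - N

  # coarse scan for multiple self-consistent sizes
  grid <- seq(N0 * 1e-6, N0, length.out = 257L)
  gv <- vapply(grid, g, numeric(1))
  flips <- which(diff(sign(gv)) != 0)
  if (length(flips) > 1L) {
    roots <- vapply(flips, function(i)
      stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-12)$root,
      numeric(1))
    roots <- unique(signif(roots, 8))
    if (length(roots) > 1L)
      stop(sprintf(
        "multiple stationary intestine sizes found: %s; refusing to choose",
        paste(format(roots), collapse = ", ")), call. = FALSE)
  }

  N <- N0
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Nn <- (1 - damping) * N + damping * sum(stationary_classes(params,
                                                               delta_c, N))
    if (!is.finite(Nn) || Nn <= 0) break
    if (abs(Nn - N) / Nn < tol) {
      N <- Nn
      converged <- TRUE
      break
    }
    N <- Nn
  }
  if (!converged) {
    if (length(flips) == 0L)
      stop("no stationary intestine size in (0, b/d1]: fixed-point ",
           "iteration diverged and no sign change bracketed", call. = FALSE)
    N <- stats::uniroot(g, c(grid[flips[1L]], grid[flips[1L] + 1L]),
                        tol = 1e-13)$root
  }

  if (delta_c / N > 1 + 1e-9)
    stop(sprintf(paste0(
      "no admissible stationary state: delta_c/N* = %.6g exceeds 1 ",
      "(the exposure outruns what the surviving epithelium can absorb)"),
      delta_c / N), call. = FALSE)

  equilibrium_result(params, delta_c, stationary_classes(params, delta_c, N),
                     iterations = iter, residual_tol = residual_tol)
}

equilibrium_result <- function(params, delta_c, Nv, iterations,
                               residual_tol) {
  residual <- max(abs(tkcd_derivatives(Nv, delta_c, params, clamp = TRUE)))
  if (residual > residual_tol)
    stop(sprintf(
      "equilibrium solver did not converge: residual rate %.3g > %g",
      residual, residual_tol), call. = FALSE)
  baseline <- params$b / params$d[1L]
  structure(list(
    N = Nv,
    N_total = sum(Nv),
    C_int = total_toxicant(Nv),
    loss_pct = percent_cell_loss(Nv, baseline),
    k = elimination_rate(Nv, params),
    q = class_fractions(Nv),
    delta_c = delta_c,
    iterations = iterations,
    residual = residual,
    params = params), class = "tkcd_equilibrium")
}

#' @export
print.tkcd_equilibrium <- function(x, ...) {
  cat(sprintf("Stationary intestine state at delta_c = %g\n", x$delta_c))
  cat(sprintf("  N* = %.6g cells (loss %.4g%%), C_int = %.6g, k = %s\n",
              x$N_total, x$loss_pct, x$C_int,
              if (is.na(x$k)) "undefined" else sprintf("%.6g", x$k)))
  cat(sprintf("  classes: %s\n", paste(format(x$N, digits = 6),
                                       collapse = ", ")))
  cat(sprintf("  %d iterations, residual rate %.3g, delta_c/N* = %.4g\n",
              x$iterations, x$residual, x$delta_c / x$N_total))
  invisible(x)
}

#' Equilibrium table over an exposure grid
#'
#' Applies [solve_equilibrium()] across a grid of constant influx values.
#' Grid points with no admissible stationary state yield `NA` rows and a
#' single collective warning.
#'
#' @inheritParams solve_equilibrium
#' @param delta_c Numeric vector of influx values (>= 0).
#' @return A data frame with one row per `delta_c`: `delta_c`, `N_total`,
#'   `C_int`, `loss_pct`, `k`.
#' @export
equilibrium_scan <- function(params, delta_c, ...) {
  params <- validate_params(params)
  rows <- lapply(delta_c, function(dc) {
    eq <- tryCatch(solve_equilibrium(params, dc, ...),
                   error = function(e) NULL)
    if (is.null(eq))
      data.frame(delta_c = dc, N_total = NA_real_, C_int = NA_real_,
                 loss_pct = NA_real_, k = NA_real_)
    else
      data.frame(delta_c = dc, N_total = eq$N_total, C_int = eq$C_int,
                 loss_pct = eq$loss_pct, k = eq$k)
  })
  out <- do.call(rbind, rows)
  bad <- out$delta_c[is.na(out$N_total)]
  if (length(bad))
    warning(sprintf("no admissible stationary state at delta_c = %s",
                    paste(format(bad), collapse = ", ")), call. = FALSE)
  out
}
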