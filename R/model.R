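#' Per-cell absorption probability
#'
#' When `delta_c` toxic particles (or toxic units) enter an intestine of
#' `N` cells during one time unit, each surviving cell absorbs one particle
#' with probability `delta_c / N`. A trajectory is only biologically sensible
#' while this ratio stays at or below one; by default an inadmissible ratio
#' is a hard error, since probabilities above one mean the exposure outruns
#' what the remaining epithelium can absorb.
#'
#' @param delta_c Toxicant influx during one time unit (particles or toxic
#'   units, >= 0).
#' @param N Intestine size (total cell count, > 0).
#' @param clamp If `TRUE`, a ratio above 1 is clamped to 1 with a warning
#'   instead of an error. Use only to inspect what the equations do beyond
#'   the admissible region.
#' @return The absorption probability `delta_c / N` (possibly clamped).
#' @examples
#' absorption_probability(1, 100)   # 0.01
#' absorption_probability(34, 34)   # 1, the admissible boundary
#' @export
absorption_probability <- function(delta_c, N, clamp = FALSE) {
  if (!is.numeric(delta_c) || length(delta_c) != 1L || !is.finite(delta_c) ||
      delta_c < 0)
    stop("`delta_c` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N))
    stop("`N` must be a single finite number", call. = FALSE)
  if (N <= 0)
    stop("intestine destroyed: N <= 0, absorption probability undefined",
         call. = FALSE)
  p <- delta_c / N
  if (p > 1) {
    if (!clamp)
      stop(sprintf(paste0("inadmissible exposure: delta_c/N = %.6g exceeds 1",
                          " (absorption probability cannot exceed one)"), p),
           call. = FALSE)
    warning(sprintf("delta_c/N = %.6g clamped to 1", p), call. = FALSE)
    p <- 1
  }
  p
}

#' Right-hand side of the contamination-class ODE system
#'
#' Rates of change of the class occupancies `N` under toxicant influx
#' `delta_c`. Writing `r = delta_c / sum(N)` for the per-cell absorption
#' probability, the system is
#' \deqn{\dot N_1 = b - (d_1 + (1 - d_1) r) N_1}
#' \deqn{\dot N_i = (1 - d_{i-1}) r N_{i-1} - (d_i + (1 - d_i) r) N_i}
#' for the interior classes, and for the last class (where `d_l = 1`)
#' the outflow reduces to `N_l` itself. Cells leave a class either by dying
#' (probability `d_i`) or by surviving and absorbing a particle
#' (probability `(1 - d_i) r`), which promotes them to the next class.
#'
#' @param N Numeric vector of class occupancies (length `params$l`,
#'   non-negative).
#' @param delta_c Toxicant influx during one time unit (>= 0).
#' @param params A [tkcd_params()] object.
#' @inheritParams absorption_probability
#' @return Numeric vector of time derivatives, one per class.
#' @examples
#' p <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))
#' tkcd_derivatives(initial_state(p), delta_c = 0, p)  # all zero
#' tkcd_derivatives(initial_state(p), delta_c = 1, p)
#' @export
tkcd_derivatives <- function(N, delta_c, params, clamp = FALSE) {
  params <- validate_params(params)
  N <- as.numeric(N)
  if (length(N) != params$l)
    stop(sprintf("state has length %d but params define %d classes",
                 length(N), params$l), call. = FALSE)
  if (!all(is.finite(N)))
    stop("state must be finite", call. = FALSE)
  d <- params$d
  l <- params$l
  r <- if (delta_c == 0) 0 else absorption_probability(delta_c, sum(N), clamp)
  # outflow coefficient of the last class is d_l + (1 - d_l) r = 1 exactly
  inflow <- c(params$b, (1 - d[-l]) * r * N[-l])
  inflow - (d + (1 - d) * r) * N
}
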