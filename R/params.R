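#' Cell demography parameters
#'
#' Defines the demography of the gut epithelium: a constant production of
#' `b` new uncontaminated cells per unit time, and `l = length(d)`
#' contamination classes with death probabilities `d`. A cell in class `i`
#' carries `i - 1` toxic particles (class 1 is uncontaminated) and dies with
#' probability `d[i]` per unit time. The death probabilities must be strictly
#' increasing, with a positive baseline turnover `d[1] > 0` and certain death
#' in the most contaminated class, `d[l] = 1` (which is what keeps cells
#' turning over at all in the fully loaded class).
#'
#' All rates are per model time unit; the time-scale constant is taken as 1,
#' so death probabilities act as per-unit-time hazard coefficients in the
#' continuous-time equations.
#'
#' @param b Cell production per unit time (cells). Non-negative scalar.
#' @param d Numeric vector of per-class death probabilities, length >= 2,
#'   strictly increasing, `d[1] > 0`, `d[length(d)] = 1`.
#'
#' @return An object of class `tkcd_params`: a list with elements `b`, `d`
#'   and `l` (the number of classes).
#'
#' @examples
#' p <- tkcd_params(b = 10, d = c(0.1, 0.11, 0.2, 0.9, 1))
#' p
#' initial_state(p)
#' @seealso [initial_state()], [discretize_mortality()] to derive `d` from a
#'   continuous mortality curve, [simulate_tkcd()].
#' @export
tkcd_params <- function(b, d) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("`b` must be a single finite number", call. = FALSE)
  if (b < 0)
    stop("`b` must be >= 0 (cell production cannot be negative)", call. = FALSE)
  d <- as.numeric(d)
  validate_d(d)
  structure(list(b = as.numeric(b), d = d, l = length(d)),
            class = "tkcd_params")
}

# shared by tkcd_params() and discretize_mortality()
validate_d <- function(d) {
  if (length(d) < 2L)
    stop("`d` must have length >= 2 (at least one contaminated class)",
         call. = FALSE)
  if (!all(is.finite(d)))
    stop("`d` must be finite", call. = FALSE)
  if (d[1L] <= 0)
    stop("`d[1]` must be > 0 (uncontaminated cells need a baseline turnover)",
         call. = FALSE)
  l <- length(d)
  if (d[l] != 1)
    stop("`d[l]` must equal 1 (certain death in the most contaminated class)",
         call. = FALSE)
  if (any(diff(d) <= 0))
    stop("`d` must be strictly increasing across contamination classes",
         call. = FALSE)
  invisible(d)
}

#' Validate a parameter object
#'
#' Re-checks every invariant of a [tkcd_params()] object and returns it
#' unchanged. Useful after manual slot manipulation or deserialization.
#'
#' @param params A `tkcd_params` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error naming
#'   the violated constraint.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "tkcd_params"))
    stop("`params` must be a `tkcd_params` object", call. = FALSE)
  if (!is.numeric(params$b) || length(params$b) != 1L ||
      !is.finite(params$b) || params$b < 0)
    stop("`b` must be a single finite number >= 0", call. = FALSE)
  validate_d(params$d)
  if (params$l != length(params$d))
    stop("`l` must equal length(d)", call. = FALSE)
  params
}

#' @export
print.tkcd_params <- function(x, ...) {
  cat("Cell demography parameters\n")
  cat(sprintf("  classes (l): %d\n", x$l))
  cat(sprintf("  birth rate (b): %g cells per time unit\n", x$b))
  cat(sprintf("  death probabilities (d): %s\n",
              paste(format(x$d), collapse = ", ")))
  cat(sprintf("  uncontaminated equilibrium b/d1: %g cells\n",
              if (x$d[1] > 0) x$b / x$d[1] else NA_real_))
  invisible(x)
}

#' Uncontaminated steady state
#'
#' The starting point of every exposure run: the equilibrium of cellular
#' turnover in an uncontaminated organism, `N1 = b/d1` with all contaminated
#' classes empty. This is the unique fixed point of `dN1/dt = b - d1 * N1`.
#'
#' @param params A [tkcd_params()] object.
#' @return Numeric vector of length `params$l`, the class occupancies at
#'   time 0.
#' @examples
#' initial_state(tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1)))  # 100, 0, 0, 0, 0
#' @export
initial_state <- function(params) {
  params <- validate_params(params)
  c(params$b / params$d[1L], rep(0, params$l - 1L))
}
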