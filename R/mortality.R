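#' Concentration-to-mortality curves
#'
#' A mortality curve maps the per-cell contamination (number of absorbed
#' particles, or toxic units) to the probability of cell death per unit
#' time. Discretizing such a curve over `l` contamination classes produces
#' the death-probability vector `d` of [tkcd_params()]. Three forms are
#' supported:
#'
#' * `"table"` — a user-tabulated set of `(contamination, d)` points,
#'   linearly interpolated. The table must be non-decreasing in `d`.
#' * `"linear"` — rises linearly from `d0` at zero contamination to 1 at the
#'   maximal class.
#' * `"sigmoid"` — a saturating exponential
#'   `d0 + (1 - d0) * (1 - exp(-s x)) / (1 - exp(-s xmax))`, pinned to `d0`
#'   at zero and to 1 at the maximal contamination `xmax`; `steepness = s`
#'   controls how early mortality saturates.
#'
#' Only monotonicity and the endpoint conditions (`d0 > 0` for baseline
#' turnover, 1 at the top class) are constrained by the model; the shape in
#' between is substance-specific and phenomenological.
#'
#' @param form One of `"table"`, `"linear"`, `"sigmoid"`.
#' @param table For `form = "table"`: a data frame or matrix with columns
#'   `contamination` and `d` (or a 2-column object in that order).
#' @param d0 For `"linear"` and `"sigmoid"`: death probability at zero
#'   contamination, in (0, 1).
#' @param steepness For `"sigmoid"`: positive saturation rate.
#' @return An object of class `mortality_curve`.
#' @examples
#' crv <- mortality_curve("table",
#'   table = data.frame(contamination = 0:4, d = c(0.1, 0.11, 0.2, 0.9, 1)))
#' discretize_mortality(crv, l = 5)
#' discretize_mortality(mortality_curve("linear", d0 = 0.05), l = 5)
#' @export
mortality_curve <- function(form = c("table", "linear", "sigmoid"),
                            table = NULL, d0 = NULL, steepness = NULL) {
  form <- match.arg(form)
  crv <- switch(form,
    table = {
      if (is.null(table))
        stop("`table` is required for form = \"table\"", call. = FALSE)
      tab <- as.data.frame(table)
      if (ncol(tab) < 2L)
        stop("`table` needs two columns: contamination and d", call. = FALSE)
      if (all(c("contamination", "d") %in% names(tab)))
        tab <- tab[, c("contamination", "d")]
      names(tab) <- c("contamination", "d")
      tab <- tab[order(tab$contamination), ]
      if (any(diff(tab$contamination) <= 0))
        stop("`table` contamination values must be distinct", call. = FALSE)
      if (any(diff(tab$d) < 0))
        stop("`table` mortalities must be non-decreasing in contamination",
             call. = FALSE)
      list(form = form, table = tab)
    },
    linear = {
      check_d0(d0)
      list(form = form, d0 = d0)
    },
    sigmoid = {
      check_d0(d0)
      if (is.null(steepness) || !is.numeric(steepness) ||
          length(steepness) != 1L || !is.finite(steepness) || steepness <= 0)
        stop("`steepness` must be a positive number", call. = FALSE)
      list(form = form, d0 = d0, steepness = steepness)
    })
  structure(crv, class = "mortality_curve")
}

check_d0 <- function(d0) {
  if (is.null(d0) || !is.numeric(d0) || length(d0) != 1L ||
      !is.finite(d0) || d0 <= 0 || d0 >= 1)
    stop("`d0` must be a single number in (0, 1)", call. = FALSE)
  invisible(d0)
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("Mortality curve (%s form)\n", x$form))
  if (x$form == "table") {
    print(x$table, row.names = FALSE)
  } else {
    cat(sprintf("  d0 = %g", x$d0))
    if (x$form == "sigmoid") cat(sprintf(", steepness = %g", x$steepness))
    cat("\n")
  }
  invisible(x)
}

# evaluate a curve at per-cell contamination x, on support [0, xmax]
eval_mortality <- function(curve, x, xmax) {
  switch(curve$form,
    table = {
      tab <- curve$table
      if (min(tab$contamination) > 0 || max(tab$contamination) < xmax)
        stop(sprintf(
          "`table` must cover the contamination range [0, %g]", xmax),
          call. = FALSE)
      stats::approx(tab$contamination, tab$d, xout = x, ties = "ordered")$y
    },
    linear = curve$d0 + (1 - curve$d0) * x / xmax,
    sigmoid = {
      s <- curve$steepness
      curve$d0 + (1 - curve$d0) * (1 - exp(-s * x)) / (1 - exp(-s * xmax))
    })
}

#' Discretize a mortality curve into class death probabilities
#'
#' Samples a [mortality_curve()] at the per-cell contaminations
#' `0, 1, ..., l - 1` carried by the `l` contamination classes. The value at
#' the top class must be 1 within `tol` (it is then pinned to exactly 1 so
#' the resulting vector satisfies the model invariants); the sampled values
#' must be strictly increasing and positive at zero contamination.
#'
#' @param curve A [mortality_curve()].
#' @param l Number of contamination classes (integer >= 2).
#' @param tol Tolerance for pinning the top-class value to 1.
#' @return A death-probability vector of length `l`, valid as the `d`
#'   argument of [tkcd_params()].
#' @export
discretize_mortality <- function(curve, l, tol = 1e-6) {
  if (!inherits(curve, "mortality_curve"))
    stop("`curve` must be a `mortality_curve` object", call. = FALSE)
  if (!is.numeric(l) || length(l) != 1L || l != round(l) || l < 2)
    stop("`l` must be an integer >= 2", call. = FALSE)
  l <- as.integer(l)
  d <- eval_mortality(curve, 0:(l - 1L), xmax = l - 1L)
  if (!all(is.finite(d)))
    stop("mortality curve produced non-finite values", call. = FALSE)
  if (d[1L] <= 0)
    stop("curve value at zero contamination must be > 0 (baseline turnover)",
         call. = FALSE)
  if (abs(d[l] - 1) > tol)
    stop(sprintf(
      "curve value at the top class is %.8g; must equal 1 within tol = %g",
      d[l], tol), call. = FALSE)
  d[l] <- 1
  if (any(diff(d) <= 0))
    stop("sampled mortalities must be strictly increasing across classes",
         call. = FALSE)
  validate_d(d)
  d
}

#' Convert a particle influx to an effective influx in toxic units
#'
#' Under an additive toxicity model, substances that share the shape of the
#' concentration-to-death-rate relation can be expressed on a common scale
#' by weighting each particle by the substance's potency (toxic units per
#' particle). The effective influx `potency * particle_influx` can then
#' drive the same death-probability vector `d` for every such substance.
#' The hybrid case — substances that differ both in potency and in curve
#' shape — is handled by composing this scaling with a substance-specific
#' [mortality_curve()]; no further machinery is needed.
#'
#' @param particle_influx Particles entering the organism per unit time
#'   (>= 0; vectorized).
#' @param potency Toxic units per particle (> 0).
#' @return Effective influx in toxic units, usable as `delta_c`.
#' @examples
#' effective_influx(4.5, potency = 2)   # 9
#' effective_influx(68, potency = 0.5)  # 34
#' @export
effective_influx <- function(particle_influx, potency = 1) {
  if (!is.numeric(potency) || length(potency) != 1L ||
      !is.finite(potency) || potency <= 0)
    stop("`potency` must be a single number > 0", call. = FALSE)
  if (!is.numeric(particle_influx) || any(!is.finite(particle_influx)) ||
      any(particle_influx < 0))
    stop("`particle_influx` must be finite and >= 0", call. = FALSE)
  potency * particle_influx
}
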