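#' Body burden: total toxicant amount in the epithelium
#'
#' A cell in contamination class `i` carries `i - 1` toxic particles, so the
#' amount aggregated in the intestine is `C_int = sum(N_i * (i - 1))`.
#'
#' @param N Numeric vector of class occupancies.
#' @return `C_int`, in particles (or toxic units); zero exactly when all
#'   contaminated classes are empty.
#' @examples
#' total_toxicant(c(100, 0, 0, 0, 0))  # 0
#' total_toxicant(c(0, 0, 0, 0, 10))   # 40
#' @export
total_toxicant <- function(N) {
  N <- check_state(N)
  sum(N * (seq_along(N) - 1))
}

#' Percentage loss of epithelial cells
#'
#' The intestine size at the start of exposure is scaled to 100 %, so model
#' output reads as percentage damage of the gut epithelium regardless of the
#' organism's actual cell count.
#'
#' @param N Class-occupancy vector, or directly the intestine size
#'   (a length-1 number).
#' @param baseline Reference cell count scaled to 100 % (> 0); typically
#'   `b/d1`, the uncontaminated steady state.
#' @return `100 * (1 - sum(N) / baseline)` (percent).
#' @export
percent_cell_loss <- function(N, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1L ||
      !is.finite(baseline) || baseline <= 0)
    stop("`baseline` must be a single number > 0", call. = FALSE)
  N <- check_state(N, allow_scalar = TRUE)
  100 * (1 - sum(N) / baseline)
}

#' Toxicant removed from the intestine per unit time
#'
#' Cells dying in class `i` take their `i - 1` particles with them, so the
#' amount removed during one time unit is `sum(N_i * d_i * (i - 1))`.
#'
#' @inheritParams total_toxicant
#' @param params A [tkcd_params()] object.
#' @return Removal amount per time unit (>= 0).
#' @export
removal_amount <- function(N, params) {
  params <- validate_params(params)
  N <- check_state(N, l = params$l)
  sum(N * params$d * (seq_along(N) - 1))
}

#' Instantaneous elimination rate
#'
#' The fraction of the body burden removed per unit time,
#' \deqn{k = \frac{\sum_i N_i d_i (i-1)}{\sum_i N_i (i-1)}
#'         = \frac{\sum_i q_i d_i (i-1)}{\sum_i q_i (i-1)},}
#' a weighted mean of the death probabilities of the contaminated classes.
#' Unlike the constant elimination rate of the classic one-compartment
#' model, `k` depends on the current composition of the epithelium (the
#' class fractions `q_i`) but not on its absolute size: scaling every `N_i`
#' by the same factor leaves `k` unchanged. It is bounded by
#' `d[2] <= k <= 1` whenever defined, and equals `d[j]` exactly when only
#' class `j` is contaminated — the degenerate case where classic
#' single-compartment kinetics are recovered.
#'
#' @inheritParams removal_amount
#' @return `k` (per time unit), or `NA_real_` when the burden is zero: with
#'   nothing to eliminate the rate is undefined, never 0.
#' @examples
#' p <- tkcd_params(10, c(0.1, 0.11, 0.2, 0.9, 1))
#' elimination_rate(c(90, 10, 0, 0, 0), p)   # 0.11, only class 2 occupied
#' elimination_rate(c(0, 10, 10, 0, 0), p)   # 5.1 / 30 = 0.17
#' elimination_rate(c(100, 0, 0, 0, 0), p)   # NA: burden is zero
#' @export
elimination_rate <- function(N, params) {
  params <- validate_params(params)
  N <- check_state(N, l = params$l)
  burden <- total_toxicant(N)
  if (burden == 0) return(NA_real_)
  removal_amount(N, params) / burden
}

#' Relative sizes of the contamination classes
#'
#' @inheritParams total_toxicant
#' @return Vector `q` with `q_i = N_i / sum(N)`; non-negative, summing
#'   to 1. Errors when the intestine is empty.
#' @export
class_fractions <- function(N) {
  N <- check_state(N)
  tot <- sum(N)
  if (tot <= 0)
    stop("intestine destroyed: N = 0, class fractions undefined",
         call. = FALSE)
  N / tot
}

#' Peak body burden of a trajectory
#'
#' The maximum of `C_int` over the stored trajectory points and the time at
#' which it is attained (earliest such time on ties). The reported peak time
#' is resolved only to the storage stride of the trajectory; no
#' interpolation between stored points is attempted.
#'
#' @param traj A [simulate_tkcd()] trajectory.
#' @return A list with elements `time` and `value`.
#' @export
peak_toxicant <- function(traj) {
  if (!inherits(traj, "tkcd_trajectory") || nrow(traj) == 0L)
    stop("`traj` must be a non-empty `tkcd_trajectory`", call. = FALSE)
  i <- which.max(traj$C_int)  # which.max picks the first maximum
  list(time = traj$t[i], value = traj$C_int[i])
}

check_state <- function(N, l = NULL, allow_scalar = FALSE) {
  N <- as.numeric(N)
  if (!allow_scalar && length(N) < 2L && is.null(l))
    stop("state `N` must be a class-occupancy vector", call. = FALSE)
  if (!is.null(l) && length(N) != l)
    stop(sprintf("state has length %d but params define %d classes",
                 length(N), l), call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0))
    stop("state occupancies must be finite and >= 0", call. = FALSE)
  N
}
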