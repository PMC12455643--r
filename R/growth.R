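#' Estimate exponential growth rate from an OD730 time series
#'
#' Fits ordinary least squares of `ln(OD730)` on time over the full window
#' provided and reports the slope as the specific growth rate `mu` (h^-1).
#' The whole window is assumed to lie within the exponential phase, as is
#' standard for growth-dilution ALE cultures sampled every couple of hours
#' after dilution; no window search or lag/stationary modelling is done.
#'
#' @param curve A data frame with numeric columns `time_h` (hours, strictly
#'   increasing) and `od730` (optical density at 730 nm, > 0). At least three
#'   points are required.
#'
#' @return A one-row tibble with columns `mu` (h^-1), `se_mu` (standard error
#'   of the slope, h^-1), `n_points`, `t_start` and `t_end` (hours).
#'
#' @examples
#' curve <- tibble::tibble(time_h = seq(0, 10, by = 2),
#'                         od730 = 0.05 * exp(0.052 * seq(0, 10, by = 2)))
#' fit_growth_rate(curve)
#' @export
fit_growth_rate <- function(curve) {
  stopifnot(is.data.frame(curve))
  req <- c("time_h", "od730")
  missing_cols <- setdiff(req, names(curve))
  if (length(missing_cols) > 0) {
    stop("`curve` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  t <- as.numeric(curve$time_h)
  od <- as.numeric(curve$od730)
  if (length(t) < 3) stop("growth curve needs at least 3 points", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(od))) {
    stop("non-finite time or OD values in growth curve", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("time points must be strictly increasing", call. = FALSE)
  if (any(od <= 0)) stop("all OD730 values must be positive", call. = FALSE)

  fit <- stats::lm(log(od) ~ t)
  # noiseless curves trip lm's perfect-fit warning; the zero SE is correct
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    mu = unname(co["t", "Estimate"]),
    se_mu = unname(co["t", "Std. Error"]),
    n_points = length(t),
    t_start = t[1],
    t_end = t[length(t)]
  )
}

#' Generations per growth-dilution cycle
#'
#' A serial-transfer cycle growing from `od_initial` to `od_final` contributes
#' `log2(od_final / od_initial)` doublings. With the usual dilution from an
#' OD730 of ~2.0 down to 0.05 this is `log2(40)` (about 5.32) generations per
#' transfer.
#'
#' @param od_initial OD730 immediately after dilution (> 0).
#' @param od_final OD730 at the end of the cycle (> `od_initial`).
#' @return Number of generations (dimensionless).
#' @export
generations_per_transfer <- function(od_initial, od_final) {
  if (!is.numeric(od_initial) || !is.numeric(od_final) ||
      !is.finite(od_initial) || !is.finite(od_final)) {
    stop("ODs must be finite numbers", call. = FALSE)
  }
  if (od_initial <= 0 || od_final <= 0) stop("ODs must be positive", call. = FALSE)
  if (od_final <= od_initial) stop("od_final must exceed od_initial", call. = FALSE)
  log2(od_final / od_initial)
}

#' Salt-step decision rule for stepwise ALE
#'
#' Decides the next salt concentration in a stepwise salt-stress ALE: the
#' concentration is raised by `step_mM` (capped at `max_mM`) once the current
#' stabilized growth rate is equal to or larger than the stabilized growth
#' rate recorded at the end of the previous salt level. While the culture is
#' still slower than it was at the end of the previous level, the
#' concentration is held. With only one salt level on record the population
#' has, by construction, just stabilized at the starting concentration, so
#' the first step is taken.
#'
#' @param history A data frame with columns `salt_mM` and `mu` (h^-1), one row
#'   per recorded stabilized growth rate, in chronological order. Several rows
#'   per salt level are allowed; the last row is the current state.
#' @param step_mM Salt increment per step (mM, > 0). Default 50.
#' @param max_mM Ceiling on the concentration (mM). Default 400.
#' @return The next salt concentration in mM (scalar).
#' @export
salt_step_controller <- function(history, step_mM = 50, max_mM = 400) {
  stopifnot(is.data.frame(history))
  if (!all(c("salt_mM", "mu") %in% names(history))) {
    stop("`history` needs columns salt_mM and mu", call. = FALSE)
  }
  if (nrow(history) == 0) stop("`history` must be non-empty", call. = FALSE)
  if (!is.numeric(step_mM) || step_mM <= 0) stop("step_mM must be > 0", call. = FALSE)

  salt <- history$salt_mM
  mu <- history$mu
  current_salt <- salt[nrow(history)]
  current_mu <- mu[nrow(history)]

  prev_idx <- which(salt != current_salt)
  if (length(prev_idx) == 0 || current_mu >= mu[max(prev_idx)]) {
    min(current_salt + step_mM, max_mM)
  } else {
    current_salt
  }
}

#' Flag stabilization of a growth-rate series
#'
#' A small helper for driving [salt_step_controller()]: the growth rate is
#' considered stabilized when the last two estimates differ by less than
#' `tol` in relative terms. The underlying experimental protocol gives no
#' numeric criterion; 5% is this package's operational choice.
#'
#' @param mus Numeric vector of successive growth-rate estimates (h^-1).
#' @param tol Relative tolerance (default 0.05).
#' @return Logical scalar.
#' @export
is_stabilized <- function(mus, tol = 0.05) {
  mus <- as.numeric(mus)
  n <- length(mus)
  if (n < 2) return(FALSE)
  prev <- mus[n - 1]
  if (prev == 0) return(mus[n] == 0)
  abs(mus[n] - prev) / abs(prev) < tol
}

#' OD-normalized product titre
#'
#' Normalizes a product (e.g. mannitol) concentration by the culture density
#' at sampling, yielding the standard mg L^-1 OD730^-1 productivity unit.
#'
#' @param samples A data frame with columns `mannitol_mg_per_l` (>= 0) and
#'   `od730` (> 0); an optional `compartment` column
#'   (`"extracellular"`/`"total"`) and any id columns are carried through.
#' @return The input as a tibble with an added `normalized_mg_per_l_od`
#'   column.
#' @examples
#' normalize_productivity(tibble::tibble(mannitol_mg_per_l = 55.42, od730 = 2))
#' @export
normalize_productivity <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("mannitol_mg_per_l", "od730") %in% names(samples))) {
    stop("`samples` needs columns mannitol_mg_per_l and od730", call. = FALSE)
  }
  conc <- as.numeric(samples$mannitol_mg_per_l)
  od <- as.numeric(samples$od730)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("mannitol_mg_per_l must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(od)) || any(od <= 0)) {
    stop("od730 must be finite and > 0 (division by zero otherwise)", call. = FALSE)
  }
  out <- tibble::as_tibble(samples)
  out$normalized_mg_per_l_od <- conc / od
  out
}

#' Fold change between two normalized productivities
#'
#' @param a,b Normalized productivities (mg L^-1 OD730^-1); `b` is the
#'   reference and must be > 0.
#' @return `a / b` (dimensionless).
#' @export
fold_change <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) stop("inputs must be numeric", call. = FALSE)
  if (any(b <= 0)) stop("reference productivity must be > 0", call. = FALSE)
  a / b
}
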