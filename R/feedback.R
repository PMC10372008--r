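#' Feedback parameters
#'
#' Parameters of the microbe-to-host feedback channel. In the reward-circuit
#' variant each affecting strain senses the trend of its own proportion over
#' the last `omega_m` steps and secretes a positive or negative signal; the
#' host integrates these against its own behavioral trend over the last
#' `omega_h` steps. In the direct-pull variant each strain instead pulls the
#' host towards its own feature coordinates.
#'
#' @param omega_m rolling-window length for strain-proportion trends (>= 2).
#' @param omega_h rolling-window length for the host-behavior trend (>= 2).
#' @param slope_tol neutrality threshold: regression slopes in
#'   `(-slope_tol, slope_tol)` count as flat (default `1e-6`, representing
#'   limited sensing accuracy).
#' @param variant `"reward_circuit"` or `"direct_pull"`.
#' @return An object of class `mb_feedback_params`.
#' @export
feedback_params <- function(omega_m = 10, omega_h = 10, slope_tol = 1e-6,
                            variant = c("reward_circuit", "direct_pull")) {
  variant <- match.arg(variant)
  if (omega_m < 2 || omega_h < 2) stop("window lengths must be >= 2")
  if (slope_tol <= 0) stop("slope_tol must be > 0")
  structure(list(omega_m = as.integer(omega_m),
                 omega_h = as.integer(omega_h),
                 slope_tol = slope_tol, variant = variant),
            class = "mb_feedback_params")
}

#' Ordinary least-squares slope of an equally spaced series
#'
#' Returns the OLS regression slope of the values against their (unit
#' spaced) time indices.
#'
#' @param series numeric vector of length >= 2, in chronological order.
#' @return The slope, a single number.
#' @export
window_slope <- function(series) {
  w <- length(series)
  if (w < 2) stop("window must contain at least 2 points")
  k <- seq_len(w) - 1
  kc <- k - mean(k)
  sum(kc * (series - mean(series))) / sum(kc * kc)
}

#' Three-level trend indicator
#'
#' Maps a regression slope to +1 (rising), -1 (falling) or 0 (neutral,
#' within the tolerance band); the comparisons are strict, so a slope of
#' exactly `+/- tol` is neutral.
#'
#' @param slope finite numeric slope.
#' @param tol positive neutrality threshold.
#' @return Integer in `{-1, 0, 1}` (vectorized over `slope`).
#' @export
trend_indicator <- function(slope, tol = 1e-6) {
  if (tol <= 0) stop("tol must be > 0")
  ifelse(slope > tol, 1L, ifelse(slope < -tol, -1L, 0L))
}

#' Trend indicators for all strains and the host
#'
#' Applies [window_slope()] plus [trend_indicator()] to each strain's
#' proportion history and to the host-behavior history. Histories shorter
#' than the corresponding window yield indicator 0 (warm-up convention);
#' otherwise the most recent `omega` points are used.
#'
#' @param micro_history numeric matrix of proportion vectors, one row per
#'   time step (or `NULL` for no history).
#' @param behavior_history numeric vector of past `b1` values.
#' @param params an [feedback_params()] object.
#' @return List with integer vector `I_m` (one entry per strain) and scalar
#'   integer `I_b`.
#' @export
compute_all_indicators <- function(micro_history, behavior_history,
                                   params = feedback_params()) {
  n <- if (is.null(micro_history)) 0L else ncol(micro_history)
  I_m <- integer(n)
  if (!is.null(micro_history) && nrow(micro_history) >= params$omega_m) {
    tail_rows <- micro_history[nrow(micro_history) - params$omega_m +
                                 seq_len(params$omega_m), , drop = FALSE]
    slopes <- apply(tail_rows, 2, window_slope)
    I_m <- trend_indicator(slopes, params$slope_tol)
  }
  I_b <- 0L
  if (length(behavior_history) >= params$omega_h) {
    bh <- utils::tail(behavior_history, params$omega_h)
    I_b <- trend_indicator(window_slope(bh), params$slope_tol)
  }
  list(I_m = as.integer(I_m), I_b = as.integer(I_b))
}

#' Reward-circuit microbiome effect on host behavior
#'
#' Aggregates the strains' trend feedback into a single behavioral nudge:
#' `M = |sigma_step| * I_b * sum_i x_i * d_i * I_m_i`. The product
#' `I_m_i * I_b` is positive when a strain reinforces the host's current
#' trend (reward while advancing, aversion while retreating) and negative
#' when it opposes it.
#'
#' @param x proportion (relative-abundance) vector.
#' @param strains an [strain_set()] object supplying the `d_i`.
#' @param I_m integer vector of strain trend indicators.
#' @param I_b integer host trend indicator.
#' @param sigma_step host baseline step magnitude at this time step.
#' @return The scalar effect `M`.
#' @export
microbiome_effect <- function(x, strains, I_m, I_b, sigma_step) {
  abs(sigma_step) * I_b * sum(x * strains$effect_magnitude * I_m)
}

#' Direct-pull microbiome effect on host behavior
#'
#' Each strain pulls the host towards its own coordinates: unit vectors
#' `(m_i - b) / ||m_i - b||` are averaged with weights `x_i * d_i`, the
#' result is projected on the first (active) behavior axis and scaled by
#' the baseline step size. Strains closer than `1e-12` to the host
#' contribute nothing (degenerate direction).
#'
#' @param b host behavior coordinate vector.
#' @param strains an [strain_set()] object.
#' @param x proportion vector.
#' @param sigma_step baseline step size at this time step.
#' @return The scalar effect `M`.
#' @export
direct_pull_effect <- function(b, strains, x, sigma_step) {
  diffs <- t(strains$features) - as.numeric(b)
  nrm <- sqrt(colSums(diffs^2))
  keep <- nrm >= 1e-12
  if (!any(keep)) return(0)
  sigma_step * sum(x[keep] * strains$effect_magnitude[keep] *
                     diffs[1, keep] / nrm[keep])
}

#' Host behavior update
#'
#' Advances the active behavior coordinate by the baseline step plus the
#' microbiome effect, clamped to `[lower, upper]`.
#'
#' @param b1 current behavior coordinate.
#' @param base_step signed baseline step.
#' @param M microbiome effect (see [microbiome_effect()]).
#' @param lower,upper clamp bounds (`lower <= upper`).
#' @return The new behavior coordinate.
#' @export
behavior_update <- function(b1, base_step, M, lower = 0, upper = 1) {
  if (lower > upper) stop("lower bound exceeds upper bound")
  min(max(b1 + base_step + M, lower), upper)
}
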