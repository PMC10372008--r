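#' Dynamics parameters
#'
#' Parameters of the one-step composition update. The normalized variant
#' tracks relative abundances under a shared carrying capacity: an Euler
#' step of logistic competition, renormalization, a small inflow of every
#' strain, and a second normalization. The generalized Lotka-Volterra (glv)
#' variant tracks raw abundances with an interaction matrix and no
#' normalization.
#'
#' @param s non-negative intra-strain competition coefficient (shared by all
#'   strains; 1 in the community scenarios, 0.1 or 0.01 in the two-strain
#'   competition runs).
#' @param mu total inflow rate; under `inflow_mode = "per_strain_scaled"`
#'   each strain receives `mu / N` per step, keeping every strain's
#'   proportion positive so no extinction is permanent.
#' @param delta magnitude of the (negative) off-diagonal interaction in the
#'   glv variant.
#' @param inflow_mode `"per_strain_scaled"` (`mu / N` each),
#'   `"per_strain_constant"` (`mu` each, regardless of N) or `"none"`.
#' @param variant `"normalized"` or `"glv"`.
#' @param glv_ceiling abundance ceiling above which the glv step aborts with
#'   an instability error naming the step.
#' @return An object of class `mb_dynamics_params`.
#' @export
dynamics_params <- function(s = 1, mu = 1e-8, delta = 0.5,
                            inflow_mode = c("per_strain_scaled",
                                            "per_strain_constant", "none"),
                            variant = c("normalized", "glv"),
                            glv_ceiling = 1e6) {
  inflow_mode <- match.arg(inflow_mode)
  variant <- match.arg(variant)
  if (s < 0) stop("s must be >= 0")
  if (mu < 0) stop("mu must be >= 0")
  if (delta < 0) stop("delta must be >= 0")
  structure(list(s = s, mu = mu, delta = delta, inflow_mode = inflow_mode,
                 variant = variant, glv_ceiling = glv_ceiling),
            class = "mb_dynamics_params")
}

#' Microbiome state container
#'
#' Holds the current composition vector, an integer time counter and a
#' history matrix (one row per past step) used by the rolling-window trend
#' computations.
#'
#' @param proportions non-negative numeric vector; relative abundances in
#'   the normalized variant (summing to 1), raw abundances in the glv
#'   variant.
#' @param time integer step counter.
#' @param history optional numeric matrix of past composition vectors.
#' @return An object of class `mb_state`.
#' @export
microbiome_state <- function(proportions, time = 0L, history = NULL) {
  proportions <- as.numeric(proportions)
  if (any(proportions < 0)) stop("abundances must be >= 0")
  if (is.null(history)) history <- matrix(proportions, nrow = 1)
  structure(list(proportions = proportions, time = as.integer(time),
                 history = history),
            class = "mb_state")
}

inflow_per_strain <- function(params, n) {
  switch(params$inflow_mode,
         per_strain_scaled = params$mu / n,
         per_strain_constant = params$mu,
         none = 0)
}

#' One step of the normalized competition dynamics
#'
#' Applies the Euler update `x_i <- x_i + x_i * (r_i - s * x_i - c_i)`,
#' clips negative intermediates at 0, normalizes by the sum, adds the
#' per-strain inflow and normalizes again. Proportions therefore sum to 1
#' after every step, and with a positive scaled inflow every strain retains
#' a proportion of at least `mu / (N * (1 + mu))`.
#'
#' @param state an [microbiome_state()] object satisfying its invariants.
#' @param r numeric vector of growth rates (see [growth_rate()]).
#' @param strains an [strain_set()] object (supplies the costs `c_i`).
#' @param params an [dynamics_params()] object.
#' @return The updated `mb_state`, with the new composition appended to the
#'   history and time advanced by one.
#' @export
step_normalized <- function(state, r, strains, params = dynamics_params()) {
  x <- state$proportions
  n <- length(x)
  if (length(r) != n) stop("growth-rate vector length does not match state")
  g <- x + x * (r - params$s * x - strains$cost)
  g[g < 0] <- 0
  sm <- sum(g)
  if (sm <= 0 && params$inflow_mode == "none")
    stop("degenerate community: all strains extinct with no inflow")
  if (sm > 0) g <- g / sm
  g <- g + inflow_per_strain(params, n)
  g <- g / sum(g)
  microbiome_state(g, state$time + 1L, rbind(state$history, g))
}

#' One step of the generalized Lotka-Volterra dynamics
#'
#' Forward-Euler step of size 1:
#' `x_i <- x_i + x_i * (r_i - c_i + A_i . x) + inflow`, clipped at 0, with
#' no normalization. Aborts with an instability error if any abundance
#' exceeds `params$glv_ceiling`.
#'
#' @inheritParams step_normalized
#' @param A interaction matrix (see [build_interaction_matrix()]).
#' @param strains optional [strain_set()] supplying costs; `NULL` means zero
#'   cost.
#' @return The updated `mb_state`.
#' @export
step_glv <- function(state, r, A, params = dynamics_params(variant = "glv"),
                     strains = NULL) {
  x <- state$proportions
  n <- length(x)
  if (length(r) != n) stop("growth-rate vector length does not match state")
  if (!all(dim(A) == c(n, n))) stop("interaction matrix dimension mismatch")
  cost <- if (is.null(strains)) 0 else strains$cost
  g <- x + x * (r - cost + as.numeric(A %*% x)) + inflow_per_strain(params, n)
  g[g < 0] <- 0
  if (any(g > params$glv_ceiling))
    stop(sprintf("unstable trajectory: abundance exceeded ceiling at step %d",
                 state$time + 1L))
  microbiome_state(g, state$time + 1L, rbind(state$history, g))
}

#' Uniform competition interaction matrix
#'
#' Builds the `N x N` matrix with diagonal -1 (intra-strain competition)
#' and all off-diagonal entries `-delta` (every strain suppresses every
#' other strain equally); algebraically `-(1 - delta) I - delta J`.
#'
#' @param n number of strains.
#' @param delta non-negative off-diagonal magnitude.
#' @return Numeric matrix.
#' @export
build_interaction_matrix <- function(n, delta) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (delta < 0) stop("delta must be >= 0")
  A <- matrix(-delta, n, n)
  diag(A) <- -1
  A
}
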