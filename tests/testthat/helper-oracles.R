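# Independent oracles used across the suite.

# two-pass closed-form OLS slope (independent of window_slope)
ols_slope_oracle <- function(y) {
  j <- seq_along(y) - 1
  jbar <- mean(j)
  ybar <- mean(y)
  sum((j - jbar) * (y - ybar)) / sum((j - jbar)^2)
}

# quadratic brute-force maximal rise over ordered pairs, floored at 0
brute_relapse <- function(v) {
  best <- 0
  n <- length(v)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (v[j] - v[i] > best) best <- v[j] - v[i]
  best
}

# Pure-R reference of the coupled loop, composed from the exported module
# functions; used as the independent route against the fused C++ core.
ref_sim <- function(strains, steps, sigma_mag = abs(steps), b_start = 0.5,
                    clamp = c(0, 1), gp = growth_params(),
                    dp = dynamics_params(), fp = feedback_params()) {
  n <- nrow(strains$features)
  dims <- ncol(strains$features)
  glv <- dp$variant == "glv"
  x0 <- rep(1 / n, n)
  state <- microbiome_state(x0)
  b1 <- b_start
  relfun <- function(x) if (glv && sum(x) > 0) x / sum(x) else x
  mhist <- matrix(relfun(x0), nrow = 1)
  bhist <- b1
  b_out <- numeric(length(steps))
  for (t in seq_along(steps)) {
    ind <- compute_all_indicators(mhist, bhist, fp)
    xrel <- relfun(state$proportions)
    M <- if (fp$variant == "reward_circuit")
      microbiome_effect(xrel, strains, ind$I_m, ind$I_b, sigma_mag[t])
    else
      direct_pull_effect(c(b1, rep(0, dims - 1)), strains, xrel,
                         sigma_mag[t])
    b_new <- behavior_update(b1, steps[t], M, clamp[1], clamp[2])
    r <- growth_rate(c(b1, rep(0, dims - 1)), strains, gp)
    state <- if (glv)
      step_glv(state, r, build_interaction_matrix(n, dp$delta), dp, strains)
    else
      step_normalized(state, r, strains, dp)
    b1 <- b_new
    mhist <- rbind(mhist, relfun(state$proportions))
    bhist <- c(bhist, b1)
    b_out[t] <- b1
  }
  list(b1 = b_out, proportions = state$proportions)
}

laplace_steps <- function(n, scale, seed) {
  set.seed(seed)
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

run_core <- function(strains, steps, sigma_mag = abs(steps), b_start = 0.5,
                     clamp = c(0, 1), gp = growth_params(),
                     dp = dynamics_params(), fp = feedback_params(),
                     n_initial = nrow(strains$features),
                     intervention_at = -1L, equilibrate = FALSE,
                     stab = c(1e-10, 100, 100)) {
  inflow_code <- c(per_strain_scaled = 0L, per_strain_constant = 1L,
                   none = 2L)[[dp$inflow_mode]]
  microbehave:::sim_core_cpp(
      strains$features, strains$effect_magnitude, strains$cost,
      strains$behavior_independent, gp$r_independent,
      gp$alpha, gp$beta, gp$floor,
      dp$s, dp$mu, inflow_code,
      if (dp$variant == "glv") 1L else 0L, dp$delta, dp$glv_ceiling,
      if (fp$variant == "direct_pull") 1L else 0L,
      fp$omega_m, fp$omega_h, fp$slope_tol,
      as.integer(n_initial), as.integer(intervention_at),
      steps, sigma_mag, clamp[1], clamp[2], -1L, -1, b_start,
      equilibrate, stab[1], as.integer(stab[2]), as.integer(stab[3]),
      10L, FALSE)
}
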