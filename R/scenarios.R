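#' Simulation configuration
#'
#' Collects every tunable parameter of the host-microbiome simulations with
#' the standard defaults: 50 strains in 2 dimensions, behavioral step scale
#' `sigma = 1e-4`, addiction-phase length `tau = 20000`, maximal addiction
#' severity `R = 0.7`, mean effect magnitude `E[d] = 10`, intra-strain
#' competition `s = 1`, inflow `mu = 1e-8`, growth parameters `alpha = 3`,
#' `beta = 0.1`, feedback windows `omega_m = omega_h = 10`.
#'
#' @param n_strains number of strains `N`.
#' @param dims feature-space dimensionality `D`.
#' @param sigma behavioral step scale: Laplace scale in the two-strain
#'   random walk, exponential mean in the addiction schedule.
#' @param tau addiction-phase length in steps (counted from its initiation).
#' @param R maximal addiction severity, `0 < R <= 1`.
#' @param mean_effect mean effect magnitude `E[d]` (also the deterministic
#'   effect magnitude of the affecting strain in the two-strain scenario).
#' @param affecting_fraction fraction of strains that affect host behavior.
#' @param s intra-strain competition coefficient.
#' @param mu total inflow rate.
#' @param cost per-step cost paid by each affecting strain.
#' @param alpha,beta,rate_floor growth-function parameters
#'   (see [growth_params()]).
#' @param r_independent constant rate for behavior-independent strains.
#' @param behavior_independent_fraction fraction of strains with constant
#'   growth (robustness variant).
#' @param omega_m,omega_h,slope_tol feedback-window parameters
#'   (see [feedback_params()]).
#' @param dynamics_variant `"normalized"` or `"glv"`.
#' @param feedback_variant `"reward_circuit"` or `"direct_pull"`.
#' @param inflow_mode inflow handling (see [dynamics_params()]).
#' @param delta glv off-diagonal interaction magnitude.
#' @param glv_ceiling abundance ceiling for the glv instability guard.
#' @param withdrawal_horizon number of withdrawal steps simulated (the
#'   fixed window over which `phi(Withdrawal)` is integrated).
#' @param total_steps_two_strain length of the two-strain random walk.
#' @param intervention_new_strains number of freshly sampled strains `k`
#'   introduced at withdrawal start (0 for none).
#' @param allow_exceed_R if `TRUE`, withdrawal-phase relapses may exceed
#'   `R` (behavior clamped to `[0, 1]` instead of `[0, R]`).
#' @param stab_tol,stab_window,stab_cap equilibrium-phase stabilization
#'   criterion: the phase ends once the largest per-strain change stays
#'   below `stab_tol` for `stab_window` consecutive steps, or after
#'   `stab_cap` steps (with a warning recorded in the run).
#' @param return_epsilon threshold under which the final behavior counts as
#'   returned to the initial state.
#' @param thin stride for recording proportion vectors in trajectories.
#' @param seed default RNG seed for runs using this configuration.
#' @return An object of class `mb_config` (a validated named list).
#' @export
sim_config <- function(n_strains = 50, dims = 2, sigma = 1e-4, tau = 20000,
                       R = 0.7, mean_effect = 10, affecting_fraction = 1,
                       s = 1, mu = 1e-8, cost = 0,
                       alpha = 3, beta = 0.1, rate_floor = 0.1,
                       r_independent = 0.6,
                       behavior_independent_fraction = 0,
                       omega_m = 10, omega_h = 10, slope_tol = 1e-6,
                       dynamics_variant = "normalized",
                       feedback_variant = "reward_circuit",
                       inflow_mode = "per_strain_scaled",
                       delta = 0.5, glv_ceiling = 1e6,
                       withdrawal_horizon = 100000,
                       total_steps_two_strain = 100000,
                       intervention_new_strains = 0,
                       allow_exceed_R = FALSE,
                       stab_tol = 1e-10, stab_window = 100, stab_cap = 10000,
                       return_epsilon = 0.01, thin = 10, seed = 1) {
  config <- list(n_strains = as.integer(n_strains), dims = as.integer(dims),
                 sigma = sigma, tau = as.integer(tau), R = R,
                 mean_effect = mean_effect,
                 affecting_fraction = affecting_fraction,
                 s = s, mu = mu, cost = cost,
                 alpha = alpha, beta = beta, rate_floor = rate_floor,
                 r_independent = r_independent,
                 behavior_independent_fraction = behavior_independent_fraction,
                 omega_m = as.integer(omega_m), omega_h = as.integer(omega_h),
                 slope_tol = slope_tol,
                 dynamics_variant = dynamics_variant,
                 feedback_variant = feedback_variant,
                 inflow_mode = inflow_mode,
                 delta = delta, glv_ceiling = glv_ceiling,
                 withdrawal_horizon = as.integer(withdrawal_horizon),
                 total_steps_two_strain = as.integer(total_steps_two_strain),
                 intervention_new_strains = as.integer(intervention_new_strains),
                 allow_exceed_R = isTRUE(allow_exceed_R),
                 stab_tol = stab_tol, stab_window = as.integer(stab_window),
                 stab_cap = as.integer(stab_cap),
                 return_epsilon = return_epsilon, thin = as.integer(thin),
                 seed = as.integer(seed))
  class(config) <- "mb_config"
  validate_sim_config(config)
  config
}

#' Validate a simulation configuration
#'
#' Checks every constraint a configuration must satisfy and fails with an
#' error naming the offending field.
#'
#' @param config an `mb_config` object (or plain named list).
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, field, constraint) {
    if (!isTRUE(ok))
      stop(sprintf("invalid configuration: '%s' must satisfy %s",
                   field, constraint), call. = FALSE)
  }
  chk(config$n_strains >= 1, "n_strains", ">= 1")
  chk(config$dims >= 1, "dims", ">= 1")
  chk(config$sigma > 0, "sigma", "> 0")
  chk(config$tau >= 0, "tau", ">= 0")
  chk(config$R > 0 && config$R <= 1, "R", "0 < R <= 1")
  chk(config$mean_effect >= 0, "mean_effect", ">= 0")
  chk(config$affecting_fraction >= 0 && config$affecting_fraction <= 1,
      "affecting_fraction", "in [0, 1]")
  chk(config$s >= 0, "s", ">= 0")
  chk(config$mu >= 0, "mu", ">= 0")
  chk(config$cost >= 0, "cost", ">= 0")
  chk(config$alpha > 0, "alpha", "> 0")
  chk(config$beta >= 0, "beta", ">= 0")
  chk(config$omega_m >= 2, "omega_m", ">= 2")
  chk(config$omega_h >= 2, "omega_h", ">= 2")
  chk(config$slope_tol > 0, "slope_tol", "> 0")
  chk(config$dynamics_variant %in% c("normalized", "glv"),
      "dynamics_variant", "'normalized' or 'glv'")
  chk(config$feedback_variant %in% c("reward_circuit", "direct_pull"),
      "feedback_variant", "'reward_circuit' or 'direct_pull'")
  chk(config$inflow_mode %in% c("per_strain_scaled", "per_strain_constant",
                                "none"),
      "inflow_mode", "a supported inflow mode")
  chk(config$delta >= 0, "delta", ">= 0")
  chk(config$withdrawal_horizon >= 1, "withdrawal_horizon", ">= 1")
  chk(config$total_steps_two_strain >= 1, "total_steps_two_strain", ">= 1")
  chk(config$intervention_new_strains >= 0, "intervention_new_strains",
      ">= 0")
  chk(config$stab_tol > 0, "stab_tol", "> 0")
  chk(config$stab_window >= 1, "stab_window", ">= 1")
  chk(config$stab_cap >= 1, "stab_cap", ">= 1")
  chk(config$thin >= 1, "thin", ">= 1")
  invisible(config)
}

# Deterministic 31-bit seed mixer: derives independent sub-stream seeds
# (strain sampling vs behavior draws, per-replicate, per-sweep-cell) from a
# base seed so that e.g. changing N never perturbs the behavior-step
# sequence of a paired run.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (v in parts) h <- (h * 69069 + (v %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

mb_variant_code <- function(config) {
  c(normalized = 0L, glv = 1L)[[config$dynamics_variant]]
}
mb_feedback_code <- function(config) {
  c(reward_circuit = 0L, direct_pull = 1L)[[config$feedback_variant]]
}
mb_inflow_code <- function(config) {
  c(per_strain_scaled = 0L, per_strain_constant = 1L,
    none = 2L)[[config$inflow_mode]]
}

# Laplace(0, scale) draws via inverse CDF
rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Baseline behavior schedule
#'
#' The microbiome-free addiction schedule: starting at 0, the behavior
#' accumulates the positive draws during the addiction phase (clamped at
#' `R`) and the negated draws during withdrawal (clamped at 0). Computed
#' with the same sequential clamping as the full simulation, so a run with
#' all effect magnitudes zero reproduces it bit for bit.
#'
#' @param sigma_steps positive step magnitudes, one per step (addiction
#'   draws first, then withdrawal draws).
#' @param tau number of addiction steps at the head of `sigma_steps`.
#' @param R maximal addiction severity.
#' @return Numeric vector of `b1` values, one per step.
#' @export
baseline_schedule <- function(sigma_steps, tau, R) {
  n <- length(sigma_steps)
  out <- numeric(n)
  b <- 0
  for (t in seq_len(n)) {
    step <- if (t <= tau) sigma_steps[t] else -sigma_steps[t]
    b <- b + step
    if (b < 0) b <- 0
    if (b > R) b <- R
    out[t] <- b
  }
  out
}

new_trajectory <- function(b1, tau, horizon, equil_steps, stabilized,
                           base_steps, sigma_steps, res, config, seed,
                           strains, warnings = character()) {
  structure(list(b1 = b1, tau = tau, horizon = horizon,
                 addiction_start = 1L, withdrawal_start = tau + 1L,
                 end = tau + horizon,
                 equil_steps = equil_steps, stabilized = stabilized,
                 base_steps = base_steps, sigma_steps = sigma_steps,
                 proportions = res$proportions, prop_steps = res$prop_steps,
                 final_proportions = res$final,
                 max_sum_dev = res$max_sum_dev, min_prop = res$min_prop,
                 config = config, seed = seed, strains = strains,
                 warnings = warnings),
            class = "mb_trajectory")
}

#' @export
print.mb_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<mb_trajectory> equilibrium %d steps (%s), addiction %d",
                     " steps, withdrawal %d steps; final b1 = %.4g\n"),
              x$equil_steps, if (x$stabilized) "stabilized" else "cap reached",
              x$tau, x$horizon, x$b1[length(x$b1)]))
  invisible(x)
}

#' Run one three-phase addiction simulation
#'
#' Phase 1 holds the host at the origin until the microbiome composition
#' stabilizes (see `stab_*` in [sim_config()]). Phase 2 (addiction) applies
#' positive baseline steps drawn from an exponential distribution with mean
#' `sigma` for `tau` steps, with the behavior clamped to `[0, R]`. Phase 3
#' (withdrawal) negates the baseline steps for `withdrawal_horizon` steps,
#' clamped to `[0, R]` (or `[0, 1]` when `allow_exceed_R`). The microbiome
#' feedback `M(t)` is active throughout phases 2 and 3, including the
#' addiction plateau. If `intervention_new_strains > 0`, that many freshly
#' sampled strains enter the community (at abundance 0, joining the inflow
#' pool) at withdrawal start.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; sub-streams for strain sampling and behavior
#'   draws are derived from it.
#' @param strains optional pre-built [strain_set()] (must contain
#'   `n_strains + intervention_new_strains` strains); if `NULL`, strains are
#'   sampled from the seed's strain sub-stream.
#' @param record_proportions if `TRUE`, record the composition every
#'   `config$thin` steps.
#' @return List with elements `trajectory` (class `mb_trajectory`) and
#'   `metrics` (a one-row data frame: `phi_addiction`, `phi_withdrawal`,
#'   `max_relapse`, `reached_R`, `returned`, `final_b1`, `equil_steps`,
#'   `stabilized`).
#' @export
run_addiction <- function(config = sim_config(), seed = config$seed,
                          strains = NULL, record_proportions = FALSE) {
  validate_sim_config(config)
  k <- config$intervention_new_strains
  n_total <- config$n_strains + k
  if (is.null(strains)) {
    set.seed(derive_seed(seed, 101))
    strains <- sample_strains(n_total, config$dims, config$mean_effect,
                              config$affecting_fraction, config$cost,
                              config$behavior_independent_fraction)
  } else if (nrow(strains$features) != n_total) {
    stop("provided strain set must contain n_strains + intervention strains")
  }
  set.seed(derive_seed(seed, 202))
  n_steps <- config$tau + config$withdrawal_horizon
  sig <- stats::rexp(n_steps, rate = 1 / config$sigma)
  base_steps <- c(sig[seq_len(config$tau)],
                  -sig[config$tau + seq_len(config$withdrawal_horizon)])

  res <- sim_core_cpp(strains$features, strains$effect_magnitude,
                      strains$cost, strains$behavior_independent,
                      config$r_independent,
                      config$alpha, config$beta, config$rate_floor,
                      config$s, config$mu, mb_inflow_code(config),
                      mb_variant_code(config), config$delta,
                      config$glv_ceiling, mb_feedback_code(config),
                      config$omega_m, config$omega_h, config$slope_tol,
                      config$n_strains,
                      if (k > 0) config$tau else -1L,
                      base_steps, sig,
                      0, config$R,
                      if (config$allow_exceed_R) config$tau else -1L,
                      if (config$allow_exceed_R) 1 else -1,
                      0,
                      TRUE, config$stab_tol, config$stab_window,
                      config$stab_cap,
                      config$thin, record_proportions)

  warnings <- character()
  if (!res$stabilized)
    warnings <- sprintf("equilibrium phase hit the %d-step cap before stabilizing",
                        config$stab_cap)
  traj <- new_trajectory(res$b1, config$tau, config$withdrawal_horizon,
                         res$equil_steps, res$stabilized, base_steps, sig,
                         res, config, seed, strains, warnings)
  list(trajectory = traj, metrics = trajectory_metrics(traj))
}

trajectory_metrics <- function(traj) {
  config <- traj$config
  data.frame(phi_addiction = phi(traj, "addiction"),
             phi_withdrawal = phi(traj, "withdrawal"),
             max_relapse = max_relapse(traj),
             reached_R = max(traj$b1[seq_len(traj$tau)]) >= config$R - 1e-12,
             returned = traj$b1[traj$end] < config$return_epsilon,
             final_b1 = traj$b1[traj$end],
             equil_steps = traj$equil_steps,
             stabilized = traj$stabilized)
}

#' Run the two-strain evolution-of-feedback simulation
#'
#' Two strains sit at coordinates `(0, 0, ...)` and `(1, 0, ...)` on the
#' behavior axis; the first affects host behavior with effect magnitude
#' `config$mean_effect` and pays `config$cost` per step, the second does
#' neither. The host performs a random walk on `[0, 1]` starting at 0.5
#' with Laplace(0, `sigma`) steps; the strain's feedback (proportional to
#' its abundance and the realized step magnitude) is added to each step.
#'
#' @inheritParams run_addiction
#' @return List with elements `trajectory` (list with `b1`, `x_affecting`
#'   thinned series, `prop_steps`, `base_steps`, config echo) and
#'   `final_affecting`, the affecting strain's proportion at the last step.
#' @export
run_two_strain <- function(config = sim_config(sigma = 1e-3, s = 0.1),
                           seed = config$seed, record_proportions = TRUE) {
  validate_sim_config(config)
  features <- matrix(0, nrow = 2, ncol = config$dims)
  features[2, 1] <- 1
  strains <- strain_set(features,
                        effect_magnitude = c(config$mean_effect, 0),
                        cost = c(config$cost, 0),
                        affecting = c(TRUE, FALSE))
  set.seed(derive_seed(seed, 202))
  steps <- rlaplace(config$total_steps_two_strain, config$sigma)

  res <- sim_core_cpp(strains$features, strains$effect_magnitude,
                      strains$cost, strains$behavior_independent,
                      config$r_independent,
                      config$alpha, config$beta, config$rate_floor,
                      config$s, config$mu, mb_inflow_code(config),
                      mb_variant_code(config), config$delta,
                      config$glv_ceiling, mb_feedback_code(config),
                      config$omega_m, config$omega_h, config$slope_tol,
                      2L, -1L,
                      steps, abs(steps),
                      0, 1, -1L, -1,
                      0.5,
                      FALSE, config$stab_tol, config$stab_window,
                      config$stab_cap,
                      config$thin, record_proportions)

  trajectory <- list(b1 = res$b1,
                     x_affecting = if (length(res$prop_steps))
                       res$proportions[, 1] else numeric(),
                     prop_steps = res$prop_steps,
                     base_steps = steps,
                     final_proportions = res$final,
                     config = config, seed = seed)
  list(trajectory = trajectory, final_affecting = res$final[1])
}

#' Has the composition stabilized?
#'
#' The equilibrium phase of the addiction scenario ends when the largest
#' per-strain step-to-step change stays below `tol` for `window`
#' consecutive steps; this helper applies that criterion to a recorded
#' history.
#'
#' @param history numeric matrix of composition vectors, one row per step
#'   (chronological).
#' @param tol positive tolerance on the per-strain change.
#' @param window number of consecutive sub-tolerance steps required.
#' @return `TRUE` or `FALSE`.
#' @export
detect_stabilization <- function(history, tol = 1e-10, window = 100) {
  history <- as.matrix(history)
  if (nrow(history) < window + 1) return(FALSE)
  d <- abs(diff(history))
  md <- apply(d, 1, max)
  all(utils::tail(md, window) < tol)
}

#' Behavior integral of a trajectory phase
#'
#' Unit-step Riemann sum of the behavior coordinate over the addiction
#' window (`tau` steps from addiction initiation) or the withdrawal window
#' (`withdrawal_horizon` steps from withdrawal initiation). Larger
#' `phi(Withdrawal)` means a slower, more aggravated withdrawal.
#'
#' @param trajectory an `mb_trajectory` from [run_addiction()].
#' @param phase `"addiction"` or `"withdrawal"`.
#' @return Non-negative number.
#' @export
phi <- function(trajectory, phase = c("addiction", "withdrawal")) {
  phase <- match.arg(phase)
  if (is.null(trajectory$tau) || is.null(trajectory$horizon))
    stop("trajectory is missing phase boundaries")
  if (phase == "addiction") sum(trajectory$b1[seq_len(trajectory$tau)])
  else sum(trajectory$b1[trajectory$tau + seq_len(trajectory$horizon)])
}

# linear-time maximal rise of a series: max over t1 < t2 of v[t2] - v[t1],
# floored at 0
relapse_magnitude <- function(series) {
  if (length(series) < 2) return(0)
  max(0, max(series - cummin(series)))
}

#' Maximal relapse magnitude
#'
#' A relapse is any increase of the behavior coordinate after withdrawal
#' initiation; its magnitude is the largest rise `b1(t2) - b1(t1)` over
#' ordered pairs of withdrawal time points (0 if the withdrawal is
#' monotone non-increasing). Computed in linear time via a running prefix
#' minimum.
#'
#' @param trajectory an `mb_trajectory` from [run_addiction()].
#' @return Non-negative number, at most `R` (when relapses are clamped).
#' @export
max_relapse <- function(trajectory) {
  if (is.null(trajectory$tau)) stop("trajectory is missing phase boundaries")
  relapse_magnitude(trajectory$b1[trajectory$tau +
                                    seq_len(trajectory$horizon)])
}

baseline_metrics_from_schedule <- function(config, seed) {
  set.seed(derive_seed(seed, 202))
  n_steps <- config$tau + config$withdrawal_horizon
  sig <- stats::rexp(n_steps, rate = 1 / config$sigma)
  b1 <- baseline_schedule(sig, config$tau, config$R)
  traj <- list(b1 = b1, tau = config$tau, horizon = config$withdrawal_horizon,
               end = n_steps)
  data.frame(phi_addiction = sum(b1[seq_len(config$tau)]),
             phi_withdrawal = sum(b1[config$tau +
                                       seq_len(config$withdrawal_horizon)]),
             max_relapse = relapse_magnitude(
                 b1[config$tau + seq_len(config$withdrawal_horizon)]),
             reached_R = max(b1[seq_len(config$tau)]) >= config$R - 1e-12,
             returned = b1[n_steps] < config$return_epsilon,
             final_b1 = b1[n_steps],
             equil_steps = NA_integer_, stabilized = NA)
}

#' Run a seeded ensemble with a matched no-effect baseline
#'
#' Runs `n_reps` replicates of the addiction scenario under the microbiome
#' effect and `n_reps` matched baseline replicates without it (same
#' behavior-step draws per replicate, effect magnitudes all zero), and
#' summarizes the phase integrals, their fold changes, relapse magnitudes
#' and the fractions of runs that never reach `R` or never return to the
#' initial state.
#'
#' @param config an [sim_config()] object.
#' @param n_reps number of replicates per arm.
#' @param base_seed base seed; per-replicate seeds are derived from it.
#' @param baseline `"simulate"` runs full dynamics with all effect
#'   magnitudes zero; `"schedule"` evaluates the baseline behavior schedule
#'   directly (identical by the zero-effect equivalence property, and much
#'   cheaper for large communities).
#' @return List with `metrics` (one row per replicate and arm) and
#'   `summary` (one row: mean phi per arm and phase, fold changes
#'   `mean(effect) / mean(baseline)`, mean maximal relapse, fractions not
#'   reaching `R` / not returned, replicate count).
#' @export
run_ensemble <- function(config = sim_config(), n_reps = 50, base_seed = 1,
                         baseline = c("simulate", "schedule")) {
  baseline <- match.arg(baseline)
  if (n_reps < 1) stop("n_reps must be >= 1")
  base_cfg <- config
  base_cfg$mean_effect <- 0
  rows <- vector("list", 2 * n_reps)
  for (rep in seq_len(n_reps)) {
    seed <- derive_seed(base_seed, rep)
    eff <- run_addiction(config, seed = seed)$metrics
    bas <- if (baseline == "simulate")
      run_addiction(base_cfg, seed = seed)$metrics
    else baseline_metrics_from_schedule(base_cfg, seed)
    eff$rep <- rep; eff$arm <- "effect"; eff$seed <- seed
    bas$rep <- rep; bas$arm <- "baseline"; bas$seed <- seed
    rows[[2 * rep - 1]] <- eff
    rows[[2 * rep]] <- bas
  }
  metrics <- do.call(rbind, rows)
  eff <- metrics[metrics$arm == "effect", ]
  bas <- metrics[metrics$arm == "baseline", ]
  if (mean(bas$phi_addiction) <= 0 || mean(bas$phi_withdrawal) <= 0)
    stop("undefined fold change: baseline mean phi is zero")
  summary <- data.frame(
      n_reps = n_reps,
      mean_phi_addiction = mean(eff$phi_addiction),
      mean_phi_withdrawal = mean(eff$phi_withdrawal),
      baseline_phi_addiction = mean(bas$phi_addiction),
      baseline_phi_withdrawal = mean(bas$phi_withdrawal),
      fold_phi_addiction = mean(eff$phi_addiction) / mean(bas$phi_addiction),
      fold_phi_withdrawal = mean(eff$phi_withdrawal) /
          mean(bas$phi_withdrawal),
      mean_max_relapse = mean(eff$max_relapse),
      frac_not_reached = mean(!eff$reached_R),
      frac_not_returned = mean(!eff$returned))
  list(metrics = metrics, summary = summary)
}

#' Parameter sweep over configuration fields
#'
#' Runs [run_ensemble()] on the cross product of the supplied axes, with a
#' deterministic per-cell seed derived from the base seed and the cell
#' index. With `couple_effect = TRUE` the mean effect magnitude is tied to
#' the affecting fraction as `mean_effect = 5 / affecting_fraction`,
#' keeping the expected total microbiome effect constant while varying how
#' it is distributed.
#'
#' @param grid named list of value vectors; names must be [sim_config()]
#'   fields.
#' @param config template configuration for fields not swept.
#' @param reps replicates per cell and arm.
#' @param base_seed base seed for per-cell seed derivation.
#' @param couple_effect tie `mean_effect` to `affecting_fraction` (see
#'   above).
#' @param baseline passed to [run_ensemble()].
#' @return Long-format data frame: one row per cell with the axis values
#'   and the ensemble summary columns.
#' @export
sweep_sim <- function(grid, config = sim_config(), reps = 10, base_seed = 1,
                      couple_effect = FALSE,
                      baseline = c("simulate", "schedule")) {
  baseline <- match.arg(baseline)
  if (!length(grid) || is.null(names(grid)) || any(names(grid) == ""))
    stop("grid must be a named list of configuration axes")
  unknown <- setdiff(names(grid), names(config))
  if (length(unknown))
    stop(sprintf("unknown configuration field(s) in grid: %s",
                 paste(unknown, collapse = ", ")))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- config
    for (field in names(grid)) cfg[[field]] <- cells[ci, field]
    if (couple_effect) {
      if (cfg$affecting_fraction <= 0)
        stop("couple_effect requires a positive affecting_fraction")
      cfg$mean_effect <- 5 / cfg$affecting_fraction
    }
    cfg$n_strains <- as.integer(cfg$n_strains)
    cfg$tau <- as.integer(cfg$tau)
    cfg$withdrawal_horizon <- as.integer(cfg$withdrawal_horizon)
    cfg$intervention_new_strains <- as.integer(cfg$intervention_new_strains)
    validate_sim_config(cfg)
    cell_seed <- derive_seed(base_seed, ci)
    smry <- run_ensemble(cfg, reps, cell_seed, baseline = baseline)$summary
    row <- cbind(cells[ci, , drop = FALSE],
                 data.frame(mean_effect_used = cfg$mean_effect,
                            cell_seed = cell_seed),
                 smry)
    out[[ci]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
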