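small_cfg <- function(...) {
  args <- list(n_strains = 10, tau = 400, withdrawal_horizon = 800,
               stab_cap = 300, sigma = 1e-3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("configuration validation names the offending field", {
  expect_error(sim_config(R = 1.5), "'R'")
  expect_error(sim_config(sigma = 0), "'sigma'")
  expect_error(sim_config(n_strains = 0), "'n_strains'")
  expect_error(sim_config(dynamics_variant = "bogus"), "dynamics_variant")
})

test_that("phase integrals follow the unit-step Riemann sum", {
  traj <- list(b1 = c(0, 0.2, 0.4, 0.4, rep(0.7, 5)), tau = 4L,
               horizon = 5L)
  expect_equal(phi(traj, "addiction"), 1.0)
  expect_equal(phi(traj, "withdrawal"), 3.5)
  zero <- list(b1 = rep(0, 9), tau = 4L, horizon = 5L)
  expect_equal(phi(zero, "addiction"), 0)
  expect_error(phi(list(b1 = 1:3), "addiction"), "boundaries")
})

test_that("maximal relapse matches the brute-force pair scan", {
  traj <- list(b1 = c(0.7, 0.7, 0.6, 0.65, 0.5), tau = 1L, horizon = 4L)
  expect_equal(max_relapse(traj), 0.05)
  mono <- list(b1 = c(0.7, rev(seq(0, 0.6, by = 0.1))), tau = 1L,
               horizon = 7L)
  expect_equal(max_relapse(mono), 0)
  flat <- list(b1 = rep(0.4, 6), tau = 2L, horizon = 4L)
  expect_equal(max_relapse(flat), 0)
  set.seed(21)
  for (i in 1:50) {
    v <- cumsum(rnorm(40, sd = 0.05))
    expect_equal(microbehave:::relapse_magnitude(v), brute_relapse(v),
                 tolerance = 1e-14)
  }
})

test_that("stabilization detection distinguishes flat from oscillating histories", {
  flat <- matrix(rep(c(0.4, 0.6), each = 150), ncol = 2)
  expect_true(detect_stabilization(flat, tol = 1e-10, window = 100))
  single <- matrix(1, nrow = 120, ncol = 1)
  expect_true(detect_stabilization(single, tol = 1e-10, window = 100))
  osc <- matrix(c(0.4, 0.6)[1 + (1:300) %% 2], ncol = 1)
  expect_false(detect_stabilization(osc, tol = 1e-10, window = 100))
  expect_false(detect_stabilization(flat[1:50, ], tol = 1e-10,
                                    window = 100))
})

test_that("zero-effect runs reproduce the baseline schedule exactly", {
  cfg <- small_cfg(mean_effect = 0)
  run <- run_addiction(cfg, seed = 3)
  sched <- baseline_schedule(run$trajectory$sigma_steps, cfg$tau, cfg$R)
  expect_identical(run$trajectory$b1, sched)
})

test_that("addiction runs are deterministic under a fixed seed", {
  cfg <- small_cfg(mean_effect = 10)
  a <- run_addiction(cfg, seed = 5)
  b <- run_addiction(cfg, seed = 5)
  expect_identical(a$trajectory$b1, b$trajectory$b1)
  expect_identical(a$metrics, b$metrics)
  c2 <- run_addiction(cfg, seed = 6)
  expect_false(identical(a$trajectory$b1, c2$trajectory$b1))
})

test_that("behavior stays within [0, R] and metrics respect their bounds", {
  cfg <- small_cfg(mean_effect = 20, R = 0.5)
  run <- run_addiction(cfg, seed = 9)
  expect_true(all(run$trajectory$b1 >= 0 & run$trajectory$b1 <= 0.5))
  m <- run$metrics
  expect_gte(m$phi_addiction, 0)
  expect_gte(m$phi_withdrawal, 0)
  expect_true(m$max_relapse >= 0 && m$max_relapse <= 0.5)
  expect_lte(m$phi_withdrawal, 0.5 * cfg$withdrawal_horizon)
})

test_that("intervention strains are absent before withdrawal and seeded after", {
  cfg <- small_cfg(n_strains = 6, mean_effect = 5,
                   intervention_new_strains = 4, thin = 50)
  run <- run_addiction(cfg, seed = 13, record_proportions = TRUE)
  props <- run$trajectory$proportions
  steps <- run$trajectory$prop_steps
  newcols <- 7:10
  before <- props[steps <= cfg$tau, newcols, drop = FALSE]
  expect_true(all(before == 0))
  expect_true(all(run$trajectory$final_proportions > 0))
  expect_equal(sum(run$trajectory$final_proportions), 1,
               tolerance = 1e-12)
})

test_that("two-strain symmetry: no effect and no cost leaves no winner on average", {
  cfg <- sim_config(sigma = 1e-3, s = 0.1, mean_effect = 0, cost = 0,
                    total_steps_two_strain = 20000)
  fin <- vapply(1:200, function(s)
    run_two_strain(cfg, seed = s, record_proportions = FALSE)$final_affecting,
    numeric(1))
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 0.5), 3 * se + 1e-12)
})

test_that("paired ensembles with no effect in either arm give fold change 1", {
  cfg <- small_cfg(mean_effect = 0)
  ens <- run_ensemble(cfg, n_reps = 3, base_seed = 2)
  expect_equal(ens$summary$fold_phi_addiction, 1, tolerance = 1e-12)
  expect_equal(ens$summary$fold_phi_withdrawal, 1, tolerance = 1e-12)
  expect_equal(nrow(ens$metrics), 6)
})

test_that("schedule baselines equal simulated zero-effect baselines", {
  cfg <- small_cfg(mean_effect = 8)
  sim <- run_ensemble(cfg, n_reps = 3, base_seed = 4,
                      baseline = "simulate")
  sch <- run_ensemble(cfg, n_reps = 3, base_seed = 4,
                      baseline = "schedule")
  expect_equal(sim$summary$baseline_phi_withdrawal,
               sch$summary$baseline_phi_withdrawal, tolerance = 1e-12)
  expect_equal(sim$summary$fold_phi_withdrawal,
               sch$summary$fold_phi_withdrawal, tolerance = 1e-12)
})

test_that("sweeps cross axes, derive per-cell seeds and support effect coupling", {
  cfg <- small_cfg()
  grid <- list(n_strains = c(5L, 10L), mean_effect = c(0.5, 2))
  res <- sweep_sim(grid, cfg, reps = 2, base_seed = 3)
  expect_equal(nrow(res), 4)
  expect_true(all(c("fold_phi_withdrawal", "cell_seed") %in% names(res)))
  res2 <- sweep_sim(grid, cfg, reps = 2, base_seed = 3)
  expect_identical(res, res2)

  # a 1x1 grid reduces to run_ensemble at the derived cell seed
  one <- sweep_sim(list(n_strains = 8L), cfg, reps = 2, base_seed = 7)
  ens <- run_ensemble({cfg2 <- cfg; cfg2$n_strains <- 8L; cfg2}, 2,
                      microbehave:::derive_seed(7, 1))
  expect_equal(one$fold_phi_withdrawal, ens$summary$fold_phi_withdrawal)

  # coupling rule: E[d] = 5 / affecting fraction
  cp <- sweep_sim(list(affecting_fraction = c(0.1, 0.5, 1.0)), cfg,
                  reps = 1, base_seed = 1, couple_effect = TRUE,
                  baseline = "schedule")
  expect_equal(cp$mean_effect_used, c(50, 10, 5))
  expect_error(sweep_sim(list(bogus = 1), cfg, reps = 1), "unknown")
})
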