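no_strains <- function(n, cost = 0) {
  strain_set(matrix(0, n, 2), rep(0, n), cost = cost,
             affecting = cost > 0)
}

test_that("normalized step reproduces hand-computed updates", {
  # single strain: normalization pins the proportion at 1
  st1 <- microbiome_state(1)
  out1 <- step_normalized(st1, r = 0.7, no_strains(1),
                          dynamics_params(mu = 0))
  expect_equal(out1$proportions, 1)

  # symmetric community stays symmetric
  st2 <- microbiome_state(c(0.5, 0.5))
  out2 <- step_normalized(st2, r = c(1, 1), no_strains(2),
                          dynamics_params(mu = 0))
  expect_equal(out2$proportions, c(0.5, 0.5))

  # hand iteration: x = [0.5, 0.5], r = [1.1, 1.0], s = 1, c = 0, mu = 0
  # pre-normalization [0.8, 0.75], then divide by 1.55
  out3 <- step_normalized(st2, r = c(1.1, 1.0), no_strains(2),
                          dynamics_params(s = 1, mu = 0))
  expect_equal(out3$proportions, c(0.8, 0.75) / 1.55, tolerance = 1e-12)
})

test_that("normalized step keeps the simplex and the inflow floor", {
  set.seed(8)
  n <- 20
  st <- sample_strains(n, mean_effect = 0, affecting_fraction = 0)
  dp <- dynamics_params(mu = 1e-8)
  state <- microbiome_state(rep(1 / n, n))
  for (i in 1:200) {
    r <- growth_rate(c(runif(1), 0), st)
    state <- step_normalized(state, r, st, dp)
    expect_equal(sum(state$proportions), 1, tolerance = 1e-12)
    expect_true(all(state$proportions >= 1e-8 / (n * (1 + 1e-8)) - 1e-18))
  }
})

test_that("equal-rate communities preserve permutation symmetry exactly", {
  x <- c(0.1, 0.25, 0.4, 0.25)
  perm <- c(3, 1, 4, 2)
  st <- no_strains(4)
  dp <- dynamics_params()
  a <- step_normalized(microbiome_state(x), rep(0.9, 4), st, dp)
  b <- step_normalized(microbiome_state(x[perm]), rep(0.9, 4), st, dp)
  expect_equal(a$proportions[perm], b$proportions, tolerance = 1e-15)
})

test_that("extinct community without inflow raises a degenerate-community error", {
  st <- no_strains(2, cost = 2.5)   # cost so large both strains die
  state <- microbiome_state(c(0.5, 0.5))
  expect_error(step_normalized(state, r = c(0.3, 0.3), st,
                               dynamics_params(mu = 0,
                                               inflow_mode = "none")),
               "degenerate")
})

test_that("interaction matrix has the prescribed structure", {
  expect_equal(build_interaction_matrix(2, 0), diag(c(-1, -1)))
  A3 <- build_interaction_matrix(3, 0.5)
  expect_true(all(A3[row(A3) != col(A3)] == -0.5))
  expect_true(all(diag(A3) == -1))
  # algebraic identity: A = -(1 - delta) I - delta J
  n <- 5; delta <- 0.3
  expect_equal(build_interaction_matrix(n, delta),
               -(1 - delta) * diag(n) - delta * matrix(1, n, n))
})

test_that("GLV step reproduces hand-computed updates and guards", {
  dp <- dynamics_params(variant = "glv", mu = 0, delta = 0.5)
  # absorbing zero without inflow
  out0 <- step_glv(microbiome_state(0), r = 1,
                   build_interaction_matrix(1, 0), dp)
  expect_equal(out0$proportions, 0)
  # logistic fixed point x* = r
  outf <- step_glv(microbiome_state(0.8), r = 0.8,
                   build_interaction_matrix(1, 0), dp)
  expect_equal(outf$proportions, 0.8, tolerance = 1e-15)
  # hand evaluation for two strains
  out2 <- step_glv(microbiome_state(c(0.5, 0.5)), r = c(1.1, 1.0),
                   build_interaction_matrix(2, 0.5), dp)
  expect_equal(out2$proportions, c(0.675, 0.625), tolerance = 1e-12)
  # divergence guard names the step
  dpc <- dynamics_params(variant = "glv", mu = 0, glv_ceiling = 1)
  expect_error(step_glv(microbiome_state(0.9, time = 41L), r = 5,
                        build_interaction_matrix(1, 0), dpc),
               "step 42")
})

test_that("GLV trajectory matches an independently coded logistic recurrence", {
  r <- 0.85; mu <- 1e-4
  dp <- dynamics_params(variant = "glv", mu = mu,
                        inflow_mode = "per_strain_scaled")
  A <- build_interaction_matrix(1, 0)
  state <- microbiome_state(0.05)
  x_ref <- 0.05
  for (i in 1:500) {
    state <- step_glv(state, r, A, dp)
    x_ref <- x_ref + x_ref * (r - x_ref) + mu   # independent recurrence
    expect_equal(state$proportions, x_ref, tolerance = 1e-13)
  }
  expect_equal(state$proportions, r, tolerance = 1e-3)  # near fixed point
})
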