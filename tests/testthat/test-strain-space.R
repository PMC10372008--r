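test_that("sampled communities respect the unit ball and effect assignment", {
  set.seed(1)
  st <- sample_strains(50, dims = 2, mean_effect = 10, affecting_fraction = 1)
  expect_equal(nrow(st$features), 50)
  expect_true(all(sqrt(rowSums(st$features^2)) <= 1))
  expect_true(all(st$affecting))
  expect_true(all(st$effect_magnitude > 0))

  set.seed(2)
  st0 <- sample_strains(1, dims = 3, mean_effect = 10,
                        affecting_fraction = 0)
  expect_identical(st0$effect_magnitude, 0)
  expect_false(any(st0$affecting))

  set.seed(3)
  half <- sample_strains(40, mean_effect = 4, affecting_fraction = 0.5,
                         cost = 0.1)
  expect_equal(sum(half$affecting), 20)
  expect_true(all(half$effect_magnitude[!half$affecting] == 0))
  expect_true(all(half$cost[!half$affecting] == 0))
  expect_true(all(half$cost[half$affecting] == 0.1))
})

test_that("sampled feature and effect moments match the uniform-disk and exponential laws", {
  set.seed(123)
  n <- 1e4
  st <- sample_strains(n, dims = 2, mean_effect = 10)
  # uniform disk: E[r^2] = 1/2, Var[r^2] = 1/12
  r2 <- rowSums(st$features^2)
  expect_lt(abs(mean(r2) - 0.5), 3 * sqrt(1 / 12 / n))
  # exponential effects: mean within 3 standard errors of E[d]
  d <- st$effect_magnitude
  expect_lt(abs(mean(d) - 10), 3 * 10 / sqrt(n))
})

test_that("strain sampling is reproducible under a fixed seed", {
  set.seed(77)
  a <- sample_strains(30, mean_effect = 5, affecting_fraction = 0.4)
  set.seed(77)
  b <- sample_strains(30, mean_effect = 5, affecting_fraction = 0.4)
  expect_identical(a, b)
})

test_that("strain_set enforces its invariants", {
  expect_error(sample_strains(0, 2), "positive")
  expect_error(sample_strains(5, 0), "positive")
  expect_error(strain_set(rbind(c(2, 0)), 1), "unit ball")
  expect_error(strain_set(rbind(c(0, 0)), -1), ">= 0")
  expect_error(strain_set(rbind(c(0, 0)), 1, affecting = FALSE),
               "non-affecting")
  expect_error(strain_set(rbind(c(0, 0)), 0, cost = 0.1,
                          affecting = FALSE), "non-affecting")
})

test_that("growth rates follow the distance-decay law", {
  st <- strain_set(rbind(c(0, 0), c(1, 0), c(-1, 0)), c(0, 0, 0),
                   affecting = FALSE)
  gp <- growth_params()  # alpha = 3, beta = 0.1, floor = 0.1
  r <- growth_rate(c(0, 0), st, gp)
  expect_equal(r[1], 1.1)           # zero distance
  expect_equal(r[2], 1.0)           # 0.1 + 1 - 0.1 * 1^3
  r2 <- growth_rate(c(1, 0), st, gp)
  expect_equal(r2[3], 0.3)          # distance 2: 0.1 + max(0, 1 - 0.8)
})

test_that("growth rate is non-increasing in distance and bounded on the segment", {
  gp <- growth_params()
  dists <- seq(0, 2, length.out = 200)
  st <- strain_set(cbind(0, 0), 0, affecting = FALSE)
  r <- sapply(dists, function(dd) growth_rate(c(dd, 0), st, gp))
  expect_true(all(diff(r) <= 1e-15))
  # all strain/behavior pairs inside the ball x unit segment stay in [0.3, 1.1]
  set.seed(5)
  st2 <- sample_strains(200, dims = 2, mean_effect = 0,
                        affecting_fraction = 0)
  for (b in c(0, 0.3, 0.7, 1)) {
    rr <- growth_rate(c(b, 0), st2, gp)
    expect_true(all(rr >= 0.3 - 1e-12 & rr <= 1.1 + 1e-12))
  }
})

test_that("behavior-independent strains receive the constant rate", {
  st <- strain_set(rbind(c(0.5, 0), c(0.5, 0)), c(0, 0), affecting = FALSE,
                   behavior_independent = c(FALSE, TRUE))
  r <- growth_rate(c(0, 0), st, growth_params(r_independent = 0.6))
  expect_equal(r[2], 0.6)
  expect_false(r[1] == 0.6)
})

test_that("growth_rate rejects dimension mismatches and non-finite input", {
  st <- strain_set(rbind(c(0, 0)), 0, affecting = FALSE)
  expect_error(growth_rate(c(0, 0, 0), st), "dimensionality")
  expect_error(growth_rate(c(NA, 0), st), "finite")
})

test_that("strain communities round-trip through TSV with a JSON sidecar", {
  set.seed(11)
  st <- sample_strains(12, dims = 3, mean_effect = 7,
                       affecting_fraction = 0.5, cost = 0.05)
  path <- file.path(tempdir(), "strains.tsv")
  write_strains(st, path, meta = list(seed = 11, mean_effect = 7))
  back <- read_strains(path)
  expect_equal(back$features, st$features, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$effect_magnitude, st$effect_magnitude,
               tolerance = 1e-12)
  expect_identical(back$affecting, st$affecting)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(meta$mean_effect, 7)
})
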