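sched <- spr_schedule()
grid <- kinetic_grid()

test_that("schedule and grid validate the published layout", {
  expect_equal(sched$concentrations_nM, c(20, 100, 300, 1000, 3000))
  expect_equal(length(grid$kd), 21)
  expect_equal(range(grid$kd), c(1e-9, 1e-3))
  expect_equal(range(grid$koff), c(1e-5, 1))
  # log-uniform spacing
  expect_equal(diff(log10(grid$kd)), rep(0.3, 20))
  expect_error(spr_schedule(concentrations_nM = c(100, 20)), "invalid-input")
  expect_error(spr_schedule(dissoc_window = c(700, 2400)), "invalid-input")
})

test_that("Langmuir occupancy reaches equilibrium and halves per off-rate half-life", {
  kd <- 1e-7; koff <- 1e-2
  th <- langmuir_basis(kd, koff, spr_schedule(concentrations_nM = kd * 1e9),
                       times = c(0, 790))  # kobs = 0.02/s: equilibrated by 790 s
  expect_equal(th[2, 1], 0.5, tolerance = 1e-4)  # C = K_D -> theta_eq = 1/2
  # dissociation half-life
  t_half <- 800 + log(2) / koff
  th2 <- langmuir_basis(kd, koff, sched, times = c(800, t_half))
  expect_equal(th2[2, ] / th2[1, ], rep(0.5, 5), tolerance = 1e-12)
  # occupancies stay in [0, 1]
  th3 <- langmuir_basis(1e-8, 0.5, sched, times = seq(0, 2400, 10))
  expect_true(all(th3 >= 0 & th3 <= 1))
  # equilibrium limit at long times, any node
  for (j in c(1, 100, 441)) {
    kdj <- grid$nodes$kd[j]; koffj <- grid$nodes$koff[j]
    s_long <- spr_schedule(t_inject_end = 8e6, t_dissoc_end = 9e6,
                           assoc_window = c(2, 8e6 - 2),
                           dissoc_window = c(8e6 + 1, 9e6))
    th <- langmuir_basis(kdj, koffj, s_long, times = 8e6 - 10)
    eq <- s_long$concentrations_M / (s_long$concentrations_M + kdj)
    expect_equal(unname(th[1, ]), eq, tolerance = 1e-6)
  }
})

test_that("sequential titration carries occupancy; full dissociation resets it", {
  fast <- langmuir_basis(1e-7, 0.1, sched, times = seq(0, 2400, 50),
                         mode = "sequential_titration")
  indep <- langmuir_basis(1e-7, 0.1, sched, times = seq(0, 2400, 50))
  # koff = 0.1/s empties the surface in the 1600 s dissociation phase
  expect_equal(fast, indep, tolerance = 1e-10)
  slow <- langmuir_basis(1e-7, 1e-4, sched, times = 0,
                         mode = "sequential_titration")
  expect_gt(slow[1, 2], 0)      # cycle 2 starts loaded
  expect_equal(slow[1, 1], 0)   # cycle 1 starts empty
})

test_that("drift correction removes the mean of pre/post baseline slopes", {
  t <- seq(0, 2400, 4)
  pre <- c(0, 100); post <- c(2300, 2400)
  dc <- drift_correct(t, 0.1 * t, pre, post)
  expect_equal(dc$response, rep(0, length(t)), tolerance = 1e-9)
  dc0 <- drift_correct(t, rep(2, length(t)), pre, post)
  expect_equal(dc0$response, rep(2, length(t)), tolerance = 1e-9)
  # asymmetric drift: slope (0.05 + 0.15)/2 = 0.10 is removed
  r <- ifelse(t <= 100, 0.05 * t, 0.15 * t)
  dc2 <- drift_correct(t, r, pre, post)
  expect_equal(dc2$slope, 0.1, tolerance = 1e-9)
  expect_error(drift_correct(t, r, c(-10, -5), post), "insufficient-baseline")
})

test_that("design matrix columns are unit Langmuir traces", {
  A <- build_design_matrix(grid, sched)
  expect_equal(dim(A), c(length(retained_times(sched)) * 5, 441))
  expect_true(all(A >= 0 & A <= 1))
  # single-node weight reproduces that basis trace exactly
  j <- 150; R <- 42
  model <- A %*% replace(numeric(441), j, R)
  basis <- langmuir_basis(grid$nodes$kd[j], grid$nodes$koff[j], sched,
                          retained_times(sched))
  expect_equal(drop(model), R * as.vector(basis), tolerance = 1e-12)
  # distinct nodes give distinct columns on the multi-concentration schedule
  set.seed(14)
  pick <- sample(441, 30)
  d <- as.matrix(dist(t(A[, pick])))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("fnnls agrees with the Lawson-Hanson reference solver", {
  skip_if_not_installed("pracma")
  set.seed(8)
  for (k in 1:8) {
    n <- 40; p <- 15
    Z <- matrix(rnorm(n * p), n, p)
    d <- drop(Z %*% pmax(0, rnorm(p)) + 0.05 * rnorm(n))
    x1 <- fnnls(crossprod(Z), drop(crossprod(Z, d)))
    x2 <- pracma::lsqnonneg(Z, d)$x
    expect_equal(x1, x2, tolerance = 1e-6)
    expect_true(all(x1 >= 0))
  }
})

test_that("noiseless single-node data concentrate the fitted distribution", {
  i <- 9; j <- 12
  sim <- generate_sensorgrams(data.frame(kd = grid$kd[i], koff = grid$koff[j],
                                         amplitude = 100),
                              sched, grid, noise_sigma = 0, seed = 1)
  fit <- fit_distribution(sim$retained, grid, sched)
  nb <- fit$P[max(1, i - 1):min(21, i + 1), max(1, j - 1):min(21, j + 1)]
  expect_gte(sum(nb) / sum(fit$P), 0.95)
  expect_equal(sum(fit$P), 100, tolerance = 0.05)
  # linearity: the fitted traces reproduce the data at alpha -> 0
  expect_lt(sqrt(fit$rss_min / fit$n_points), 1e-8)
})

test_that("zero response yields an empty distribution", {
  fit <- fit_distribution(rep(0, length(retained_times(sched)) * 5),
                          grid, sched)
  expect_equal(sum(fit$P), 0)
  expect_error(population_fractions(fit, list(all = list(kd = c(1e-9, 1e-3),
                                                         koff = c(1e-5, 1)))),
               "empty-distribution")
})

test_that("regularization misfit grows monotonically with alpha", {
  sim <- generate_sensorgrams(data.frame(kd = 1e-7, koff = 1e-2, amplitude = 80),
                              sched, grid, noise_sigma = 1, seed = 3)
  A <- build_design_matrix(grid, sched)
  AtA <- crossprod(A); Atb <- drop(crossprod(A, sim$retained))
  btb <- sum(sim$retained^2)
  alphas <- mean(diag(AtA)) * 10^seq(-6, 2, length.out = 9)
  rss <- vapply(alphas, function(a) {
    x <- fnnls(AtA + diag(a, 441), Atb)
    btb - 2 * sum(x * Atb) + drop(crossprod(x, AtA %*% x))
  }, 0)
  expect_true(all(diff(rss) > -1e-6 * max(rss)))
})

test_that("population fractions sum regions of the weight grid", {
  fit <- list(grid = grid, P = matrix(0, 21, 21))
  class(fit) <- "kinetic_fit"
  fit$P[5, 7] <- 2
  full <- population_fractions(fit, list(all = list(kd = c(1e-9, 1e-3),
                                                    koff = c(1e-5, 1))))
  expect_equal(unname(full["all"]), 1)
  expect_equal(unname(full["unassigned"]), 0)
  delta <- population_fractions(fit, list(
    a = list(kd = c(1e-9, 1e-6), koff = c(1e-5, 1e-2)),
    b = list(kd = c(1e-5, 1e-3), koff = c(1e-1, 1))))
  expect_equal(unname(delta["a"]), 1)
  expect_equal(unname(delta["b"]), 0)
  expect_error(population_fractions(fit, list(
    a = list(kd = c(1e-9, 1e-3), koff = c(1e-5, 1)),
    b = list(kd = c(1e-5, 1e-3), koff = c(1e-1, 1)))), "overlap")
})

test_that("two concentration-bracketed sites are decomposed within 10 points", {
  # strong/slow minor site + weak/fast major site, both on grid nodes inside
  # the titration's informative K_D range (mirrors the published fit shape:
  # a major fast population and a minor strong population)
  reg_strong <- list(kd = c(1e-9, 10^-6.2), koff = c(1e-5, 10^-2.1))
  reg_weak <- list(kd = c(10^-6.1, 1e-3), koff = c(10^-2.0, 1))
  A <- build_design_matrix(grid, sched)
  for (s in 1:3) {
    sim <- generate_sensorgrams(
      data.frame(kd = c(10^-6.9, 10^-5.4), koff = c(10^-3, 10^-1),
                 amplitude = c(30, 70)),
      sched, grid, noise_sigma = 0.3, seed = s)
    fit <- fit_distribution(sim$retained, grid, sched, design = A)
    fr <- population_fractions(fit, list(strong = reg_strong, weak = reg_weak))
    expect_lt(abs(fr["strong"] - 0.3), 0.1)
    expect_lt(abs(fr["weak"] - 0.7), 0.1)
  }
})

test_that("sensorgram generator superposes sites, drift and noise reproducibly", {
  sites <- data.frame(kd = 1e-7, koff = 1e-2, amplitude = 50)
  a <- generate_sensorgrams(sites, sched, grid, noise_sigma = 1, seed = 5)
  b <- generate_sensorgrams(sites, sched, grid, noise_sigma = 1, seed = 5)
  expect_identical(a$response, b$response)
  # amplitude 0 -> pure noise around zero
  z <- generate_sensorgrams(data.frame(kd = 1e-7, koff = 1e-2, amplitude = 0),
                            sched, grid, noise_sigma = 1, seed = 5)
  expect_lt(abs(mean(z$response)), 0.1)
  # noiseless end-of-association response approaches the isotherm
  n0 <- generate_sensorgrams(sites, sched, grid, noise_sigma = 0, seed = 1)
  i800 <- which(n0$times == 800)
  eq <- 50 * sched$concentrations_M / (sched$concentrations_M + 1e-7)
  expect_equal(unname(n0$response[i800, ]), unname(eq), tolerance = 1e-2)
  # drift is a straight line added on top
  dr <- generate_sensorgrams(sites, sched, grid, noise_sigma = 0,
                             drift_slope = 0.01, seed = 1)
  expect_equal(dr$response - n0$response,
               matrix(0.01 * n0$times, length(n0$times), 5), tolerance = 1e-9)
  # truth rasterizes onto the nearest grid node
  expect_equal(sum(n0$truth_P), 50)
  expect_equal(which(n0$truth_P > 0, arr.ind = TRUE)[1, ],
               c(row = 8, col = 13))
})
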