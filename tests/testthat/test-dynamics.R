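test_that("derivative matches hand evaluation", {
  p <- dynamics_params(phi = 0.1, pi = 0.2)
  mu <- setNames(rep(0.5, 8), edge_names())
  zero <- setNames(rep(0, 6), nflevo:::species_names())

  expect_equal(unname(signaling_derivative(zero, mu, p)), rep(0, 6))

  # logistic at carrying capacity: dP/dt = 0 when P = 1 and clearance is off
  y <- zero; y["P"] <- 1
  mu0 <- setNames(rep(0, 8), edge_names())
  expect_equal(signaling_derivative(y, mu0, p)[["P"]], 0)

  # dP/dt = pi * P * (1 - P) with no immunity
  y <- zero; y["P"] <- 0.5
  expect_equal(signaling_derivative(y, mu0, p)[["P"]], 0.2 * 0.5 * 0.5)

  # activation saturates with (1 - y_i), inhibition scales with y_i
  y <- c(P = 0.5, R = 0.4, A = 0, I = 0, U = 0, D = 0)
  muRP <- setNames(c(0.6, rep(0, 7)), edge_names())
  expect_equal(signaling_derivative(y, muRP, p)[["R"]],
               -0.1 * 0.4 + 0.6 * 0.5 * (1 - 0.4))
  muRP["R_P"] <- -0.6
  expect_equal(signaling_derivative(y, muRP, p)[["R"]],
               -0.1 * 0.4 - 0.6 * 0.5 * 0.4)
})

test_that("uninfected hosts have the identically zero trajectory", {
  p <- dynamics_params(phi = 0.15, pi = 0.3, infected = FALSE)
  tr <- integrate_lifetime(setNames(runif(8, -1, 1), edge_names()), p)
  expect_true(all(tr$y == 0))
  expect_identical(tr$P_bar, 0)
  expect_identical(tr$I_bar, 0)
})

test_that("pathogen at carrying capacity with inert network stays at 1", {
  p <- dynamics_params(phi = 0, pi = 0.5, P0 = 1)
  tr <- integrate_lifetime(setNames(rep(0, 8), edge_names()), p)
  expect_true(all(tr$y[, "P"] == 1))
  expect_equal(tr$P_bar, (p$steps + 1) / p$steps)  # grid sum incl. t=0 over T
  expect_true(all(tr$y[, c("R", "A", "I", "U", "D")] == 0))
})

test_that("free pathogen growth follows the logistic closed form", {
  p <- dynamics_params(phi = 0, pi = 0.1, P0 = 0.5, T = 200)
  tr <- integrate_lifetime(setNames(rep(0, 8), edge_names()), p)
  closed <- 1 / (1 + (1 / 0.5 - 1) * exp(-0.1 * tr$times))
  expect_lt(max(abs(tr$y[, "P"] - closed)), 0.005)  # Euler truncation at dt=1
})

test_that("concentrations stay in [0,1] for random parameter draws", {
  set.seed(21)
  for (i in 1:15) {
    p <- dynamics_params(phi = runif(1, 0, 0.5), pi = runif(1, 0, 1),
                         P0 = runif(1), T = 200)
    tr <- integrate_lifetime(random_mu(), p)
    expect_true(all(tr$y >= 0 & tr$y <= 1))
  }
})

test_that("inhibition of absent proteins keeps them absent", {
  mu <- setNames(pmin(runif(8, -1, 0), 0), edge_names())
  p <- dynamics_params(phi = 0, pi = 0.2, P0 = 1)
  tr <- integrate_lifetime(mu, p)
  expect_true(all(tr$y[, c("R", "A", "I", "U", "D")] == 0))
})

test_that("stronger activation of immunity never lowers its lifetime average", {
  # clearance off, so the receptor drive is constant and the comparison is
  # not confounded by immunity feeding back on the pathogen
  p <- dynamics_params(phi = 0.15, pi = 0.2)
  ibars <- vapply(seq(0, 1, by = 0.25), function(m) {
    mu <- setNames(c(1, 1, m, 0, 0, 0, 0, 0), edge_names())
    integrate_lifetime(mu, p)$I_bar
  }, numeric(1))
  expect_true(all(diff(ibars) >= 0))
})

test_that("batch integration reproduces the scalar path", {
  set.seed(33)
  p <- dynamics_params(phi = 0.1, pi = 0.25, T = 300)
  mus <- lapply(1:10, function(i) random_mu())
  b <- batch_integrate(mus, p)
  for (i in seq_along(mus)) {
    r <- integrate_lifetime(mus[[i]], p)
    expect_lt(max(abs(r$y - b$trajectories[[i]]$y)), 1e-12)
    expect_equal(b$P_bar[i], r$P_bar, tolerance = 1e-12)
  }
  one <- batch_integrate(mus[1], p)
  expect_equal(one$trajectories[[1]]$y, integrate_lifetime(mus[[1]], p)$y)
  expect_error(batch_integrate(list(), p), "at least one")
})

test_that("dynamics parameters are validated", {
  expect_error(dynamics_params(phi = 0.1), "pi")
  expect_error(dynamics_params(phi = -1, pi = 0.2), "phi")
  expect_error(dynamics_params(phi = 0, pi = 0.2, P0 = 2), "P0")
  expect_error(dynamics_params(phi = 0, pi = 0.2, T = 10, dt = 3), "whole number")
  expect_error(dynamics_params(phi = c(R = 0, A = 0), pi = 0.2), "named")
})

test_that("trajectory export writes a readable table", {
  p <- dynamics_params(phi = 0, pi = 0.2, T = 50)
  tr <- integrate_lifetime(setNames(rep(0, 8), edge_names()), p)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f, thin = 5)
  tab <- read.delim(f)
  expect_identical(names(tab), c("time", "P", "R", "A", "I", "U", "D"))
  expect_equal(tab$time, seq(0, 50, by = 5))
  unlink(f)
})
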