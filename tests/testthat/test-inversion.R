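test_that("posterior mean and covariance match joint-Gaussian conditioning", {
  set.seed(23)
  for (rep in 1:8) {
    nd <- sample(3:10, 1); nc <- sample(2:8, 1); nt <- sample(1:5, 1)
    L <- matrix(rnorm(nc * nd), nc, nd)
    Q <- random_psd(nd)
    R <- random_psd(nc)
    Y <- matrix(rnorm(nc * nt), nc, nt)
    oracle <- joint_gaussian_oracle(Y, L, Q, R)
    est <- posterior_mean(Y, L, Q, R)
    expect_equal(est$Jhat, oracle$mean, tolerance = 1e-8)
    expect_equal(posterior_covariance(L, Q, R), oracle$cov, tolerance = 1e-8)
    expect_equal(posterior_covariance(L, Q, R, diagonal = TRUE),
                 pmax(diag(oracle$cov), 0), tolerance = 1e-8)
  }
})

test_that("degenerate priors and noise behave as limits demand", {
  set.seed(29)
  L <- matrix(rnorm(4 * 6), 4, 6)
  Y <- matrix(rnorm(4 * 3), 4, 3)
  # Q = 0: no prior variance, zero posterior mean and covariance
  z <- posterior_mean(Y, L, matrix(0, 6, 6), diag(4))
  expect_equal(z$Jhat, matrix(0, 6, 3))
  expect_equal(posterior_covariance(L, matrix(0, 6, 6), diag(4)),
               matrix(0, 6, 6))
  # infinite noise: estimate collapses to zero
  big <- posterior_mean(Y, L, diag(6), diag(exp(40), 4))
  expect_lt(max(abs(big$Jhat)), 1e-12)
  # L = 0: posterior covariance equals the prior
  Q <- random_psd(6)
  expect_equal(posterior_covariance(matrix(0, 4, 6), Q, diag(4)), Q,
               tolerance = 1e-12)
})

test_that("Woodbury consistency: sensor-space and source-space solutions agree", {
  set.seed(31)
  L <- matrix(rnorm(5 * 8), 5, 8)
  Q <- diag(0.7, 8)
  R <- diag(0.3, 5)
  Y <- matrix(rnorm(5 * 2), 5, 2)
  sensor_form <- posterior_mean(Y, L, Q, R)$Jhat
  source_form <- solve(solve(Q) + t(L) %*% solve(R) %*% L,
                       t(L) %*% solve(R) %*% Y)
  expect_equal(sensor_form, source_form, tolerance = 1e-9)
})

test_that("the log-posterior is maximised at the posterior mean", {
  set.seed(37)
  L <- matrix(rnorm(4 * 5), 4, 5)
  Q <- random_psd(5)
  R <- random_psd(4)
  Y <- matrix(rnorm(4 * 2), 4, 2)
  Jhat <- posterior_mean(Y, L, Q, R)$Jhat
  psi_hat <- log_posterior_psi(Jhat, Y, L, Q, R)
  expect_equal(log_posterior_psi(matrix(0, 5, 2), matrix(0, 4, 2), L, Q, R), 0)
  for (rep in 1:10) {
    J <- Jhat + matrix(rnorm(10, sd = 0.3), 5, 2)
    expect_lte(log_posterior_psi(J, Y, L, Q, R), psi_hat + 1e-10)
  }
  # finite-difference gradient vanishes at the maximiser
  eps <- 1e-5
  for (k in sample(10, 4)) {
    Jp <- Jhat; Jp[k] <- Jp[k] + eps
    Jm <- Jhat; Jm[k] <- Jm[k] - eps
    g <- (log_posterior_psi(Jp, Y, L, Q, R) - log_posterior_psi(Jm, Y, L, Q, R)) / (2 * eps)
    expect_lt(abs(g), 1e-5)
  }
})

test_that("accuracy equals the closed-form Gaussian log-density of the data", {
  set.seed(41)
  # one sensor, one source, fixed hyperparameters
  L <- matrix(2, 1, 1)
  y <- matrix(rnorm(20, sd = 1.5), 1, 20)
  comps <- minimum_norm_prior(1)
  hyper <- msp_hyper(c(noise = log(0.6), C1 = log(0.9)))
  fe <- free_energy(y, L, comps, hyper)
  Cy <- 0.6 + 4 * 0.9
  expect_equal(fe$accuracy, sum(dnorm(y, 0, sqrt(Cy), log = TRUE)), tolerance = 1e-10)
  # complexity is zero when posterior equals prior
  hyper0 <- msp_hyper(c(noise = 0.2, C1 = -0.3), nu = c(0.2, -0.3), alpha = 64,
                      Sigma_lambda = diag(64, 2))
  expect_equal(free_energy(y, L, comps, hyper0)$complexity, 0, tolerance = 1e-12)
})

test_that("inflating the noise model away from the data lowers F", {
  set.seed(43)
  L <- matrix(rnorm(6 * 10), 6, 10)
  comps <- minimum_norm_prior(10)
  Y <- L %*% matrix(rnorm(10 * 30, sd = 0.4), 10, 30)
  base <- msp_hyper(c(noise = log(0.1), C1 = log(0.16)))
  worse <- msp_hyper(c(noise = log(500), C1 = log(0.16)))
  expect_lt(free_energy(Y, L, comps, worse)$F,
            free_energy(Y, L, comps, base)$F)
})

test_that("hyperparameter optimisation identifies a single active component", {
  setup <- tiny_setup(150, 24, 16, 16)
  L <- compute_lead_field(setup$mesh, setup$sensors)
  set.seed(47)
  g <- setup$comps$vectors[, 7]
  J <- g %o% sin(2 * pi * 20 * (0:80) * 0.005)
  Yc <- L$matrix %*% J
  Y <- Yc + matrix(rnorm(length(Yc), sd = sqrt(mean(Yc^2) / 1000)),
                   nrow(Yc), ncol(Yc))
  fit <- msp_invert(Y, L, setup$comps, compute_sources = FALSE)
  # compare sensor-level contributions so the test is scale-free
  sens_w <- fit$w_source * colSums((L$matrix %*% setup$comps$vectors)^2)
  expect_equal(which.max(sens_w), 7L)
  expect_lt(sort(sens_w, decreasing = TRUE)[2] / max(sens_w), 1e-3)
})

test_that("pure-noise data prune the sources and recover the noise variance", {
  setup <- tiny_setup(150, 24, 16, 16)
  L <- compute_lead_field(setup$mesh, setup$sensors)
  set.seed(53)
  ratios <- replicate(30, {
    Y <- matrix(rnorm(24 * 80, sd = sqrt(0.5)), 24, 80)
    fit <- msp_invert(Y, L, setup$comps, compute_sources = FALSE)
    src_power <- sum(fit$w_source * colSums((L$matrix %*% setup$comps$vectors)^2)) / 24
    c(fit$sigma2_noise / 0.5, src_power / fit$sigma2_noise)
  })
  expect_lt(abs(mean(ratios[1, ]) - 1), 0.2)   # sigma^2 within 20%
  expect_lt(mean(ratios[2, ]), 0.2)            # sources carry < 20% of noise power
})

test_that("the free-energy trace is non-decreasing and Sigma_lambda is PSD", {
  setup <- tiny_setup(150, 24, 16, 16)
  L <- compute_lead_field(setup$mesh, setup$sensors)
  set.seed(59)
  spec <- simulation_spec(n_sources = 2, snr_db = 5, n_time = 81)
  truth <- simulate_sources(setup$mesh, setup$comps, spec)
  Y <- add_noise(L$matrix %*% truth$J_true, 5)
  fit <- msp_invert(Y, L, setup$comps, compute_sources = FALSE)
  expect_true(all(diff(fit$F_trace) >= -1e-6 * pmax(abs(fit$F_trace[-1]), 1)))
  ev <- eigen(fit$hyper$Sigma_lambda, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_identical(names(fit$hyper$mu)[1], "noise")
  # tidy/glance views are consistent with the fit
  td <- tidy(fit)
  expect_equal(nrow(td), n_components(setup$comps))
  expect_equal(glance(fit)$F, fit$F)
})
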