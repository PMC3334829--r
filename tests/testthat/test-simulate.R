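test_that("source profiles follow the Gaussian FWHM relation", {
  # a flat strip mesh with known inter-vertex distances
  xs <- seq(0, 35, by = 5)
  verts <- rbind(cbind(xs, 0, 0), cbind(xs, 5, 0))
  n <- length(xs)
  faces <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    rbind(c(i, i + 1, n + i), c(i + 1, n + i + 1, n + i))))
  mesh <- cortical_mesh(verts, faces,
                        normals = matrix(rep(c(0, 0, 1), 2 * n), 2 * n, byrow = TRUE))
  comps <- structure(list(type = "rank1",
                          vectors = diag(2 * n)[, 2, drop = FALSE],
                          centers = 2L, n_dipoles = 2L * n),
                     class = "msp_components")
  spec <- simulation_spec(n_sources = 1, freq_hz = 10, fwhm = 10, snr_db = NULL,
                          n_time = 41, dt = 0.005, profile = "gaussian")
  set.seed(3)
  truth <- simulate_sources(mesh, comps, spec)
  expect_equal(truth$source_vertices, 2L)
  prof <- apply(abs(truth$J_true), 1, max)
  # maximum at the centre vertex
  expect_equal(which.max(prof), 2L)
  # amplitude at distance FWHM/2 = 5 mm is half the peak (sigma = FWHM/2.355)
  expect_equal(prof[3] / prof[2], 0.5, tolerance = 1e-6)
  expect_equal(prof[1] / prof[2], 0.5, tolerance = 1e-6)
  # temporal course is the requested sinusoid
  expect_equal(truth$J_true[2, ], sin(2 * pi * 10 * (0:40) * 0.005),
               tolerance = 1e-12)
})

test_that("a vanishing FWHM gives a delta source", {
  mesh <- tiny_mesh(120)
  comps <- minimum_norm_prior(nrow(mesh$vertices))
  spec <- simulation_spec(n_sources = 1, fwhm = 1e-6, snr_db = NULL, n_time = 11,
                          profile = "gaussian")
  set.seed(7)
  truth <- simulate_sources(mesh, comps, spec)
  prof <- apply(abs(truth$J_true), 1, max)
  expect_equal(sum(prof > 1e-12), 1L)
  expect_equal(which.max(prof), truth$source_vertices)
})

test_that("noise is calibrated to the requested SNR and uncorrelated", {
  set.seed(11)
  Y <- matrix(rnorm(60 * 161, sd = 3), 60, 161)
  for (snr in c(0, 20)) {
    noisy <- add_noise(Y, snr)
    v_ratio <- mean(Y^2) / mean((noisy - Y)^2)
    expect_equal(10 * log10(v_ratio), snr, tolerance = 0.5)
  }
  expect_identical(add_noise(Y, NULL), Y)
  # off-diagonal sensor correlations of the pure noise are small
  noise <- add_noise(Y, 0) - Y
  cm <- cor(t(noise))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("localisation error is the per-source Euclidean distance", {
  est <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  tru <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  err <- localisation_error(est, tru)
  expect_equal(err$error_mm, c(0, 5, 0))
  expect_equal(mean(err$error_mm), 5 / 3)
})

test_that("power peaks are genuine local maxima matched to sources", {
  mesh <- tiny_mesh(150)
  A <- as.matrix(mesh_adjacency(mesh))
  power <- rep(0.001, nrow(mesh$vertices))
  power[40] <- 1; power[120] <- 0.7
  pks <- find_power_peaks(power, mesh, rel_threshold = 0.05)
  expect_setequal(pks, c(40L, 120L))
  err <- source_recovery_error(power, mesh, c(40L, 120L))
  expect_equal(err$error_mm, c(0, 0))
  expect_false(any(err$missing))
  # a distant "source" with no nearby maximum is flagged under a region cap
  far <- which.max(rowSums(sweep(mesh$vertices, 2, mesh$vertices[40, ])^2))
  err2 <- source_recovery_error(power, mesh, far, region_mm = 10)
  expect_true(err2$missing)
})

test_that("experiments are deterministic given the master seed", {
  spec <- simulation_spec(n_sources = 2, snr_db = 5, n_time = 41)
  cfg <- search_config(n_chains = 2, min_samples = 12, max_samples = 24)
  a <- run_experiment(spec, n_dipoles = 150, n_sensors = 24, n_modes = 12,
                      n_comp = 16, search = cfg, n_draws = 300, seed = 42)
  b <- run_experiment(spec, n_dipoles = 150, n_sensors = 24, n_modes = 12,
                      n_comp = 16, search = cfg, n_draws = 300, seed = 42)
  # equality to floating-point noise (threaded BLAS reductions may differ
  # in the last ulp between otherwise identical runs)
  expect_equal(glance(a), glance(b), tolerance = 1e-10)
  expect_equal(a$search$chains[[1]]$trace, b$search$chains[[1]]$trace,
               tolerance = 1e-10)
  expect_equal(a$bma$mean_power, b$bma$mean_power, tolerance = 1e-10)
  # a different seed produces a different realisation
  c2 <- run_experiment(spec, n_dipoles = 150, n_sensors = 24, n_modes = 12,
                       n_comp = 16, search = cfg, n_draws = 300, seed = 43)
  expect_false(identical(a$truth$Y, c2$truth$Y))
})

test_that("the fixed-head baseline skips the search", {
  ex <- run_experiment(simulation_spec(n_sources = 2, snr_db = NULL, n_time = 41),
                       n_dipoles = 150, n_sensors = 24, n_modes = 12,
                       n_comp = 16, seed = 8, run_search = FALSE)
  expect_null(ex$search)
  expect_true(is.na(glance(ex)$fiducial_error_mm))
  expect_equal(ex$mean_source_error, 0)
})
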