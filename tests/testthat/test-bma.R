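# A small search_data bundle plus a hand-made posterior sample table let the
# averaging identities be checked without running a Metropolis search.
bma_fixture <- function(n_mesh = 150, n_time = 30, snr_db = 5, seed = 101) {
  setup <- tiny_setup(n_mesh, 24, 16, 16)
  set.seed(seed)
  spec <- simulation_spec(n_sources = 2, snr_db = snr_db, n_time = n_time)
  truth <- simulate_sources(setup$mesh, setup$comps, spec)
  L <- compute_lead_field(setup$mesh, setup$sensors)
  Y <- add_noise(L$matrix %*% truth$J_true, snr_db)
  data <- search_data(Y, setup$mesh, setup$sensors, setup$fids, setup$comps,
                      n_modes = 16)
  list(data = data, truth = truth, setup = setup)
}

sample_row <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0, F = 0) {
  tibble::tibble(chain = 1L, iteration = 1L, tx = tx, ty = ty, tz = tz,
                 rx = rx, ry = ry, rz = rz, F = F, accepted = TRUE)
}

test_that("a single head reproduces the fixed-head posterior", {
  fx <- bma_fixture()
  samples <- sample_row()
  set.seed(1)
  b <- bma_average(samples, fx$data, n_draws = 10000, mode = "current")
  # the fixed-head fit this mixture degenerates to
  ev <- megcoreg:::make_f_evaluator(fx$data)
  fit <- compute_sources(ev(rigid_body_params())$fit)
  # elementwise mean within 3 standard errors of Jhat
  se <- sqrt(matrix(fit$diag_Sigma_J, length(fit$diag_Sigma_J),
                    ncol(fit$Jhat)) / 10000)
  dev <- abs(b$Jbar - fit$Jhat) / pmax(se, 1e-300)
  expect_lt(stats::quantile(dev, 0.999), 5)
  # per-vertex variance of the draws matches diag Sigma_J
  v_emp <- rowMeans(b$var_J)
  expect_equal(v_emp, fit$diag_Sigma_J, tolerance = 0.1)
  # the Rao-Blackwellised power-mode mean is exactly Jhat
  set.seed(2)
  bp <- bma_average(samples, fx$data, n_draws = 500, mode = "power")
  expect_equal(bp$Jbar, fit$Jhat, tolerance = 1e-12)
})

test_that("two equally weighted heads average to the mixture midpoint", {
  fx <- bma_fixture()
  h2 <- rigid_body_params(translation = c(2, 0, 0))
  samples <- dplyr::bind_rows(sample_row(), sample_row(tx = 2))
  ev <- megcoreg:::make_f_evaluator(fx$data)
  J1 <- compute_sources(ev(rigid_body_params())$fit)$Jhat
  J2 <- compute_sources(ev(h2)$fit)$Jhat
  set.seed(3)
  b <- bma_average(samples, fx$data, n_draws = 10000, mode = "power")
  mid <- (J1 + J2) / 2
  # multinomial weighting error ~ |J1-J2|/(2 sqrt(T))
  tolcap <- 4 * max(abs(J1 - J2)) / (2 * sqrt(10000))
  expect_lt(max(abs(b$Jbar - mid)), tolcap + 1e-12)
  expect_equal(b$n_heads, 2L)
})

test_that("the law of total variance holds across heads", {
  fx <- bma_fixture()
  samples <- dplyr::bind_rows(sample_row(), sample_row(tx = 4, ry = 5))
  set.seed(4)
  b <- bma_average(samples, fx$data, n_draws = 4000, mode = "current")
  v_emp <- rowMeans(b$var_J)
  # variance of draws >= mixture-mean within-model variance (minus MC slack)
  expect_true(mean(v_emp >= 0.8 * b$mean_diag_Sigma_J) > 0.95)
})

test_that("occam_window filters by log evidence", {
  s <- dplyr::bind_rows(sample_row(F = 10), sample_row(tx = 1, F = 8),
                        sample_row(tx = 2, F = 3))
  expect_equal(nrow(occam_window(s, Inf)), 3L)
  expect_equal(nrow(occam_window(s, 3)), 2L)
  expect_equal(occam_window(s, 0)$F, 10)
  expect_error(occam_window(s, -1), "non-negative")
  # filtering never increases the count
  for (w in c(0, 1, 5, 100)) expect_lte(nrow(occam_window(s, w)), nrow(s))
})

test_that("peak-location posterior tallies draws and builds confidence sets", {
  # identical draws: point mass on one vertex
  P1 <- matrix(rep(c(1, 5, 2), each = 50), 50, 3)
  pk <- peak_location_posterior(P1)
  expect_equal(pk$mass$mass, c(0, 1, 0))
  expect_equal(pk$confidence_set, 2L)

  # 60/40 split between two vertices
  set.seed(5)
  n <- 10000
  P2 <- matrix(0, n, 4)
  hot <- ifelse(runif(n) < 0.6, 2L, 4L)
  P2[cbind(seq_len(n), hot)] <- 1
  pk2 <- peak_location_posterior(P2)
  expect_lt(abs(pk2$mass$mass[2] - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  expect_equal(sum(pk2$mass$mass), 1)
  expect_setequal(pk2$confidence_set, c(2L, 4L))

  # masks restrict the argmax
  pk3 <- peak_location_posterior(P2, mask = c(3L, 4L))
  expect_equal(sum(pk3$mass$mass[c(3, 4)]), 1)
  expect_error(peak_location_posterior(P2, mask = integer(0)), "empty")
})

test_that("fiducial posteriors average isometries as expected", {
  fids <- fiducial_set(c(0, 90, 0), c(-80, 0, -10), c(80, 0, -10))
  # single identity sample: posterior mean is the reference
  fp0 <- fiducial_posterior(sample_row(), fids)
  expect_equal(fp0$mean$nasion, fids$nasion, tolerance = 1e-12)
  # two pure translations (2,0,0) and (4,0,0): nasion mean displaced (3,0,0)
  s <- dplyr::bind_rows(sample_row(tx = 2), sample_row(tx = 4))
  fp <- fiducial_posterior(s, fids)
  expect_equal(fp$mean$nasion, fids$nasion + c(3, 0, 0), tolerance = 1e-12)
  expect_equal(fiducial_error(fp, fids), 3, tolerance = 1e-12)
  # symmetric rotations about the ear axis average back to the reference
  s2 <- dplyr::bind_rows(sample_row(rz = 10), sample_row(rz = -10))
  fp2 <- fiducial_posterior(s2, fids)
  expect_lt(sqrt(sum((fp2$mean$left_ear - fids$left_ear)^2)), 1.3)
})
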