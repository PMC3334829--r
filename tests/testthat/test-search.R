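test_that("prior draws respect their bounds and moments", {
  p0 <- head_prior(sigma = 0, rotation_range = 180, init_rotation = 0)
  set.seed(61)
  h0 <- sample_prior(p0)
  expect_equal(h0$translation, c(0, 0, 0))
  expect_equal(h0$rotation, c(0, 0, 0))

  pr <- head_prior(sigma = 20)
  set.seed(61)
  draws <- t(replicate(10000, sample_prior(pr)$translation))
  expect_true(all(abs(draws) <= 20))
  # uniform on [-20, 20]: mean 0 within 3 standard errors
  se <- 20 / sqrt(3) / sqrt(10000)
  expect_true(all(abs(colMeans(draws)) < 3 * se))
})

test_that("Gaussian proposals have the configured spread and degenerate limit", {
  h <- rigid_body_params(c(1, 2, 3), c(4, 5, 6))
  expect_equal(propose(h, 0), h)
  set.seed(67)
  prop <- t(replicate(10000, propose(h, 1.5)$translation))
  sds <- apply(sweep(prop, 2, h$translation), 2, sd)
  expect_true(all(abs(sds - 1.5) / 1.5 < 0.05))
})

test_that("acceptance ratios follow the evidence difference and prior support", {
  expect_equal(acceptance_ratio(10, 10), 1)
  expect_equal(acceptance_ratio(10 + log(2), 10), 2, tolerance = 1e-12)
  expect_equal(acceptance_ratio(50, 10, prior_new = 0), 0)
  expect_error(acceptance_ratio(1, 1, 0, 0), "zero")
  # a proposal outside the 20 mm box has zero prior density
  pr <- head_prior(sigma = 20)
  expect_equal(prior_density(rigid_body_params(c(25, 0, 0)), pr), 0)
  expect_equal(prior_density(rigid_body_params(c(5, -19, 0)), pr), 1)
})

test_that("metropolis decisions match their probabilities", {
  expect_true(metropolis_decide(1.5))
  expect_false(metropolis_decide(0))
  set.seed(71)
  acc <- mean(replicate(10000, metropolis_decide(0.3)))
  expect_lt(abs(acc - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("a zero-width prior pins the chain and traces have the right length", {
  f_eval <- function(h) list(F = -sum(h$translation^2))
  p0 <- head_prior(sigma = 0, rotation_range = 0, init_rotation = 0)
  ch <- run_chain(prior = p0, config = search_config(n_chains = 2, min_samples = 10,
                                                     max_samples = 50),
                  n_samples = 50, f_eval = f_eval, seed = 5)
  expect_equal(nrow(ch$trace), 50L)
  expect_true(all(ch$trace$F == ch$trace$F[1]))
  expect_true(all(abs(as.matrix(ch$trace[, c("tx", "ty", "tz")])) == 0))
})

test_that("rejected proposals repeat the previous state", {
  # an evaluator that makes every move much worse forces rejections
  f_eval <- function(h) list(F = -1e6 * sum(h$translation^2))
  ch <- run_chain(prior = head_prior(sigma = 20, init_rotation = 0),
                  config = search_config(min_samples = 10, max_samples = 60),
                  n_samples = 60, f_eval = f_eval, seed = 9)
  tr <- ch$trace
  rejected <- which(!tr$accepted)[-1]
  for (k in rejected[rejected > 1]) {
    expect_equal(as.numeric(tr[k, 2:7]), as.numeric(tr[k - 1, 2:7]))
  }
})

test_that("the sampler recovers an analytic 1-D Gaussian posterior", {
  # free energy quadratic in tx alone: posterior is N(0, tau^2) inside a
  # wide flat prior box; only tx is proposed so this is a clean 1-D target
  tau <- 2
  f_eval <- function(h) list(F = -h$translation[1]^2 / (2 * tau^2))
  cfg <- search_config(proposal_sd = c(2.4 * tau, 0, 0, 0, 0, 0),
                       min_samples = 10, max_samples = 2e5)
  ch <- run_chain(prior = head_prior(sigma = 20, init_rotation = 0),
                  config = cfg, n_samples = 2e5, f_eval = f_eval, seed = 12,
                  init = rigid_body_params())
  x <- ch$trace$tx[-(1:1000)]
  thin <- x[seq(1, length(x), by = 20)]       # ~10,000 near-independent draws
  expect_gte(length(thin), 9000)
  ks <- suppressWarnings(stats::ks.test(thin, "pnorm", 0, tau))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(thin)), 0.3)
  expect_lt(abs(sd(thin) - tau), 0.1 * tau)
})

test_that("gelman_rubin reproduces hand-computed diagnostics", {
  # identical chains: B = 0, Rhat = (n-1)/n
  d <- gelman_rubin(list(rep(c(1, 2), 10), rep(c(1, 2), 10)))
  expect_equal(d$B, 0)
  expect_equal(d$rhat, (d$n - 1) / d$n)

  # chains {0,2} and {1,3}: Z = 2, B = 1, var = 1.5, Rhat = 0.75
  d2 <- gelman_rubin(list(c(0, 2), c(1, 3)), halve = FALSE)
  expect_equal(d2$Z, 2)
  expect_equal(d2$B, 1)
  expect_equal(d2$var_post, 1.5)
  expect_equal(d2$rhat, 0.75)

  # all values identical: degenerate, flagged
  d3 <- gelman_rubin(list(rep(1, 10), rep(1, 10)))
  expect_true(d3$degenerate)
  expect_true(is.na(d3$rhat))

  expect_error(gelman_rubin(list(1:10)), "two chains")
})

test_that("iid chains from one Gaussian give Rhat near 1", {
  set.seed(73)
  chains <- lapply(1:4, function(g) rnorm(20000, 5, 2))
  d <- gelman_rubin(chains)
  expect_gt(d$rhat, 0.98)
  expect_lt(d$rhat, 1.02)
})

test_that("multichain search stops by rule and is reproducible", {
  tau <- 2
  f_eval <- function(h) list(F = -h$translation[1]^2 / (2 * tau^2))
  cfg <- search_config(proposal_sd = c(2.4 * tau, 0, 0, 0, 0, 0), n_chains = 2,
                       min_samples = 50, max_samples = 4000, rhat_tol = 1.05)
  hs <- run_multichain(prior = head_prior(sigma = 20, init_rotation = 0),
                       config = cfg, f_eval = f_eval, seed = 3)
  expect_true(hs$converged)
  # pooled posterior mean within Monte Carlo error of the analytic value
  expect_lt(abs(mean(hs$samples$tx)), 1.0)

  # an infinite tolerance stops right after warm-up
  cfg2 <- search_config(proposal_sd = c(2.4 * tau, 0, 0, 0, 0, 0), n_chains = 2,
                        min_samples = 50, max_samples = 4000, rhat_tol = Inf)
  hs2 <- run_multichain(prior = head_prior(sigma = 20, init_rotation = 0),
                        config = cfg2, f_eval = f_eval, seed = 3)
  expect_equal(nrow(hs2$chains[[1]]$trace), 50L)

  # identical chain seeds give identical traces
  hs3 <- run_multichain(prior = head_prior(sigma = 20, init_rotation = 0),
                        config = cfg2, f_eval = f_eval, seed = 3,
                        chain_seeds = c(8, 8))
  expect_identical(hs3$chains[[1]]$trace, hs3$chains[[2]]$trace)

  # same master seed reruns identically
  hs4 <- run_multichain(prior = head_prior(sigma = 20, init_rotation = 0),
                        config = cfg, f_eval = f_eval, seed = 3)
  expect_identical(hs$chains[[1]]$trace, hs4$chains[[1]]$trace)

  # pooled samples are strictly the second halves
  n <- nrow(hs2$chains[[1]]$trace)
  expect_equal(nrow(hs2$samples), 2 * (n - floor(n / 2)))
  expect_true(all(hs2$samples$iteration > floor(n / 2)))
})
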