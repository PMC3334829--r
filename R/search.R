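#' Uniform prior over head position
#'
#' The worst-case co-registration prior: translation uniform on
#' `[-sigma, sigma]` per axis (mm) and rotation free over the configured
#' range (degrees). Chains are initialised with rotations drawn within
#' `init_rotation` degrees of the reference orientation, mirroring the
#' simulation design in which the starting orientation is known to within
#' about 15 degrees.
#'
#' @param sigma Translation half-width, mm (default 20).
#' @param rotation_range Rotation half-range used as prior support, degrees
#'   (default 180: free rotation).
#' @param init_rotation Half-range of the initial rotation draw, degrees
#'   (default 15).
#' @return Object of class `head_prior`.
#' @export
head_prior <- function(sigma = 20, rotation_range = 180, init_rotation = 15) {
  stopifnot(sigma >= 0, rotation_range >= 0, rotation_range <= 180,
            init_rotation >= 0, init_rotation <= rotation_range || rotation_range == 0)
  structure(list(sigma = sigma, rotation_range = rotation_range,
                 init_rotation = init_rotation),
            class = "head_prior")
}

#' Draw an initial head hypothesis from the prior
#'
#' Translation uniform on the prior box; rotation uniform within the
#' initialisation range.
#'
#' @param prior A [head_prior()].
#' @return A [rigid_body_params()].
#' @export
sample_prior <- function(prior) {
  stopifnot(inherits(prior, "head_prior"))
  tr <- if (prior$sigma > 0) runif(3, -prior$sigma, prior$sigma) else c(0, 0, 0)
  ro <- if (prior$init_rotation > 0) runif(3, -prior$init_rotation, prior$init_rotation) else c(0, 0, 0)
  rigid_body_params(tr, ro)
}

#' Prior density (unnormalised) of a head hypothesis
#'
#' 1 inside the support (translation box, rotation range), 0 outside.
#'
#' @param h A [rigid_body_params()].
#' @param prior A [head_prior()].
#' @return 0 or 1.
#' @export
prior_density <- function(h, prior) {
  intr <- all(abs(h$translation) <= prior$sigma)
  inro <- all(abs(wrap_angle(h$rotation)) <= prior$rotation_range)
  as.numeric(intr && inro)
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Gaussian random-walk proposal
#'
#' Perturbs each of the six degrees of freedom by independent Gaussian noise.
#' The kernel is symmetric, so the acceptance ratio needs no proposal
#' correction.
#'
#' @param h_prev Current [rigid_body_params()].
#' @param proposal_sd Per-axis standard deviation: a scalar applied to all
#'   six coordinates (mm for translation, degrees for rotation) or a
#'   6-vector `(tx, ty, tz, rx, ry, rz)`. Default `2.4 / sqrt(6)`.
#' @return A proposed [rigid_body_params()].
#' @export
propose <- function(h_prev, proposal_sd = 2.4 / sqrt(6)) {
  stopifnot(inherits(h_prev, "rigid_body_params"))
  sd6 <- if (length(proposal_sd) == 1) rep(proposal_sd, 6) else proposal_sd
  stopifnot(length(sd6) == 6, all(sd6 >= 0))
  eps <- rnorm(6, 0, sd6)
  rigid_body_params(h_prev$translation + eps[1:3],
                    wrap_angle(h_prev$rotation + eps[4:6]),
                    origin = h_prev$origin)
}

#' Metropolis acceptance ratio from free energies
#'
#' `r = exp(F_new - F_old) * prior_new / prior_old`. With the flat prior the
#' ratio reduces to the exponentiated log-evidence difference; proposals
#' outside the prior support get `r = 0`.
#'
#' @param F_new,F_old Free energies (log evidences) of the proposed and
#'   current head.
#' @param prior_new,prior_old Prior densities (both 1 under the flat prior
#'   inside its support).
#' @return Non-negative acceptance ratio.
#' @export
acceptance_ratio <- function(F_new, F_old, prior_new = 1, prior_old = 1) {
  stopifnot(is.finite(F_old), prior_new >= 0, prior_old >= 0)
  if (prior_old == 0 && prior_new == 0)
    stop("both prior densities are zero; the chain state is outside the prior support",
         call. = FALSE)
  if (prior_new == 0 || !is.finite(F_new)) return(0)
  exp(F_new - F_old) * prior_new / prior_old
}

#' Metropolis accept/reject decision
#'
#' Accept when `r > 1`; otherwise accept with probability `r` (compare with
#' a uniform draw). Downhill moves are thus possible, which lets the chain
#' escape local maxima of the evidence surface.
#'
#' @param r Acceptance ratio, non-negative.
#' @return Logical.
#' @export
metropolis_decide <- function(r) {
  stopifnot(r >= 0)
  if (r > 1) TRUE else r > runif(1)
}

#' Search configuration
#'
#' @param proposal_sd Per-axis proposal standard deviation (scalar or
#'   6-vector, zero entries pinning an axis; default `2.4/sqrt(6)`,
#'   mm / degrees).
#' @param n_chains Number of parallel chains `G` (default 4; at least 2 for
#'   the convergence rule).
#' @param min_samples Warm-up: samples per chain before the convergence rule
#'   is consulted (default 100).
#' @param rhat_tol Stop when the potential scale reduction on `F` falls to
#'   or below this value (default 1.1).
#' @param max_samples Per-chain cap (default 300).
#' @param sqrt_rhat Report the square root of the variance ratio instead of
#'   the plain ratio (default `FALSE`, matching the stopping rule used
#'   here).
#' @return List of settings, class `search_config`.
#' @export
search_config <- function(proposal_sd = 2.4 / sqrt(6), n_chains = 4,
                          min_samples = 100, rhat_tol = 1.1,
                          max_samples = 300, sqrt_rhat = FALSE) {
  stopifnot(all(proposal_sd >= 0), any(proposal_sd > 0), n_chains >= 1,
            min_samples >= 4, max_samples >= min_samples, rhat_tol > 0)
  structure(list(proposal_sd = proposal_sd, n_chains = n_chains,
                 min_samples = min_samples, rhat_tol = rhat_tol,
                 max_samples = max_samples, sqrt_rhat = sqrt_rhat),
            class = "search_config")
}

#' Bundle the fixed inputs of a head search
#'
#' Projects the data once into the eigenmode basis of the reference-head
#' lead field; every subsequent head hypothesis is evaluated in that fixed
#' basis so the (reduced) data never change during the search.
#'
#' @param Y Sensor data (`n_sensors x n_time`).
#' @param mesh Reference-head [cortical_mesh()].
#' @param sensors A [sensor_array()].
#' @param fids Reference [fiducial_set()].
#' @param components An `msp_components` set (head-independent).
#' @param n_modes Number of eigenmodes kept (default 100).
#' @param projector Optionally a prebuilt [build_projector()]; computed from
#'   the reference lead field when `NULL`.
#' @param inversion An [inversion_config()].
#' @return Object of class `search_data`.
#' @export
search_data <- function(Y, mesh, sensors, fids, components, n_modes = 100,
                        projector = NULL, inversion = inversion_config()) {
  L0 <- compute_lead_field(mesh, sensors, head_id = "reference")
  if (is.null(projector)) projector <- build_projector(L0, m = n_modes)
  Y_proj <- project_modes(projector, Y)
  # reference-head fit; its hyperparameters are the common warm start for
  # every head hypothesis (fixed, so F stays a function of h alone)
  fit0 <- msp_invert(Y_proj, project_modes(projector, L0), components,
                     config = inversion, compute_sources = FALSE)
  structure(list(
    Y = as.matrix(Y), Y_proj = Y_proj,
    mesh = mesh, sensors = sensors, fids = fids,
    components = components, projector = projector,
    inversion = inversion,
    ref_fit = fit0,
    ref_init = list(w_source = fit0$w_source, sigma2_noise = fit0$sigma2_noise)
  ), class = "search_data")
}

# Free-energy evaluator over head hypotheses, with a cache shared across
# chains (the inversion is deterministic given h).
make_f_evaluator <- function(data, cache = new.env(parent = emptyenv())) {
  force(data)
  function(h) {
    key <- params_key(h)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- tryCatch({
      th <- apply_head_transform(data$mesh, data$fids, h)
      L <- compute_lead_field(th$mesh, data$sensors, head_id = key)
      Lp <- project_modes(data$projector, L)
      fit <- msp_invert(data$Y_proj, Lp, data$components,
                        config = data$inversion, compute_sources = FALSE,
                        init = data$ref_init)
      list(F = fit$F, fit = fit, ok = TRUE)
    }, error = function(e) list(F = -Inf, fit = NULL, ok = FALSE, message = conditionMessage(e)))
    cache[[key]] <- out
    out
  }
}

#' Run one Metropolis chain over head positions
#'
#' Implements the search loop: draw `h_0` from the prior, then repeatedly
#' propose a Gaussian perturbation of the six rigid-body coordinates,
#' re-derive the lead field for the moved head, re-fit the MSP model, and
#' accept or reject on the exponentiated free-energy difference weighted by
#' the prior. Rejected proposals repeat the previous state, so the trace
#' length equals the number of iterations. Forward-model failures at a
#' proposal are treated as zero-evidence (`r = 0`).
#'
#' @param data A [search_data()] bundle, or `NULL` when `f_eval` is given.
#' @param prior A [head_prior()].
#' @param config A [search_config()].
#' @param n_samples Chain length (defaults to `config$max_samples`).
#' @param f_eval Optional evaluator `function(h) list(F = ...)` replacing
#'   the MSP free energy (used for analytic-target validation).
#' @param seed Optional integer seed for this chain.
#' @param init Optional [rigid_body_params()] overriding the prior draw.
#' @return Object of class `metropolis_chain`: a list with `trace` (a
#'   tibble: iteration, six coordinates, `F`, `accepted`), `cache`, and the
#'   final state.
#' @export
run_chain <- function(data = NULL, prior = head_prior(), config = search_config(),
                      n_samples = config$max_samples, f_eval = NULL, seed = NULL,
                      init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(f_eval)) {
    stopifnot(inherits(data, "search_data"))
    f_eval <- make_f_evaluator(data)
  }
  st <- chain_init(prior, f_eval, init = init)
  st <- chain_extend(st, n_samples - 1L, prior, config, f_eval)
  chain_finalize(st)
}

chain_init <- function(prior, f_eval, init = NULL) {
  h <- init %||% sample_prior(prior)
  ev <- f_eval(h)
  tries <- 0L
  while (!is.finite(ev$F) && is.null(init) && tries < 20L) {
    h <- sample_prior(prior); ev <- f_eval(h); tries <- tries + 1L
  }
  if (!is.finite(ev$F))
    stop("could not find a starting head with finite free energy", call. = FALSE)
  list(h = h, F = ev$F, params = matrix(c(h$translation, h$rotation), 1, 6),
       Fs = ev$F, acc = TRUE)
}

chain_extend <- function(st, n_new, prior, config, f_eval) {
  if (n_new <= 0) return(st)
  k0 <- nrow(st$params)
  P <- rbind(st$params, matrix(NA_real_, n_new, 6))
  Fs <- c(st$Fs, rep(NA_real_, n_new))
  acc <- c(st$acc, rep(NA, n_new))
  h <- st$h; Fcur <- st$F
  for (k in seq_len(n_new) + k0) {
    hp <- propose(h, config$proposal_sd)
    p_new <- prior_density(hp, prior)
    accept <- FALSE
    if (p_new > 0) {
      ev <- f_eval(hp)
      r <- acceptance_ratio(ev$F, Fcur, p_new, prior_density(h, prior))
      accept <- metropolis_decide(r)
      if (accept) { h <- hp; Fcur <- ev$F }
    } else {
      runif(1)  # keep the RNG stream aligned whether or not we evaluate
    }
    P[k, ] <- c(h$translation, h$rotation)
    Fs[k] <- Fcur
    acc[k] <- accept
  }
  list(h = h, F = Fcur, params = P, Fs = Fs, acc = acc)
}

chain_finalize <- function(st) {
  colnames(st$params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  trace <- tibble::as_tibble(st$params)
  trace <- dplyr::mutate(trace, iteration = dplyr::row_number(), F = st$Fs,
                         accepted = st$acc)
  trace <- dplyr::relocate(trace, "iteration")
  structure(list(trace = trace, state = st$h, F = st$F), class = "metropolis_chain")
}

#' @export
print.metropolis_chain <- function(x, ...) {
  cat(sprintf("<metropolis_chain> %d samples, acceptance %.2f, final F = %.3f\n",
              nrow(x$trace), mean(x$trace$accepted), x$F))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic on free-energy traces
#'
#' Computed on the second half of each chain (the first half is burn-in):
#' between-chain variance `B = n/(G-1) * sum_g (Fbar_g - Fbar)^2`,
#' within-chain variance `Z = mean_g var_g`, pooled marginal posterior
#' variance `var(F|Y) = (n-1)/n Z + B/n`, and the ratio
#' `Rhat = var(F|Y) / Z`. Values near 1 indicate that the chains sample the
#' same density. When all retained values are identical (`Z = 0`) the ratio
#' is undefined and the diagnostic reports convergence with a flag.
#'
#' @param chains A list of numeric vectors (full `F` traces, halved
#'   internally), a list of `metropolis_chain` objects, or a matrix with one
#'   chain per column.
#' @param sqrt_rhat Return `sqrt` of the ratio (default `FALSE`).
#' @param halve Use only the second half of each trace (default `TRUE`).
#' @return Object of class `convergence_diagnostic` with fields `n`, `G`,
#'   `chain_means`, `grand_mean`, `B`, `Z`, `var_post`, `rhat`,
#'   `degenerate`.
#' @export
gelman_rubin <- function(chains, sqrt_rhat = FALSE, halve = TRUE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  chains <- lapply(chains, function(ch)
    if (inherits(ch, "metropolis_chain")) ch$trace$F else as.numeric(ch))
  G <- length(chains)
  if (G < 2) stop("at least two chains are required", call. = FALSE)
  halves <- lapply(chains, function(f) {
    n <- length(f)
    if (halve) f[(floor(n / 2) + 1):n] else f
  })
  n <- min(lengths(halves))
  if (n < 2) stop("each chain must retain at least 2 samples", call. = FALSE)
  halves <- lapply(halves, function(f) tail(f, n))
  means <- vapply(halves, mean, 0)
  grand <- mean(means)
  B <- n / (G - 1) * sum((means - grand)^2)
  Z <- mean(vapply(halves, function(f) sum((f - mean(f))^2) / (n - 1), 0))
  var_post <- (n - 1) / n * Z + B / n
  degenerate <- Z <= 0
  rhat <- if (degenerate) NA_real_ else var_post / Z
  if (!degenerate && sqrt_rhat) rhat <- sqrt(rhat)
  structure(list(n = n, G = G, chain_means = means, grand_mean = grand,
                 B = B, Z = Z, var_post = var_post, rhat = rhat,
                 degenerate = degenerate, sqrt_rhat = sqrt_rhat),
            class = "convergence_diagnostic")
}

#' @export
print.convergence_diagnostic <- function(x, ...) {
  cat(sprintf("<convergence_diagnostic> G = %d chains, n = %d retained: Rhat = %s%s\n",
              x$G, x$n, if (x$degenerate) "degenerate (all equal)" else sprintf("%.4f", x$rhat),
              if (x$sqrt_rhat) " (sqrt)" else ""))
  invisible(x)
}

#' @export
glance.convergence_diagnostic <- function(x, ...) {
  tibble::tibble(G = x$G, n = x$n, B = x$B, Z = x$Z, var_post = x$var_post,
                 rhat = x$rhat, degenerate = x$degenerate)
}

#' Multi-chain Metropolis search with convergence-gated stopping
#'
#' Runs `G` chains from independent prior draws, advancing them in lockstep.
#' After every chain has at least `min_samples`, the Gelman-Rubin ratio on
#' the free-energy traces is evaluated after each sweep and the search stops
#' when it reaches `rhat_tol` (or `max_samples` is hit, in which case a
#' non-convergence flag is set). The pooled second halves of all chains form
#' the posterior sample of head positions.
#'
#' @inheritParams run_chain
#' @param seed Master seed; chain `g` uses `seed + g` unless `chain_seeds`
#'   is given.
#' @param chain_seeds Optional explicit per-chain seeds (e.g. identical
#'   seeds reproduce identical chains).
#' @param rhat_every Check the diagnostic every this many sweeps after
#'   warm-up (default 10; checking each sweep is exact but slower).
#' @return Object of class `head_search` with fields `chains` (list of
#'   `metropolis_chain`), `diagnostic`, `rhat_history` (tibble), `samples`
#'   (pooled second-half posterior tibble), `converged`, `cache`.
#' @export
run_multichain <- function(data = NULL, prior = head_prior(), config = search_config(),
                           f_eval = NULL, seed = 1, chain_seeds = NULL,
                           rhat_every = 10) {
  G <- config$n_chains
  if (G < 2) stop("convergence checking needs at least 2 chains", call. = FALSE)
  if (is.null(f_eval)) {
    stopifnot(inherits(data, "search_data"))
    cache <- new.env(parent = emptyenv())
    f_eval <- make_f_evaluator(data, cache)
  } else cache <- NULL
  chain_seeds <- chain_seeds %||% (seed + seq_len(G))
  stopifnot(length(chain_seeds) == G)

  # per-chain RNG streams: save/restore .Random.seed around each advance
  states <- vector("list", G)
  rngs <- vector("list", G)
  for (g in seq_len(G)) {
    set.seed(chain_seeds[g])
    states[[g]] <- chain_init(prior, f_eval)
    rngs[[g]] <- get(".Random.seed", envir = globalenv())
  }
  advance <- function(g, n_new) {
    assign(".Random.seed", rngs[[g]], envir = globalenv())
    states[[g]] <<- chain_extend(states[[g]], n_new, prior, config, f_eval)
    rngs[[g]] <<- get(".Random.seed", envir = globalenv())
  }
  for (g in seq_len(G)) advance(g, config$min_samples - 1L)

  history <- list()
  repeat {
    d <- gelman_rubin(lapply(states, `[[`, "Fs"))
    n_now <- nrow(states[[1]]$params)
    history[[length(history) + 1]] <- tibble::tibble(
      samples_per_chain = n_now, rhat = d$rhat, B = d$B, Z = d$Z,
      degenerate = d$degenerate
    )
    converged <- d$degenerate || (!is.na(d$rhat) && d$rhat <= config$rhat_tol)
    if (converged || n_now >= config$max_samples) break
    step <- min(rhat_every, config$max_samples - n_now)
    for (g in seq_len(G)) advance(g, step)
  }

  chains <- lapply(states, chain_finalize)
  samples <- pool_posterior_samples(chains)
  structure(list(chains = chains, diagnostic = d,
                 rhat_history = dplyr::bind_rows(history),
                 samples = samples, converged = converged,
                 cache = cache),
            class = "head_search")
}

#' Pool post-burn-in head samples from a set of chains
#'
#' Strictly the second half of each chain is retained (the first half is the
#' burn-in period and is discarded).
#'
#' @param chains List of `metropolis_chain` objects.
#' @return Tibble with chain id, iteration, the six coordinates and `F`.
#' @export
pool_posterior_samples <- function(chains) {
  purrr::imap_dfr(chains, function(ch, g) {
    tr <- ch$trace
    n <- nrow(tr)
    dplyr::mutate(tr[(floor(n / 2) + 1):n, ], chain = g, .before = 1)
  })
}

#' @export
print.head_search <- function(x, ...) {
  cat(sprintf("<head_search> %d chains x %d samples; %s\n",
              length(x$chains), nrow(x$chains[[1]]$trace),
              if (x$converged) sprintf("converged (Rhat = %.4f)",
                                       x$diagnostic$rhat %||% NA_real_)
              else "not converged"))
  cat(sprintf("  %d pooled posterior samples of head position\n", nrow(x$samples)))
  invisible(x)
}

#' @export
glance.head_search <- function(x, ...) {
  tibble::tibble(
    n_chains = length(x$chains),
    samples_per_chain = nrow(x$chains[[1]]$trace),
    n_posterior = nrow(x$samples),
    rhat = x$diagnostic$rhat,
    converged = x$converged,
    acceptance = mean(vapply(x$chains, function(ch) mean(ch$trace$accepted), 0))
  )
}

#' @export
tidy.head_search <- function(x, ...) {
  purrr::imap_dfr(x$chains, function(ch, g)
    dplyr::mutate(ch$trace, chain = g, .before = 1))
}
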