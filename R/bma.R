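#' Occam's window over posterior head samples
#'
#' Retains only samples whose log evidence is within `window` of the best
#' sample: `F >= max(F) - window`. Filtering never increases the sample
#' count; `window = 0` keeps only the argmax (and exact ties),
#' `window = Inf` keeps everything.
#'
#' @param samples Tibble of posterior samples carrying an `F` column (e.g.
#'   the `samples` element of a [run_multichain()] result), or a
#'   `head_search`.
#' @param window Log-evidence window, `>= 0` (default 3, a conventional
#'   "strong evidence" cut).
#' @return The filtered tibble.
#' @export
occam_window <- function(samples, window = 3) {
  if (inherits(samples, "head_search")) samples <- samples$samples
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window < 0)
    stop("window must be a non-negative scalar", call. = FALSE)
  dplyr::filter(samples, .data$F >= max(.data$F) - window)
}

row_to_params <- function(row) {
  rigid_body_params(c(row$tx, row$ty, row$tz), c(row$rx, row$ry, row$rz))
}

#' Bayesian model averaging over posterior head samples
#'
#' Approximates the head-marginalised source posterior by Monte Carlo: for
#' each of `T` draws, (a) pick a head sample uniformly from the pooled
#' post-burn-in Metropolis samples (sample frequency is the posterior
#' weight), (b) take that head's posterior source mean and per-dipole
#' variances, (c) draw a Gaussian source realisation. Summaries are formed
#' from the draws.
#'
#' In the default `"power"` mode the per-draw time-integrated power map is
#' sampled exactly from its scaled noncentral chi-square distribution
#' (`sum_t (Jhat_vt + sigma_v eps)^2`), which is what the peak-location
#' posterior needs, and the averaged current `Jbar` is the exact
#' (Rao-Blackwellised) mixture mean over the picked heads. The `"current"`
#' mode draws `J` elementwise and additionally returns the per-vertex,
#' per-sample mean and variance of the draws; use it for small problems.
#'
#' @param search A [run_multichain()] result (its cache supplies the fitted
#'   hyperparameters per visited head).
#' @param data The [search_data()] used for the search.
#' @param n_draws Number of BMA iterations `T` (default 10000).
#' @param mode `"power"` or `"current"`.
#' @param occam Occam-window width applied to the pooled samples before
#'   averaging (default 3 log-evidence units, a conventional "strong
#'   evidence" cut; `NULL` applies no filter).
#' @param keep_draws Store the per-draw power maps (`T x n_dipoles`; needed
#'   for masked peak posteriors).
#' @return Object of class `bma_result`.
#' @export
bma_average <- function(search, data, n_draws = 10000, mode = c("power", "current"),
                        occam = 3, keep_draws = FALSE) {
  mode <- match.arg(mode)
  if (tibble::is_tibble(search) || is.data.frame(search))
    search <- structure(list(samples = tibble::as_tibble(search), cache = NULL),
                        class = "head_search")
  stopifnot(inherits(search, "head_search"), inherits(data, "search_data"),
            n_draws >= 1)
  samples <- search$samples
  if (!is.null(occam)) samples <- occam_window(samples, occam)
  S <- nrow(samples)
  if (S < 1) stop("empty posterior sample set", call. = FALSE)

  f_eval <- make_f_evaluator(data, search$cache %||% new.env(parent = emptyenv()))
  keys <- vapply(seq_len(S), function(i) params_key(row_to_params(samples[i, ])), "")
  pick <- sample.int(S, n_draws, replace = TRUE)
  counts <- table(factor(keys[pick], levels = unique(keys)))
  counts <- counts[counts > 0]

  nd <- data$components$n_dipoles
  nt <- ncol(data$Y_proj)
  sum_p <- numeric(nd); sumsq_p <- numeric(nd)
  tally <- numeric(nd)
  Jbar <- matrix(0, nd, nt)
  sum_J <- NULL; sumsq_J <- NULL
  mean_dsig <- numeric(nd)
  draws <- if (keep_draws) matrix(NA_real_, n_draws, nd) else NULL
  peak_idx <- integer(n_draws)
  offset <- 0L

  for (key in names(counts)) {
    n_k <- as.integer(counts[[key]])
    i <- match(key, keys)
    fit <- f_eval(row_to_params(samples[i, ]))$fit
    if (is.null(fit)) stop("inversion failed for a posterior head sample", call. = FALSE)
    fit <- compute_sources(fit)
    Jk <- fit$Jhat; sk2 <- fit$diag_Sigma_J
    Pk <- rowSums(Jk^2)
    wk <- n_k / n_draws
    mean_dsig <- mean_dsig + wk * sk2   # mixture-averaged per-dipole variance
    if (mode == "power") {
      Jbar <- Jbar + wk * Jk
      pos <- sk2 > 0
      Pd <- matrix(rep(Pk, each = n_k), n_k, nd)
      if (any(pos)) {
        ncp <- Pk[pos] / sk2[pos]
        Pd[, pos] <- rchisq(n_k * sum(pos), df = nt, ncp = rep(ncp, each = n_k)) *
          rep(sk2[pos], each = n_k)
      }
    } else {
      if (is.null(sum_J)) { sum_J <- matrix(0, nd, nt); sumsq_J <- matrix(0, nd, nt) }
      Pd <- matrix(NA_real_, n_k, nd)
      sdv <- sqrt(sk2)
      for (t in seq_len(n_k)) {
        Jt <- Jk + sdv * matrix(rnorm(nd * nt), nd, nt)
        sum_J <- sum_J + Jt; sumsq_J <- sumsq_J + Jt^2
        Pd[t, ] <- rowSums(Jt^2)
      }
    }
    sum_p <- sum_p + colSums(Pd)
    sumsq_p <- sumsq_p + colSums(Pd^2)
    am <- max.col(Pd, ties.method = "first")
    tally <- tally + tabulate(am, nbins = nd)
    peak_idx[offset + seq_len(n_k)] <- am
    if (keep_draws) draws[offset + seq_len(n_k), ] <- Pd
    offset <- offset + n_k
  }

  mean_power <- sum_p / n_draws
  var_power <- pmax(sumsq_p / n_draws - mean_power^2, 0)
  if (mode == "current") {
    Jbar <- sum_J / n_draws
    var_J <- pmax(sumsq_J / n_draws - Jbar^2, 0)
  } else var_J <- NULL
  peak_mass <- tally / n_draws
  structure(list(
    mode = mode, n_draws = n_draws,
    mean_power = mean_power, var_power = var_power,
    Jbar = Jbar, var_J = var_J,
    mean_diag_Sigma_J = mean_dsig,
    peak_mass = peak_mass, peak_draws = peak_idx,
    power_draws = draws,
    n_heads = length(counts),
    n_posterior_samples = S
  ), class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("<bma_result> %d draws over %d distinct head models (%s mode)\n",
              x$n_draws, x$n_heads, x$mode))
  top <- order(x$peak_mass, decreasing = TRUE)[1:min(3, length(x$peak_mass))]
  cat("  top peak vertices:",
      paste(sprintf("%d (%.2f)", top, x$peak_mass[top]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.bma_result <- function(x, ...) {
  tibble::tibble(
    vertex = seq_along(x$mean_power),
    mean_power = x$mean_power,
    var_power = x$var_power,
    peak_mass = x$peak_mass
  )
}

#' @export
glance.bma_result <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, n_heads = x$n_heads, mode = x$mode,
    peak_vertex = which.max(x$peak_mass),
    peak_mass = max(x$peak_mass)
  )
}

#' Posterior over the location of peak source activity
#'
#' For each BMA draw the maximal-power vertex (optionally restricted to a
#' mask of vertices) is located; the normalised tallies form a discrete
#' posterior over peak location and the smallest vertex set holding at least
#' `level` probability is the confidence set.
#'
#' @param x A [bma_average()] result, or a `T x n_dipoles` matrix of power
#'   draws.
#' @param mask Optional integer vector of vertex indices to restrict the
#'   search to (requires stored draws when `x` is a `bma_result`).
#' @param level Confidence level (default 0.95).
#' @return List with `mass` (tibble vertex/mass), `confidence_set` (vertex
#'   indices, highest mass first), `coverage`, `level`.
#' @export
peak_location_posterior <- function(x, mask = NULL, level = 0.95) {
  if (!is.null(mask) && length(mask) == 0) stop("empty mask", call. = FALSE)
  if (inherits(x, "bma_result")) {
    if (is.null(mask)) {
      mass <- x$peak_mass
    } else {
      if (is.null(x$power_draws))
        stop("masked peak posteriors need bma_average(..., keep_draws = TRUE)", call. = FALSE)
      sub <- x$power_draws[, mask, drop = FALSE]
      am <- mask[max.col(sub, ties.method = "first")]
      mass <- tabulate(am, nbins = length(x$peak_mass)) / nrow(sub)
    }
  } else {
    P <- as.matrix(x)
    cols <- mask %||% seq_len(ncol(P))
    am <- cols[max.col(P[, cols, drop = FALSE], ties.method = "first")]
    mass <- tabulate(am, nbins = ncol(P)) / nrow(P)
  }
  ord <- order(mass, decreasing = TRUE)
  cs <- ord[seq_len(which(cumsum(mass[ord]) >= level)[1])]
  list(
    mass = tibble::tibble(vertex = seq_along(mass), mass = mass),
    confidence_set = cs,
    coverage = sum(mass[cs]),
    level = level
  )
}

#' Posterior distribution of the fiducial locations
#'
#' Applies every sampled head transformation to the reference fiducials and
#' summarises the resulting point clouds. The per-fiducial posterior mean is
#' the recommended head-location summary (it is more robust than the
#' maximum-evidence sample).
#'
#' @param samples Pooled posterior samples (tibble with `tx..rz`), or a
#'   `head_search`.
#' @param fids Reference [fiducial_set()].
#' @return Object of class `fiducial_posterior`: `samples` (long tibble),
#'   `mean` (named list of 3-vectors), `cov` (named list of 3x3 matrices).
#' @export
fiducial_posterior <- function(samples, fids) {
  if (inherits(samples, "head_search")) samples <- samples$samples
  stopifnot(inherits(fids, "fiducial_set"), nrow(samples) >= 1)
  pts <- rbind(fids$nasion, fids$left_ear, fids$right_ear)
  nm <- c("nasion", "left_ear", "right_ear")
  clouds <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    h <- row_to_params(samples[i, ])
    h <- rigid_body_params(h$translation, h$rotation, origin = ear_midpoint(fids))
    tp <- rigid_body_transform(pts, h)
    tibble::tibble(sample = i, fiducial = nm, x = tp[, 1], y = tp[, 2], z = tp[, 3])
  })
  means <- lapply(nm, function(f) {
    sub <- clouds[clouds$fiducial == f, c("x", "y", "z")]
    unname(colMeans(as.matrix(sub)))
  })
  covs <- lapply(nm, function(f) {
    sub <- as.matrix(clouds[clouds$fiducial == f, c("x", "y", "z")])
    if (nrow(sub) > 1) stats::cov(sub) else matrix(0, 3, 3)
  })
  names(means) <- names(covs) <- nm
  structure(list(samples = clouds, mean = means, cov = covs, reference = fids),
            class = "fiducial_posterior")
}

#' @export
print.fiducial_posterior <- function(x, ...) {
  cat("<fiducial_posterior> posterior means (mm):\n")
  for (nm in names(x$mean))
    cat(sprintf("  %-9s % .2f % .2f % .2f\n", nm, x$mean[[nm]][1], x$mean[[nm]][2], x$mean[[nm]][3]))
  invisible(x)
}

#' @export
tidy.fiducial_posterior <- function(x, ...) {
  purrr::imap_dfr(x$mean, function(m, nm) {
    s <- sqrt(diag(x$cov[[nm]]))
    tibble::tibble(fiducial = nm, x = m[1], y = m[2], z = m[3],
                   sd_x = s[1], sd_y = s[2], sd_z = s[3])
  })
}

#' Mean fiducial localisation error
#'
#' Average Euclidean distance (mm) between the posterior-mean fiducials and
#' a reference truth.
#'
#' @param fidpost A [fiducial_posterior()].
#' @param true_fids The true [fiducial_set()].
#' @return Scalar mm.
#' @export
fiducial_error <- function(fidpost, true_fids) {
  stopifnot(inherits(fidpost, "fiducial_posterior"), inherits(true_fids, "fiducial_set"))
  tru <- list(nasion = true_fids$nasion, left_ear = true_fids$left_ear,
              right_ear = true_fids$right_ear)
  mean(vapply(names(tru), function(nm)
    sqrt(sum((fidpost$mean[[nm]] - tru[[nm]])^2)), 0))
}
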