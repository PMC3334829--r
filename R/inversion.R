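#' Gaussian posterior mean of the sources
#'
#' For the linear model `Y = L J + e` with priors `J ~ N(0, Q)` and
#' `e ~ N(0, R)`, the posterior mean is
#' `Jhat = Q L' (R + L Q L')^-1 Y`, the classical Gaussian-linear inverse
#' solution. The inverse operator `M = Q L' (R + L Q L')^-1` is returned for
#' reuse.
#'
#' @param Y Data matrix (`n_sensors x n_time`).
#' @param L Gain matrix (`n_sensors x n_dipoles`) or `lead_field`.
#' @param Q Prior source covariance (`n_dipoles x n_dipoles`).
#' @param R Sensor noise covariance (`n_sensors x n_sensors`).
#' @return List with `Jhat` (`n_dipoles x n_time`) and `M`
#'   (`n_dipoles x n_sensors`).
#' @export
posterior_mean <- function(Y, L, Q, R) {
  L <- lf_matrix(L)
  Y <- as.matrix(Y)
  Cy <- R + L %*% Q %*% t(L)
  ch <- tryCatch(chol(Cy), error = function(e)
    stop("R + L Q L' is not positive definite (ill-conditioned model covariance)",
         call. = FALSE))
  Cinv <- chol2inv(ch)
  M <- Q %*% t(L) %*% Cinv
  list(Jhat = M %*% Y, M = M)
}

#' Gaussian posterior covariance of the sources
#'
#' `Sigma_J = Q - Q L' (R + L Q L')^-1 L Q`, usable for error bars on the
#' reconstruction. With `diagonal = TRUE` only the per-dipole variances are
#' returned (the pipeline default).
#'
#' @inheritParams posterior_mean
#' @param diagonal Return only `diag(Sigma_J)`.
#' @return Matrix `Sigma_J`, or a vector of variances if `diagonal`.
#' @export
posterior_covariance <- function(L, Q, R, diagonal = FALSE) {
  L <- lf_matrix(L)
  Cy <- R + L %*% Q %*% t(L)
  ch <- tryCatch(chol(Cy), error = function(e)
    stop("R + L Q L' is not positive definite (ill-conditioned model covariance)",
         call. = FALSE))
  Cinv <- chol2inv(ch)
  QLt <- Q %*% t(L)
  if (diagonal) {
    v <- diag(Q) - rowSums((QLt %*% Cinv) * QLt)
    pmax(v, 0)
  } else {
    S <- Q - QLt %*% Cinv %*% t(QLt)
    (S + t(S)) / 2
  }
}

#' Log-posterior over sources (up to a constant)
#'
#' `Psi = -(LJ - Y)' R^-1 (LJ - Y) - J' Q^-1 J`, summed over time samples.
#' The posterior mean maximises it.
#'
#' @param J Source matrix (`n_dipoles x n_time`).
#' @inheritParams posterior_mean
#' @return Scalar.
#' @export
log_posterior_psi <- function(J, Y, L, Q, R) {
  L <- lf_matrix(L)
  E <- L %*% J - Y
  qj <- solve(Q, J)
  -sum(E * solve(R, E)) - sum(J * qj)
}

#' Sensor noise model
#'
#' Uniform white noise on all sensors, `R = exp(lambda) I`: the single
#' log-variance hyperparameter is exponentiated to enforce positivity.
#'
#' @param lambda Sensor log-variance.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(lambda = 0) {
  stopifnot(is.finite(lambda))
  structure(list(lambda = lambda), class = "noise_model")
}

#' Hyperparameter state
#'
#' Posterior (`mu`, `Sigma_lambda`) and prior (`nu`, `C_lambda = alpha I`)
#' of the log component weights. By convention the first element, named
#' `"noise"`, is the sensor log-variance; the remaining elements match the
#' covariance components in order.
#'
#' @param mu,nu Numeric vectors (posterior / prior means of the log
#'   weights).
#' @param alpha Prior variance of each hyperparameter (`C_lambda = alpha I`;
#'   default 256, "large" = uninformative).
#' @param Sigma_lambda Posterior covariance matrix (defaults to `C_lambda`).
#' @return Object of class `msp_hyper`.
#' @export
msp_hyper <- function(mu, nu = rep(0, length(mu)), alpha = 256, Sigma_lambda = NULL) {
  k <- length(mu)
  stopifnot(length(nu) == k, alpha > 0)
  if (is.null(Sigma_lambda)) Sigma_lambda <- diag(alpha, k)
  Sigma_lambda <- as.matrix(Sigma_lambda)
  stopifnot(all(dim(Sigma_lambda) == k))
  structure(list(mu = mu, nu = nu, alpha = alpha, Sigma_lambda = Sigma_lambda),
            class = "msp_hyper")
}

#' Variational free energy of a fitted model
#'
#' `F = accuracy - complexity`. The accuracy is the Gaussian log-density of
#' the data under the model covariance `C_Y = R + L Q L'`:
#' `accuracy = -1/2 tr(C_Y^-1 Y Y') - (N_t/2) log|C_Y| - (N_t m / 2) log 2pi`.
#' The complexity penalises hyperparameters that move away from their prior:
#' `complexity = 1/2 e' C_lambda^-1 e + 1/2 log(|C_lambda| / |Sigma_lambda|)`
#' with `e = mu - nu`. Adding spurious structure to `C_Y` that worsens the
#' fit, or recruiting more hyperparameters, lowers `F`.
#'
#' @param Y Data (`m x n_time`, possibly eigenmode-reduced).
#' @param L Gain matrix (`m x n_dipoles`) or `lead_field`.
#' @param components An `msp_components` set.
#' @param hyper An [msp_hyper()]; if its first element is named `"noise"`
#'   it supplies the sensor log-variance, otherwise `noise` must be given.
#' @param noise Optional [noise_model()] overriding the `"noise"` entry.
#' @return List with `F`, `accuracy`, `complexity`, `C_Y`.
#' @export
free_energy <- function(Y, L, components, hyper, noise = NULL) {
  stopifnot(inherits(hyper, "msp_hyper"))
  L <- lf_matrix(L)
  Y <- as.matrix(Y)
  m <- nrow(Y); nt <- ncol(Y)
  mu <- hyper$mu
  if (is.null(noise)) {
    if (is.null(names(mu)) || names(mu)[1] != "noise")
      stop("supply a noise_model or name the first hyperparameter 'noise'", call. = FALSE)
    lambda0 <- mu[[1]]
    mu_src <- mu[-1]
  } else {
    stopifnot(inherits(noise, "noise_model"))
    lambda0 <- noise$lambda
    mu_src <- if (!is.null(names(mu)) && names(mu)[1] == "noise") mu[-1] else mu
  }
  Q <- assemble_Q(components, mu_src)
  Cy <- exp(lambda0) * diag(m) + L %*% Q %*% t(L)
  ch <- tryCatch(chol(Cy), error = function(e)
    stop("model covariance C_Y is not positive definite", call. = FALSE))
  logdet <- 2 * sum(log(diag(ch)))
  Cinv <- chol2inv(ch)
  accuracy <- -0.5 * sum(Cinv * tcrossprod(Y)) - nt / 2 * logdet - nt * m / 2 * log(2 * pi)
  complexity <- hyper_complexity(hyper)
  list(F = accuracy - complexity, accuracy = accuracy, complexity = complexity, C_Y = Cy)
}

hyper_complexity <- function(hyper) {
  e <- hyper$mu - hyper$nu
  k <- length(e)
  ldC <- k * log(hyper$alpha)
  chS <- tryCatch(chol(hyper$Sigma_lambda), error = function(e2) NULL)
  ldS <- if (is.null(chS)) determinant(hyper$Sigma_lambda)$modulus[1] else 2 * sum(log(diag(chS)))
  0.5 * sum(e^2) / hyper$alpha + 0.5 * (ldC - ldS)
}

lf_matrix <- function(L) if (inherits(L, "lead_field")) L$matrix else as.matrix(L)

#' Default settings for the hyperparameter ascent
#'
#' @param alpha Prior hyperparameter variance (default 256).
#' @param tol Free-energy change below which an iteration counts as
#'   converged (default 0.01; the free-energy differences that drive the
#'   head search are two to four orders of magnitude larger).
#' @param tol_consecutive Successive small-change iterations required
#'   (default 4).
#' @param max_iter Iteration cap (default 128).
#' @param prune_tol Components whose weight falls below this fraction of
#'   the largest component weight are frozen (default 1e-8).
#' @param noise_floor Lower bound on the sensor noise variance as a
#'   fraction of the mean sensor power (default 1e-3). Keeps the evidence
#'   finite on noiseless (rank-deficient) data, where the Gaussian
#'   likelihood is otherwise unbounded as the noise hyperparameter
#'   collapses; inactive whenever real noise dominates.
#' @param gain_floor Visibility cut: components whose unit-current sensor
#'   power falls below this fraction of the most visible component's are
#'   excluded from the fit and reported with zero weight (default 1e-4,
#'   i.e. 1% of the maximal field amplitude). The data cannot constrain
#'   such patches, and leaving them in lets the optimiser inflate their
#'   current by the inverse of a near-zero gain.
#' @return List of settings.
#' @export
inversion_config <- function(alpha = 256, tol = 1e-2, tol_consecutive = 4,
                             max_iter = 128, prune_tol = 1e-8,
                             noise_floor = 1e-3, gain_floor = 1e-4) {
  stopifnot(alpha > 0, tol > 0, max_iter >= 1, noise_floor > 0, gain_floor >= 0)
  list(alpha = alpha, tol = tol, tol_consecutive = tol_consecutive,
       max_iter = max_iter, prune_tol = prune_tol, noise_floor = noise_floor,
       gain_floor = gain_floor)
}

chol_jitter <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  j <- 1e-10 * mean(diag(C))
  while (is.null(ch) && j < mean(diag(C))) {
    ch <- tryCatch(chol(C + diag(j, nrow(C))), error = function(e) NULL)
    j <- j * 100
  }
  if (is.null(ch)) stop("model covariance is numerically singular", call. = FALSE)
  ch
}

#' MSP source inversion for a fixed head model
#'
#' Fits the hyperparameters of the multiple-sparse-priors model by a
#' Fisher-scored ascent on the variational free energy: the sensor-space
#' model covariance `C = exp(lambda_0) I + sum_i exp(lambda_i) L D_i L'` is
#' matched to the sample covariance of the (reduced) data, with a Gaussian
#' prior `lambda ~ N(0, alpha I)` on the (internally rescaled) log weights.
#' A backtracking line search keeps the objective non-decreasing, components
#' whose weight collapses are frozen (automatic relevance determination),
#' and the posterior covariance of the hyperparameters is the inverse Fisher
#' curvature at the optimum.
#'
#' Internally each sensor-space component is normalised to unit mean
#' diagonal and the data to unit mean sensor power, so the zero prior mean
#' is uninformative on a common scale for every head hypothesis; reported
#' hyperparameters are shifted back to the raw units of
#' `Q = sum_i exp(lambda_i) D_i` (the complexity term is invariant to this
#' shift since prior and posterior means shift together).
#'
#' @param Y Data matrix (`m x n_time`), already eigenmode-reduced in the
#'   head-search pipeline.
#' @param L Gain matrix (`m x n_dipoles`) or `lead_field`, same basis as
#'   `Y`.
#' @param components An `msp_components` set.
#' @param config An [inversion_config()].
#' @param compute_sources Also compute `Jhat`, `diag(Sigma_J)`, `M`, and the
#'   residual (default `TRUE`; the head search switches it off and only the
#'   free energy is needed).
#' @param init Optional warm start: a list with `w_source` (raw component
#'   weights) and `sigma2_noise`, e.g. from a previous `msp_fit` at a nearby
#'   head. Must be the same fixed starting point for every head hypothesis
#'   being compared, so the fitted free energies stay a well-defined
#'   function of head position.
#' @return Object of class `msp_fit`; see [tidy.msp_fit()] and
#'   [glance.msp_fit()] for tabular views, [compute_sources()] for the
#'   source estimates.
#' @export
msp_invert <- function(Y, L, components, config = inversion_config(),
                       compute_sources = TRUE, init = NULL) {
  stopifnot(inherits(components, "msp_components"))
  L <- lf_matrix(L)
  Y <- as.matrix(Y)
  m <- nrow(Y); nt <- ncol(Y)
  if (nrow(L) != m) stop("Y and L disagree on the number of sensors/modes", call. = FALSE)
  if (components$n_dipoles != ncol(L))
    stop("components and L disagree on the number of dipoles", call. = FALSE)
  np <- n_components(components)
  rank1 <- components$type == "rank1"

  # --- internal scaling ------------------------------------------------
  sc <- sum(Y^2) / (m * nt)
  if (!is.finite(sc) || sc <= 0) sc <- 1
  Ys <- Y / sqrt(sc)
  Cemp <- tcrossprod(Ys) / nt

  # components are normalised in SOURCE space (unit trace of D_i), so the
  # prior is uninformative about current density, not about sensor power:
  # a near-silent patch (deep, or near-radial orientation) must earn any
  # weight through the data instead of starting at data scale, which would
  # let its reconstructed current blow up by the inverse gain
  if (rank1) {
    s_i <- 1 / pmax(colSums(components$vectors^2), 1e-300)
    W <- L %*% components$vectors              # m x np (raw sensor profiles)
    Ws <- W * rep(sqrt(s_i), each = m)
    snr_comp <- colSums(Ws^2) / m              # sensor power per unit current
  } else {
    s_i <- 1 / vapply(components$matrices, function(D) sum(diag(D)), 0)
    Ss <- Map(function(D, s) (L %*% D %*% t(L)) * s, components$matrices, s_i)
    snr_comp <- vapply(Ss, function(S) mean(diag(S)), 0)
  }
  dead <- snr_comp <= config$gain_floor * max(snr_comp, 1e-300)
  if (rank1) Ws[, dead] <- 0

  # --- objective in the scaled parameterisation ------------------------
  alpha <- config$alpha
  k <- np + 1L                                  # noise + components
  nu <- rep(0, k)
  act <- !dead                                # active (unfrozen) components
  build_C <- function(th) {
    w <- exp(th[-1]); w[dead] <- 0
    if (rank1) {
      Wa <- Ws[, act, drop = FALSE]
      C <- Wa %*% (w[act] * t(Wa))
    } else {
      C <- Reduce(`+`, Map(`*`, Ss, w))
      if (is.null(C)) C <- matrix(0, m, m)
    }
    C <- (C + t(C)) / 2
    diag(C) <- diag(C) + exp(th[1])
    C
  }
  objective <- function(th, need_inv = TRUE) {
    ch <- chol_jitter(build_C(th))
    logdet <- 2 * sum(log(diag(ch)))
    # tr(Cinv Cemp) via triangular solves (no explicit inverse needed)
    X <- backsolve(ch, backsolve(ch, Cemp, transpose = TRUE))
    acc <- -nt / 2 * (sum(diag(X)) + logdet + m * log(2 * pi))
    out <- list(value = acc - 0.5 * sum((th - nu)^2) / alpha, acc = acc, chol = ch)
    if (need_inv) out$Cinv <- chol2inv(ch)
    out
  }

  lambda0_min <- log(config$noise_floor)
  # initialise the noise level from the flat tail of the data spectrum
  # (lower quartile of the eigenvalues of the sample covariance), the source
  # weights from the remaining power split across components
  if (is.null(init)) {
    evals <- eigen(Cemp, symmetric = TRUE, only.values = TRUE)$values
    lam0_init <- max(mean(tail(evals, ceiling(m / 4))), config$noise_floor)
    mean_gain <- mean(snr_comp[!dead])
    theta <- c(log(lam0_init),
               rep(log(max(1 - lam0_init, 0.1) /
                       (max(1, sum(!dead)) * max(mean_gain, 1e-300))), np))
  } else {
    stopifnot(length(init$w_source) == np, init$sigma2_noise > 0)
    theta <- c(log(max(init$sigma2_noise / sc, config$noise_floor)),
               log(pmax(init$w_source, 1e-14) / (sc * s_i)))
  }
  theta[-1][dead] <- -32
  frozen <- c(FALSE, dead)
  clamp <- function(th) {
    th <- pmin(pmax(th, -32), 32)
    th[1] <- max(th[1], lambda0_min)
    th
  }
  theta <- clamp(theta)

  cur <- objective(theta)
  F_trace <- numeric(config$max_iter + 1L); F_trace[1] <- cur$value
  n_done <- 0L
  small <- 0L; converged <- FALSE

  # gradient and curvature pieces at the current state; the Fisher
  # information (needed only for the fallback step and for Sigma_lambda at
  # the optimum) is assembled on demand
  grad_pieces <- function(Cinv, w) {
    if (rank1) {
      Wa <- Ws[, act, drop = FALSE]
      A <- matrix(0, m, np); tAW <- numeric(np); tACA <- numeric(np)
      Aa <- Cinv %*% Wa
      A[, act] <- Aa
      tAW[act] <- colSums(Wa * Aa)
      tACA[act] <- colSums(Aa * (Cemp %*% Aa))
    } else {
      CS <- lapply(Ss, function(S) Cinv %*% S)
      CiCe <- Cinv %*% Cemp
      tAW <- vapply(CS, function(M) sum(diag(M)), 0)
      tACA <- vapply(CS, function(M) sum(M * t(CiCe)), 0)
    }
    CC <- Cinv %*% Cemp
    tr0 <- sum(diag(Cinv)); tr0e <- sum(CC * Cinv)
    g <- c(-nt / 2 * exp(theta[1]) * (tr0 - tr0e),
           -nt / 2 * w * (tAW - tACA)) - (theta - nu) / alpha
    list(g = g, tAW = tAW, tACA = tACA, tr0 = tr0, tr0e = tr0e,
         A = if (rank1) A else NULL, CS = if (!rank1) CS else NULL)
  }
  fisher <- function(Cinv, w, gp) {
    H <- matrix(0, k, k)
    if (rank1) {
      Msrc <- crossprod(Ws, gp$A)
      H[-1, -1] <- nt / 2 * (w %o% w) * Msrc^2
      H[1, -1] <- H[-1, 1] <- nt / 2 * exp(theta[1]) * w * colSums(gp$A^2)
    } else {
      for (i in seq_len(np)) for (j in i:np) {
        v <- nt / 2 * w[i] * w[j] * sum(gp$CS[[i]] * t(gp$CS[[j]]))
        H[i + 1, j + 1] <- v; H[j + 1, i + 1] <- v
      }
      H[1, -1] <- H[-1, 1] <- nt / 2 * exp(theta[1]) * w *
        vapply(gp$CS, function(M) sum(M * t(Cinv)), 0)
    }
    H[1, 1] <- nt / 2 * exp(2 * theta[1]) * sum(Cinv^2)
    H + diag(1 / alpha, k)
  }
  line_search <- function(delta) {
    delta[frozen] <- 0
    delta <- pmin(pmax(delta, -8), 8)          # trust region on log scale
    step <- 1
    for (half in 0:6) {
      th_new <- clamp(theta + step * delta)
      cand <- objective(th_new, need_inv = FALSE)
      if (is.finite(cand$value) && cand$value >= cur$value - 1e-9 * abs(cur$value))
        return(list(theta = th_new, cand = cand))
      step <- step / 2
    }
    NULL
  }

  for (it in seq_len(config$max_iter)) {
    Cinv <- cur$Cinv
    w <- exp(theta[-1]); w[dead] <- 0
    gp <- grad_pieces(Cinv, w)
    # multiplicative fixed-point step (follows the curved valley coupling
    # the noise level to the component weights); Fisher scoring is the
    # safeguarded fallback
    delta_mackay <- log(pmax(c(gp$tr0e, gp$tACA), 1e-300) /
                        pmax(c(gp$tr0, gp$tAW), 1e-300))
    acc <- line_search(delta_mackay)
    if (is.null(acc)) {
      H <- fisher(Cinv, w, gp)
      g <- gp$g; g[frozen] <- 0
      delta_fisher <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), k), g),
                               error = function(e) g / max(diag(H)))
      acc <- line_search(delta_fisher)
    }
    if (is.null(acc)) { converged <- TRUE; break }
    dF <- acc$cand$value - cur$value
    theta <- acc$theta
    cur <- acc$cand
    cur$Cinv <- chol2inv(cur$chol)
    n_done <- n_done + 1L
    F_trace[n_done + 1L] <- cur$value
    # ARD freeze of collapsed components
    wmax <- max(exp(theta[-1][!frozen[-1]]), 0)
    frozen <- frozen | c(FALSE, exp(theta[-1]) < config$prune_tol * wmax)
    act <- !frozen[-1]
    # projected gradient: a noise parameter pinned at its floor with the
    # gradient pushing further down counts as stationary
    gq <- gp$g
    gq[frozen] <- 0
    if (theta[1] <= lambda0_min + 1e-12 && gq[1] < 0) gq[1] <- 0
    if (abs(dF) < config$tol && max(abs(gq)) < 1) small <- small + 1L else small <- 0L
    if (small >= config$tol_consecutive) { converged <- TRUE; break }
  }
  F_trace <- F_trace[seq_len(n_done + 1L)]

  # curvature at the optimum -> posterior covariance of the hyperparameters
  w <- exp(theta[-1]); w[dead] <- 0
  H <- fisher(cur$Cinv, w, grad_pieces(cur$Cinv, w))
  Sigma_lambda <- tryCatch(solve(H), error = function(e) diag(1 / diag(H)))
  Sigma_lambda <- (Sigma_lambda + t(Sigma_lambda)) / 2

  # --- report in raw units --------------------------------------------
  shift <- c(log(sc), log(sc * s_i))
  mu_raw <- theta + shift
  nu_raw <- nu + shift
  names(mu_raw) <- names(nu_raw) <- c("noise", paste0("C", seq_len(np)))
  hyper <- msp_hyper(mu_raw, nu = nu_raw, alpha = alpha, Sigma_lambda = Sigma_lambda)
  complexity <- hyper_complexity(hyper)
  accuracy <- cur$acc - nt * m / 2 * log(sc)
  Fval <- accuracy - complexity

  w_source <- exp(theta[-1]) * sc * s_i
  w_source[dead] <- 0
  fit <- structure(list(
    hyper = hyper,
    F = Fval, accuracy = accuracy, complexity = complexity,
    F_trace = F_trace + (-nt * m / 2 * log(sc)),
    converged = converged, n_iter = length(F_trace) - 1L,
    w_source = w_source,
    sigma2_noise = exp(theta[1]) * sc,
    pruned = frozen[-1],
    C_Y = sc * build_C(theta),
    components = components,
    L = L, Y = Y, m = m, n_time = nt
  ), class = "msp_fit")
  if (compute_sources) fit <- compute_sources(fit)
  fit
}

#' Optimise MSP hyperparameters (spec-style interface)
#'
#' Thin wrapper around [msp_invert()] returning the hyperparameter state and
#' the full inversion result separately.
#'
#' @inheritParams msp_invert
#' @param noise Ignored starting value (the sensor log-variance is always
#'   optimised); present for call-signature compatibility.
#' @return List with `hyper` ([msp_hyper()]) and `result` (`msp_fit`).
#' @export
optimize_hyperparameters <- function(Y, L, components, noise = noise_model(),
                                     config = inversion_config()) {
  fit <- msp_invert(Y, L, components, config = config, compute_sources = TRUE)
  list(hyper = fit$hyper, result = fit)
}

#' Source estimates from a fitted MSP model
#'
#' Adds `Jhat` (posterior mean currents), `diag_Sigma_J` (per-dipole
#' posterior variances), the inverse operator `M`, the residual `e_Y`, and
#' the time-integrated source power to an `msp_fit`.
#'
#' @param fit An `msp_fit`.
#' @return The fit, augmented.
#' @export
compute_sources <- function(fit) {
  stopifnot(inherits(fit, "msp_fit"))
  if (!is.null(fit$Jhat)) return(fit)
  ch <- chol_jitter(fit$C_Y)
  Cinv <- chol2inv(ch)
  comp <- fit$components
  if (comp$type == "rank1") {
    V <- comp$vectors
    W <- fit$L %*% V
    B0 <- fit$w_source * t(W)          # np x m  = diag(w) W'
    Tm <- V %*% B0                     # Q L'    (nd x m)
    M <- Tm %*% Cinv
    Jhat <- M %*% fit$Y
    diagQ <- as.numeric((V^2) %*% fit$w_source)
    dSig <- pmax(diagQ - rowSums(M * Tm), 0)
  } else {
    Q <- assemble_Q(comp, log(pmax(fit$w_source, 1e-300)))
    pm <- posterior_mean(fit$Y, fit$L, Q, diag(fit$sigma2_noise, fit$m))
    M <- pm$M; Jhat <- pm$Jhat
    dSig <- posterior_covariance(fit$L, Q, diag(fit$sigma2_noise, fit$m), diagonal = TRUE)
  }
  fit$Jhat <- Jhat
  fit$diag_Sigma_J <- dSig
  fit$M <- M
  fit$e_Y <- fit$Y - fit$L %*% Jhat
  fit$power <- rowSums(Jhat^2)
  fit
}

#' @export
print.msp_fit <- function(x, ...) {
  cat(sprintf("<msp_fit> F = %.3f (accuracy %.3f, complexity %.3f)\n",
              x$F, x$accuracy, x$complexity))
  cat(sprintf("  %d components (%d active), sensor noise variance %.4g, %d iterations%s\n",
              length(x$w_source), sum(!x$pruned), x$sigma2_noise, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Tidy a fitted MSP inversion
#'
#' One row per covariance component: patch-centre vertex, log weight (raw
#' units), weight, and whether the component was pruned.
#'
#' @param x An `msp_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.msp_fit <- function(x, ...) {
  np <- length(x$w_source)
  tibble::tibble(
    component = seq_len(np),
    center = if (all(is.na(x$components$centers))) NA_integer_ else x$components$centers,
    lambda = unname(x$hyper$mu[-1]),
    weight = x$w_source,
    pruned = x$pruned
  )
}

#' One-row summary of a fitted MSP inversion
#'
#' @param x An `msp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the free energy and its decomposition.
#' @export
glance.msp_fit <- function(x, ...) {
  tibble::tibble(
    F = x$F, accuracy = x$accuracy, complexity = x$complexity,
    sigma2_noise = x$sigma2_noise,
    n_components = length(x$w_source),
    n_active = sum(!x$pruned),
    n_iter = x$n_iter,
    converged = x$converged
  )
}
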