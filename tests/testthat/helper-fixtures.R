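# Shared fixtures and independent oracles, all built in code.

tiny_mesh <- function(n = 150) synthetic_cortex_mesh(n)

tiny_setup <- function(n_mesh = 150, n_sensors = 24, n_modes = 16, n_comp = 16,
                       smoothing = NULL) {
  mesh <- synthetic_cortex_mesh(n_mesh)
  sph <- fit_conductor_sphere(mesh)
  rmax <- max(sqrt(rowSums(sweep(mesh$vertices, 2, sph$center)^2)))
  sensors <- synthetic_sensor_array(n_sensors, radius = 1.55 * rmax,
                                    center = sph$center,
                                    conductor_radius = 1.08 * rmax)
  fids <- default_fiducials(rmax)
  if (is.null(smoothing)) smoothing <- calibrate_smoothing(mesh)
  G <- green_function(mesh, smoothing)
  comps <- build_msp_components(G, n_comp, mesh)
  list(mesh = mesh, sensors = sensors, fids = fids, G = G, comps = comps,
       sphere = sph, rmax = rmax)
}

# homogeneous 4x4 matrix for a rigid transform: oracle for composition
homogeneous_matrix <- function(params) {
  R <- rotation_matrix(params$rotation)
  o <- params$origin; tr <- params$translation
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- o + tr - R %*% o
  M
}

apply_homogeneous <- function(M, pts) {
  out <- cbind(pts, 1) %*% t(M)
  out[, 1:3, drop = FALSE]
}

# magnetic field of the primary (dipole-in-free-space) current only;
# outside a spherical conductor the radial field component equals this
# primary contribution exactly (volume currents are radially silent)
primary_field <- function(q, p, r) {
  a <- r - p
  an <- sqrt(sum(a^2))
  c(q[2] * a[3] - q[3] * a[2],
    q[3] * a[1] - q[1] * a[3],
    q[1] * a[2] - q[2] * a[1]) / an^3
}

# conditional mean/covariance of J | Y from the joint Gaussian [J; Y]
joint_gaussian_oracle <- function(Y, L, Q, R) {
  S_jj <- Q
  S_jy <- Q %*% t(L)
  S_yy <- L %*% Q %*% t(L) + R
  K <- S_jy %*% solve(S_yy)
  list(mean = K %*% Y, cov = S_jj - K %*% t(S_jy))
}

# truncated Taylor series for expm(s * GL) acting on the identity
expm_series_oracle <- function(GL, s, terms = 60) {
  n <- nrow(GL)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (s * GL) / k
    acc <- acc + term
  }
  acc
}

random_psd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}
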