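#' Analytic single-sphere MEG lead field
#'
#' Magnetic field of current dipoles inside a homogeneous spherical
#' conductor, evaluated at point magnetometers and projected on their pickup
#' orientations (Sarvas closed form, which accounts for both the primary
#' current and the volume return currents). Column `j` of the result is the
#' sensor-space signature of a unit dipole at mesh vertex `j` oriented along
#' its surface normal. The overall scale constant is 1 ("arbitrary
#' consistent field units"): the inference is invariant to it.
#'
#' Two exact properties of this conductor model are worth knowing: a purely
#' radial dipole produces no external field (its column is zero), and a
#' dipole at the conductor centre likewise produces no field. Neither case
#' is singular in this parameterisation; columns simply vanish, and the
#' hyperparameter optimisation prunes the corresponding components.
#'
#' The conductor is the head itself, so its centre is re-fitted to the mesh
#' on every call (least-squares sphere): a rigidly moved head carries its
#' conductor with it, which is exactly what makes the lead field of a
#' transformed head equal that of the untransformed head seen by inversely
#' transformed sensors.
#'
#' @param mesh A [cortical_mesh()]; dipoles sit at its vertices, oriented
#'   along its normals. All dipoles must be closer to the fitted sphere
#'   centre than any sensor (no collision with the helmet).
#' @param sensors A [sensor_array()].
#' @return Object of class `lead_field`: a list with `matrix`
#'   (`n_sensors x n_dipoles`) and `head_id` (a key identifying the geometry
#'   that produced it).
#' @param head_id Optional identifier for the head hypothesis.
#' @export
compute_lead_field <- function(mesh, sensors, head_id = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(sensors, "sensor_array"))
  ctr <- fit_conductor_sphere(mesh)$center
  P <- sweep(mesh$vertices, 2, ctr)        # dipole positions r0, Nd x 3
  S <- sweep(sensors$positions, 2, ctr)    # sensor positions r, Nc x 3
  U <- sensors$orientations                # Nc x 3
  N <- mesh$normals                        # dipole moments (unit), Nd x 3
  rad <- sqrt(rowSums(P^2))
  if (max(rad) >= min(sqrt(rowSums(S^2))))
    stop("head collides with the sensor array: a dipole lies at or beyond the nearest sensor",
         call. = FALSE)
  nc <- nrow(S); nd <- nrow(P)
  # q x r0 per dipole (Nd x 3)
  QxR0 <- cbind(N[, 2] * P[, 3] - N[, 3] * P[, 2],
                N[, 3] * P[, 1] - N[, 1] * P[, 3],
                N[, 1] * P[, 2] - N[, 2] * P[, 1])
  rn <- sqrt(rowSums(S^2))                     # |r| per sensor
  L <- matrix(0, nc, nd)
  # pairwise geometry, vectorised over dipoles for each sensor
  for (i in seq_len(nc)) {
    r <- S[i, ]
    A <- matrix(r, nd, 3, byrow = TRUE) - P    # a = r - r0, Nd x 3
    an <- sqrt(rowSums(A^2))
    ar <- A[, 1] * r[1] + A[, 2] * r[2] + A[, 3] * r[3]   # a . r
    r0r <- P[, 1] * r[1] + P[, 2] * r[2] + P[, 3] * r[3]  # r0 . r
    Fv <- an * (rn[i] * an + rn[i]^2 - r0r)
    c1 <- an^2 / rn[i] + ar / an + 2 * an + 2 * rn[i]
    c2 <- an + 2 * rn[i] + ar / an
    # grad F = c1 * r - c2 * r0  (Nd x 3)
    G1 <- cbind(c1 * r[1] - c2 * P[, 1],
                c1 * r[2] - c2 * P[, 2],
                c1 * r[3] - c2 * P[, 3])
    qr0_r <- QxR0[, 1] * r[1] + QxR0[, 2] * r[2] + QxR0[, 3] * r[3]
    B <- (Fv * QxR0 - qr0_r * G1) / Fv^2       # Nd x 3
    L[i, ] <- B %*% U[i, ]
  }
  if (!all(is.finite(L)))
    stop("non-finite lead field entries; check sensor/dipole geometry", call. = FALSE)
  structure(list(matrix = L, head_id = head_id %||% "reference"),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d dipoles (head '%s')\n",
              nrow(x$matrix), ncol(x$matrix), x$head_id))
  invisible(x)
}

#' Eigenmode sensor-space projector
#'
#' Orthonormal basis of the top-`m` left singular vectors of the reference
#' lead field. All data and lead fields are projected into this fixed basis
#' for the whole head search, so the (reduced) data never change between
#' head hypotheses. If `m` exceeds the numerical rank of the gain matrix it
#' is shrunk with a warning.
#'
#' @param L A [compute_lead_field()] result (the reference-head gain
#'   matrix), or a plain matrix.
#' @param m Number of eigenmodes to keep (default 100).
#' @return Object of class `eigenmode_projector` with fields `basis`
#'   (`n_sensors x m`), `singular_values`, `source_head_id`.
#' @export
build_projector <- function(L, m = 100) {
  M <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  head_id <- if (inherits(L, "lead_field")) L$head_id else "unknown"
  if (m > nrow(M)) stop("m cannot exceed the number of sensors", call. = FALSE)
  sv <- svd(M, nu = min(nrow(M), ncol(M)))
  rank <- sum(sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1])
  if (m > rank) {
    warning(sprintf("m = %d exceeds gain-matrix rank %d; using m = %d", m, rank, rank))
    m <- rank
  }
  structure(list(basis = sv$u[, seq_len(m), drop = FALSE],
                 singular_values = sv$d,
                 source_head_id = head_id),
            class = "eigenmode_projector")
}

#' @export
print.eigenmode_projector <- function(x, ...) {
  cat(sprintf("<eigenmode_projector> %d modes over %d sensors (from head '%s')\n",
              ncol(x$basis), nrow(x$basis), x$source_head_id))
  invisible(x)
}

#' Project data or lead fields onto the eigenmode basis
#'
#' Replaces sensor-space rows by coordinates in the fixed orthonormal basis.
#'
#' @param projector An [build_projector()] result.
#' @param x A matrix with `n_sensors` rows (data `Y` or a gain matrix), or a
#'   `lead_field`.
#' @return The reduced matrix (`m` rows); a `lead_field` input keeps its
#'   class and `head_id`.
#' @export
project_modes <- function(projector, x) {
  stopifnot(inherits(projector, "eigenmode_projector"))
  is_lf <- inherits(x, "lead_field")
  M <- if (is_lf) x$matrix else as.matrix(x)
  if (nrow(M) != nrow(projector$basis))
    stop(sprintf("dimension mismatch: %d rows vs %d sensors in the basis",
                 nrow(M), nrow(projector$basis)), call. = FALSE)
  out <- crossprod(projector$basis, M)
  if (is_lf) structure(list(matrix = out, head_id = x$head_id), class = "lead_field") else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
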