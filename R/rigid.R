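#' Fiducial landmark set
#'
#' Three anatomical landmarks (nasion, left preauricular, right preauricular)
#' that specify the head position in the device (sensor) frame. Head
#' hypotheses are rigid-body transformations of these three points.
#'
#' @param nasion,left_ear,right_ear Numeric 3-vectors, mm, device frame.
#' @return An object of class `fiducial_set`: a named list of the three
#'   3-vectors.
#' @examples
#' fiducial_set(c(0, 86, 0), c(-72, 0, -10), c(72, 0, -10))
#' @export
fiducial_set <- function(nasion, left_ear, right_ear) {
  pts <- list(nasion = nasion, left_ear = left_ear, right_ear = right_ear)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop("fiducial '", nm, "' must be a finite 3-vector", call. = FALSE)
    pts[[nm]] <- p
  }
  d <- c(
    sqrt(sum((pts$nasion - pts$left_ear)^2)),
    sqrt(sum((pts$nasion - pts$right_ear)^2)),
    sqrt(sum((pts$left_ear - pts$right_ear)^2))
  )
  if (any(d <= 0))
    stop("fiducials must be pairwise distinct", call. = FALSE)
  # collinearity: cross product of the two edge vectors must be non-zero
  v1 <- pts$left_ear - pts$nasion
  v2 <- pts$right_ear - pts$nasion
  cr <- cross3(v1, v2)
  if (sqrt(sum(cr^2)) <= 1e-9 * max(d))
    stop("fiducials are collinear; they must span a plane", call. = FALSE)
  structure(pts, class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set> (mm)\n")
  for (nm in names(x)) cat(sprintf("  %-9s % .3f % .3f % .3f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' @export
as_tibble.fiducial_set <- function(x, ...) {
  m <- do.call(rbind, unclass(x))
  tibble::tibble(fiducial = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Mid-point of the two ear fiducials
#'
#' Used as the origin of rotation for head transformations.
#'
#' @param fids A [fiducial_set()].
#' @return Numeric 3-vector, mm.
#' @export
ear_midpoint <- function(fids) {
  stopifnot(inherits(fids, "fiducial_set"))
  (fids$left_ear + fids$right_ear) / 2
}

#' Rigid-body transformation parameters
#'
#' A 6-DOF head hypothesis: translation (mm) plus intrinsic x-y-z Euler
#' rotations (degrees) about a rotation origin, conventionally the mid-point
#' of the ear fiducials. The induced map is `x -> R (x - o) + o + t`.
#'
#' @param translation Numeric 3-vector, mm.
#' @param rotation Numeric 3-vector of Euler angles in degrees, applied as
#'   `Rx(rx) %*% Ry(ry) %*% Rz(rz)`.
#' @param origin Rotation origin, numeric 3-vector, mm. Defaults to the
#'   coordinate origin; [apply_head_transform()] substitutes the ear
#'   mid-point of the current fiducials when not supplied explicitly.
#' @return Object of class `rigid_body_params`.
#' @export
rigid_body_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                              origin = c(0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  origin <- as.numeric(origin)
  if (length(translation) != 3L || length(rotation) != 3L || length(origin) != 3L)
    stop("translation, rotation and origin must be 3-vectors", call. = FALSE)
  if (!all(is.finite(c(translation, rotation, origin))))
    stop("rigid-body parameters must be finite", call. = FALSE)
  structure(list(translation = translation, rotation = rotation, origin = origin),
            class = "rigid_body_params")
}

#' @export
print.rigid_body_params <- function(x, ...) {
  cat(sprintf("<rigid_body_params> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  cat(sprintf("  rotation origin (%.3f, %.3f, %.3f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic x-y-z convention: `R = Rx(rx) %*% Ry(ry) %*% Rz(rz)`, angles in
#' degrees.
#'
#' @param angles_deg Numeric 3-vector of angles, degrees.
#' @return 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Apply a rigid-body transformation to points
#'
#' Maps each point `x` to `R (x - o) + o + t` where `R` is built from the
#' Euler angles, `o` is the rotation origin and `t` the translation. The map
#' is an isometry: all pairwise distances are preserved.
#'
#' @param points An `n x 3` numeric matrix (or a single 3-vector).
#' @param params A [rigid_body_params()].
#' @return Transformed points in the same shape as the input.
#' @examples
#' p <- rigid_body_params(translation = c(1, 0, 0))
#' rigid_body_transform(c(0, 0, 0), p)
#' @export
rigid_body_transform <- function(points, params) {
  stopifnot(inherits(params, "rigid_body_params"))
  vec <- is.null(dim(points))
  P <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(P) != 3L) stop("points must be n x 3", call. = FALSE)
  if (!all(is.finite(P))) stop("points must be finite", call. = FALSE)
  if (all(params$rotation == 0) && all(params$translation == 0))
    return(points)                    # identity: bit-for-bit
  R <- rotation_matrix(params$rotation)
  o <- params$origin; t <- params$translation
  out <- sweep(sweep(P, 2, o) %*% t(R), 2, o + t, `+`)
  if (vec) drop(out) else out
}

#' Transform a cortical mesh and its fiducials rigidly together
#'
#' Vertices and fiducials are mapped by the full rigid-body transform;
#' dipole orientation normals are rotated only (no translation). If the
#' parameter's rotation origin was left at the default `c(0,0,0)` and the
#' fiducials are supplied, the ear mid-point of `fids` is used as the origin
#' of rotation.
#'
#' @param mesh A [cortical_mesh()].
#' @param fids A [fiducial_set()].
#' @param params A [rigid_body_params()].
#' @param use_ear_origin Replace the parameter origin with the ear mid-point
#'   of `fids` (default `TRUE`, the head-search convention).
#' @return List with elements `mesh` and `fiducials`, transformed.
#' @export
apply_head_transform <- function(mesh, fids, params, use_ear_origin = TRUE) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(fids, "fiducial_set"),
            inherits(params, "rigid_body_params"))
  if (isTRUE(use_ear_origin))
    params <- rigid_body_params(params$translation, params$rotation,
                                origin = ear_midpoint(fids))
  identity_map <- all(params$rotation == 0) && all(params$translation == 0)
  R <- rotation_matrix(params$rotation)
  v <- rigid_body_transform(mesh$vertices, params)
  n <- if (identity_map) mesh$normals else mesh$normals %*% t(R)
  new_fids <- fiducial_set(
    rigid_body_transform(fids$nasion, params),
    rigid_body_transform(fids$left_ear, params),
    rigid_body_transform(fids$right_ear, params)
  )
  list(
    mesh = cortical_mesh(v, mesh$faces, normals = n, validate = FALSE),
    fiducials = new_fids
  )
}

# Compact string key for caching inversions per head hypothesis.
params_key <- function(params) {
  paste(sprintf("%.9g", c(params$translation, params$rotation)), collapse = "|")
}
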