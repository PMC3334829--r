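#' Cortical surface mesh
#'
#' A triangle mesh whose vertices carry current dipoles oriented along the
#' (outward) vertex normals. Coordinates in mm; vertex indices 1-based.
#'
#' @param vertices `n x 3` numeric matrix, mm.
#' @param faces Integer `f x 3` matrix of 1-based vertex indices.
#' @param normals Optional `n x 3` matrix of unit dipole orientations; when
#'   `NULL`, area-weighted vertex normals are computed from the faces.
#' @param validate Run invariant checks (default `TRUE`).
#' @return Object of class `cortical_mesh` with fields `vertices`, `faces`,
#'   `normals`.
#' @export
cortical_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 1L)
    stop("vertices must be a non-empty n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be f x 3", call. = FALSE)
  if (validate) {
    if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range (1-based)", call. = FALSE)
  }
  if (is.null(normals)) {
    normals <- vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals); storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stop("normals must match vertices in shape", call. = FALSE)
    nn <- sqrt(rowSums(normals^2))
    if (validate && any(abs(nn - 1) > 1e-6))
      normals <- normals / nn
  }
  dimnames(vertices) <- dimnames(faces) <- dimnames(normals) <- NULL
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
as_tibble.cortical_mesh <- function(x, ...) {
  v <- x$vertices; n <- x$normals
  tibble::tibble(
    vertex = seq_len(nrow(v)),
    x = v[, 1], y = v[, 2], z = v[, 3],
    nx = n[, 1], ny = n[, 2], nz = n[, 3]
  )
}

#' Area-weighted vertex normals
#'
#' Sums un-normalised triangle normals (whose length is twice the triangle
#' area) around each vertex and normalises, so larger adjacent triangles
#' contribute more.
#'
#' @param vertices `n x 3` matrix.
#' @param faces `f x 3` integer matrix, 1-based.
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], faces[, j])
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Synthetic cortex-like surface
#'
#' A deterministic, deformed sphere used as a stand-in cortical surface: a
#' latitude/longitude triangulation with a low-order angular modulation of
#' the radius (overall head asymmetry) plus higher-frequency ripples that
#' mimic sulcal folding. The ripples matter physically: they swing the
#' vertex normals well away from the radial direction, and in a spherical
#' conductor only the non-radial dipole component produces any external
#' field -- an unfolded (near-spherical) surface would carry almost
#' invisible sources. Outward normals define the fixed dipole orientations;
#' mesh vertices double as candidate patch centres.
#'
#' @param n_vertices Approximate number of vertices (default 500).
#' @param radius Nominal radius, mm (default 70).
#' @param deform Relative amplitude of the low-order modulation
#'   (default 0.08).
#' @param fold Relative amplitude of the sulcal ripples (default 0.14;
#'   combined with their angular frequency this tilts normals by roughly
#'   20-40 degrees from radial, as on a folded cortex).
#' @param asym Relative amplitude of the single-lobed (order-1) azimuthal
#'   asymmetry (default 0.07, ~5 mm at the default radius). Real heads are
#'   strongly front-back asymmetric; without this term the surface has
#'   approximate rotational symmetries at the patch-grid spacing and a
#'   rotated head can alias onto the true one.
#' @return A [cortical_mesh()].
#' @export
synthetic_cortex_mesh <- function(n_vertices = 500, radius = 70, deform = 0.08,
                                  fold = 0.14, asym = 0.07) {
  stopifnot(n_vertices >= 8, radius > 0, deform >= 0, deform < 0.5,
            fold >= 0, fold < 0.25, asym >= 0, asym < 0.25)
  # rings x segments + 2 poles ~= n_vertices, with segments ~ 2 x rings
  n_ring <- max(3L, round(sqrt((n_vertices - 2) / 2)))
  n_seg <- max(4L, round((n_vertices - 2) / n_ring))
  theta <- pi * seq_len(n_ring) / (n_ring + 1)          # polar angle
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg          # azimuth
  g <- expand.grid(phi = phi, theta = theta)
  th <- g$theta; ph <- g$phi
  rmod <- function(th, ph)
    radius * (1 + deform * (0.5 * sin(2 * th) * cos(2 * ph - 0.9) +
                            0.3 * cos(3 * th) +
                            0.2 * sin(th) * sin(3 * ph + 0.7)) +
                  asym * sin(th) * cos(ph - 0.6) +
                  fold * sin(th) * (sin(7 * th) * cos(5 * ph - 1.2) +
                                    0.7 * cos(6 * th) * sin(4 * ph + 0.4)))
  r <- rmod(th, ph)
  vertices <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  # the sphere is left open at the poles: closing it with vertex fans would
  # create high-degree vertices whose normals are exactly radial by
  # symmetry -- externally silent dipoles with pathological reconstruction
  idx <- function(i, j) (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  faces <- vector("list", 2 * (n_ring - 1) * n_seg)
  k <- 0L
  for (i in seq_len(n_ring - 1)) { # quad strips
    for (j in seq_len(n_seg)) {
      k <- k + 1L; faces[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      k <- k + 1L; faces[[k]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  faces <- do.call(rbind, faces)
  m <- cortical_mesh(vertices, faces)
  # orient normals outward (away from centroid)
  ctr <- colMeans(m$vertices)
  out <- rowSums((m$vertices - matrix(ctr, nrow(m$vertices), 3, byrow = TRUE)) * m$normals)
  flip <- out < 0
  if (any(flip)) m$normals[flip, ] <- -m$normals[flip, ]
  m
}

#' Sparse vertex adjacency of a mesh
#'
#' @param mesh A [cortical_mesh()].
#' @return A symmetric sparse 0/1 adjacency `Matrix`.
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  A@x[] <- 1
  methods::as(A, "generalMatrix")
}

#' Least-squares sphere fit to mesh vertices
#'
#' Fits centre and radius of the homogeneous spherical conductor used by the
#' analytic forward model, by linear least squares on
#' `|x|^2 = 2 c.x + (R^2 - |c|^2)`.
#'
#' @param mesh A [cortical_mesh()] or an `n x 3` matrix of points.
#' @return List with `center` (3-vector, mm) and `radius` (mm).
#' @export
fit_conductor_sphere <- function(mesh) {
  V <- if (inherits(mesh, "cortical_mesh")) mesh$vertices else as.matrix(mesh)
  b <- rowSums(V^2)
  X <- cbind(2 * V, 1)
  beta <- qr.solve(X, b)
  center <- beta[1:3]
  radius <- sqrt(beta[4] + sum(center^2))
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Read / write a Wavefront OBJ surface
#'
#' Minimal OBJ support for triangle meshes with per-vertex normals
#' (`v`, `vn` and `f` records; `f` may use `i`, `i//k` or `i/j/k` forms).
#'
#' @param path File path.
#' @return `read_obj()` returns a [cortical_mesh()].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines); nl <- grep("^vn ", lines); fl <- grep("^f ", lines)
  parse_num <- function(ids, what) {
    out <- matrix(NA_real_, length(ids), 3)
    for (q in seq_along(ids)) {
      parts <- strsplit(trimws(lines[ids[q]]), "[[:space:]]+")[[1]][-1]
      v <- suppressWarnings(as.numeric(parts[1:3]))
      if (any(is.na(v)))
        stop(sprintf("corrupt OBJ '%s': cannot parse %s at line %d", path, what, ids[q]),
             call. = FALSE)
      out[q, ] <- v
    }
    out
  }
  if (!length(vl) || !length(fl))
    stop(sprintf("corrupt OBJ '%s': no vertices or no faces", path), call. = FALSE)
  verts <- parse_num(vl, "vertex")
  norms <- if (length(nl)) parse_num(nl, "normal") else NULL
  faces <- matrix(NA_integer_, length(fl), 3)
  for (q in seq_along(fl)) {
    parts <- strsplit(trimws(lines[fl[q]]), "[[:space:]]+")[[1]][-1]
    if (length(parts) != 3)
      stop(sprintf("corrupt OBJ '%s': non-triangle face at line %d", path, fl[q]), call. = FALSE)
    v <- suppressWarnings(as.integer(vapply(strsplit(parts, "/"), `[`, "", 1)))
    if (any(is.na(v)))
      stop(sprintf("corrupt OBJ '%s': cannot parse face at line %d", path, fl[q]), call. = FALSE)
    faces[q, ] <- v
  }
  cortical_mesh(verts, faces, normals = norms)
}

#' @rdname read_obj
#' @param mesh A [cortical_mesh()] to write.
#' @return `write_obj()` returns `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# megcoreg cortical surface (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %.9g %.9g %.9g", mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$faces[, 1], mesh$faces[, 1],
                     mesh$faces[, 2], mesh$faces[, 2],
                     mesh$faces[, 3], mesh$faces[, 3]), con)
  invisible(path)
}
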