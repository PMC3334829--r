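#' MEG sensor array
#'
#' Point-magnetometer positions and orientations in the device frame, plus
#' the spherical conductor (centre, radius) used by the analytic forward
#' model. All sensors must lie strictly outside the conductor sphere.
#'
#' @param positions `n x 3` matrix, mm, device frame.
#' @param orientations `n x 3` matrix of unit vectors (pickup direction).
#' @param conductor_center 3-vector, mm.
#' @param conductor_radius Scalar, mm.
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, conductor_center, conductor_radius) {
  positions <- as.matrix(positions); storage.mode(positions) <- "double"
  orientations <- as.matrix(orientations); storage.mode(orientations) <- "double"
  if (ncol(positions) != 3L || !all(dim(positions) == dim(orientations)))
    stop("positions and orientations must be matching n x 3 matrices", call. = FALSE)
  if (!all(is.finite(positions)) || !all(is.finite(orientations)))
    stop("sensor geometry must be finite", call. = FALSE)
  len <- sqrt(rowSums(orientations^2))
  if (any(len == 0)) stop("zero-length sensor orientation", call. = FALSE)
  orientations <- orientations / len
  conductor_center <- as.numeric(conductor_center)
  stopifnot(length(conductor_center) == 3L, conductor_radius > 0)
  d <- sqrt(rowSums(sweep(positions, 2, conductor_center)^2))
  if (any(d <= conductor_radius))
    stop("all sensors must lie strictly outside the conductor sphere", call. = FALSE)
  dimnames(positions) <- dimnames(orientations) <- NULL
  structure(list(positions = positions, orientations = orientations,
                 conductor_center = conductor_center,
                 conductor_radius = conductor_radius),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors; conductor r = %.1f mm at (%.1f, %.1f, %.1f)\n",
              nrow(x$positions), x$conductor_radius,
              x$conductor_center[1], x$conductor_center[2], x$conductor_center[3]))
  invisible(x)
}

#' @export
as_tibble.sensor_array <- function(x, ...) {
  p <- x$positions; o <- x$orientations
  tibble::tibble(
    sensor = seq_len(nrow(p)),
    x = p[, 1], y = p[, 2], z = p[, 3],
    ox = o[, 1], oy = o[, 2], oz = o[, 3]
  )
}

#' Synthetic helmet-like sensor array
#'
#' Radially oriented point magnetometers on a spherical cap above the head,
#' laid out with a golden-angle (Fibonacci) spiral for even coverage.
#'
#' @param n_sensors Number of sensors (default 60; 274 at full scale).
#' @param radius Helmet radius, mm (default 105).
#' @param center Helmet/conductor centre, mm (default origin).
#' @param zmin_frac Lower edge of the cap as a fraction of the radius
#'   (default -0.35: the cap extends a little below the equator).
#' @param conductor_radius Conductor sphere radius, mm (default 75).
#' @return A [sensor_array()].
#' @export
synthetic_sensor_array <- function(n_sensors = 60, radius = 105, center = c(0, 0, 0),
                                   zmin_frac = -0.35, conductor_radius = 75) {
  stopifnot(n_sensors >= 4, radius > conductor_radius)
  i <- seq_len(n_sensors)
  z <- zmin_frac + (1 - zmin_frac) * (i - 0.5) / n_sensors
  phi <- pi * (3 - sqrt(5)) * (i - 1)  # golden angle
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(phi), rho * sin(phi), z)
  pos <- sweep(radius * u, 2, center, `+`)
  sensor_array(pos, u, conductor_center = center, conductor_radius = conductor_radius)
}

#' Default fiducials for the synthetic head
#'
#' Nasion on the anterior (+y) surface, preauricular points laterally,
#' expressed in the head/device reference frame of the synthetic mesh.
#'
#' @param radius Nominal head radius, mm (default 70).
#' @return A [fiducial_set()].
#' @export
default_fiducials <- function(radius = 70) {
  fiducial_set(
    nasion = c(0, 1.05 * radius, -5),
    left_ear = c(-1.02 * radius, 0, -12),
    right_ear = c(1.02 * radius, 0, -12)
  )
}

#' Read / write sensor layouts
#'
#' JSON carries positions, orientations and the conductor sphere; CSV
#' carries one row per sensor (`x,y,z,ox,oy,oz`) and the conductor must be
#' supplied by the caller on read.
#'
#' @param path File path.
#' @return A [sensor_array()] (readers); `path` invisibly (writers).
#' @export
read_sensors_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("positions", "orientations", "conductor_center", "conductor_radius")
  miss <- setdiff(req, names(j))
  if (length(miss))
    stop("sensor JSON '", path, "' missing fields: ", paste(miss, collapse = ", "), call. = FALSE)
  sensor_array(j$positions, j$orientations, j$conductor_center, j$conductor_radius)
}

#' @rdname read_sensors_json
#' @param sensors A [sensor_array()].
#' @export
write_sensors_json <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  jsonlite::write_json(
    list(positions = sensors$positions, orientations = sensors$orientations,
         conductor_center = sensors$conductor_center,
         conductor_radius = sensors$conductor_radius),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname read_sensors_json
#' @param conductor_center,conductor_radius Conductor sphere for the CSV
#'   reader (not represented in the flat CSV).
#' @export
read_sensors_csv <- function(path, conductor_center, conductor_radius) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("x", "y", "z", "ox", "oy", "oz")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("sensor CSV '", path, "' missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sensor_array(as.matrix(d[, c("x", "y", "z")]), as.matrix(d[, c("ox", "oy", "oz")]),
               conductor_center, conductor_radius)
}

#' @rdname read_sensors_json
#' @export
write_sensors_csv <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  readr::write_csv(as_tibble(sensors)[, c("x", "y", "z", "ox", "oy", "oz")], path)
  invisible(path)
}

#' Read / write fiducials as JSON
#'
#' Keys `nasion`, `lpa`, `rpa`, coordinates in mm.
#'
#' @param path File path.
#' @return A [fiducial_set()] (reader); `path` invisibly (writer).
#' @export
read_fiducials_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(c("nasion", "lpa", "rpa"), names(j))
  if (length(miss))
    stop("fiducial JSON '", path, "' missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  fiducial_set(j$nasion, j$lpa, j$rpa)
}

#' @rdname read_fiducials_json
#' @param fids A [fiducial_set()].
#' @export
write_fiducials_json <- function(fids, path) {
  stopifnot(inherits(fids, "fiducial_set"))
  jsonlite::write_json(list(nasion = fids$nasion, lpa = fids$left_ear, rpa = fids$right_ear),
                       path, digits = NA)
  invisible(path)
}
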