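# Config, logging and result-file plumbing for the command-line pipeline.

run_config_schema <- function() {
  list(
    seed = "integer",
    scale = "character",
    paths = list(mesh = "character", sensors = "character", fiducials = "character",
                 data = "character", out = "character"),
    simulation = list(n_sources = "numeric", freq_hz = "numeric", fwhm = "numeric",
                      snr_db = "numeric", n_time = "numeric", dt = "numeric",
                      amplitude = "numeric"),
    geometry = list(n_dipoles = "numeric", n_sensors = "numeric",
                    n_modes = "numeric", n_components = "numeric",
                    smoothing = "numeric"),
    search = list(proposal_sd = "numeric", n_chains = "numeric",
                  min_samples = "numeric", rhat_tol = "numeric",
                  max_samples = "numeric"),
    prior = list(sigma = "numeric", rotation_range = "numeric",
                 init_rotation = "numeric"),
    inversion = list(alpha = "numeric", tol = "numeric", max_iter = "numeric",
                     prune_tol = "numeric"),
    bma = list(n_draws = "numeric", occam = "numeric", mode = "character")
  )
}

check_section <- function(cfg, schema, path = "") {
  extra <- setdiff(names(cfg), names(schema))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (nm in names(cfg)) {
    want <- schema[[nm]]
    got <- cfg[[nm]]
    if (is.list(want)) {
      if (!is.list(got))
        stop("configuration section '", path, nm, "' must be a mapping", call. = FALSE)
      check_section(got, want, paste0(path, nm, "."))
    } else if (!is.null(got)) {
      ok <- switch(want,
                   numeric = is.numeric(got),
                   integer = is.numeric(got) && all(got == round(got)),
                   character = is.character(got),
                   TRUE)
      if (!ok)
        stop("configuration key '", path, nm, "' must be of type ", want, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Defaults for the pipeline configuration
#'
#' Paper-scale values are behind `scale = "paper"`; the default `"test"`
#' scale is the reduced desk-scale geometry.
#'
#' @param scale `"test"` or `"paper"`.
#' @return Nested list of defaults.
#' @export
default_run_config <- function(scale = c("test", "paper")) {
  scale <- match.arg(scale)
  geo <- if (scale == "paper")
    list(n_dipoles = 8196, n_sensors = 274, n_modes = 100, n_components = 512,
         smoothing = NULL)
  else
    list(n_dipoles = 500, n_sensors = 60, n_modes = 40, n_components = 64,
         smoothing = NULL)
  list(
    seed = 1L,
    scale = scale,
    paths = list(out = "megcoreg_run"),
    simulation = list(n_sources = 3, freq_hz = c(20, 20, 10), fwhm = 10,
                      snr_db = 0, n_time = 161, dt = 0.005, amplitude = 1),
    geometry = geo,
    search = list(proposal_sd = 2.4 / sqrt(6), n_chains = 4, min_samples = 100,
                  rhat_tol = 1.1, max_samples = 300),
    prior = list(sigma = 20, rotation_range = 180, init_rotation = 15),
    inversion = list(alpha = 256, tol = 1e-3, max_iter = 128, prune_tol = 1e-8),
    bma = list(n_draws = 10000, occam = NULL, mode = "power")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys fall back to
#' [default_run_config()] for the configured scale.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top (e.g. from command-line flags).
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) stop("configuration file must be a YAML mapping", call. = FALSE)
  check_section(user, run_config_schema())
  check_section(overrides, run_config_schema())
  scale <- overrides$scale %||% user$scale %||% "test"
  cfg <- merge_config(default_run_config(scale), user)
  cfg <- merge_config(cfg, overrides)
  cfg
}

#' Write / read a chain trace as CSV
#'
#' Columns: iteration, the six rigid-body coordinates, `F`, `accepted`.
#'
#' @param chain A `metropolis_chain` (or its trace tibble).
#' @param path Output CSV.
#' @return `path` invisibly (writer); a trace tibble (reader).
#' @export
write_chain_csv <- function(chain, path) {
  tr <- if (inherits(chain, "metropolis_chain")) chain$trace else chain
  readr::write_csv(tr, path)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
read_chain_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(accepted = readr::col_logical()))
}

#' Write a sensors-by-time data matrix as TSV
#'
#' One row per sensor, one column per sample, 9 significant digits.
#'
#' @param Y Numeric matrix.
#' @param path Output TSV.
#' @return `path` invisibly.
#' @export
write_data_tsv <- function(Y, path) {
  df <- tibble::as_tibble(as.data.frame(signif(as.matrix(Y), 9)),
                          .name_repair = "minimal")
  names(df) <- paste0("t", seq_len(ncol(df)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_data_tsv
#' @export
read_data_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' Serialise an inversion result
#'
#' JSON header (free energy split, hyperparameters, convergence) plus a
#' per-vertex TSV of source power and posterior variance.
#'
#' @param fit An `msp_fit` (sources are computed if absent).
#' @param dir Output directory.
#' @param stem File stem (default "inversion").
#' @return Paths, invisibly.
#' @export
write_inversion <- function(fit, dir, stem = "inversion") {
  fit <- compute_sources(fit)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- file.path(dir, paste0(stem, ".json"))
  table <- file.path(dir, paste0(stem, "_vertices.tsv"))
  jsonlite::write_json(list(
    F = fit$F, accuracy = fit$accuracy, complexity = fit$complexity,
    sigma2_noise = fit$sigma2_noise, converged = fit$converged,
    n_iter = fit$n_iter, lambda = unname(fit$hyper$mu)
  ), header, digits = NA, auto_unbox = TRUE)
  readr::write_tsv(tibble::tibble(
    vertex = seq_along(fit$power),
    power = signif(fit$power, 9),
    var_posterior = signif(fit$diag_Sigma_J, 9)
  ), table)
  invisible(c(header = header, table = table))
}

#' Serialise a BMA result
#'
#' JSON summary plus per-vertex TSV (mean power, variance, peak mass).
#'
#' @param bma A `bma_result`.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_bma <- function(bma, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- file.path(dir, "bma.json")
  table <- file.path(dir, "bma_vertices.tsv")
  jsonlite::write_json(list(
    n_draws = bma$n_draws, n_heads = bma$n_heads, mode = bma$mode,
    peak_vertex = which.max(bma$peak_mass), peak_mass = max(bma$peak_mass)
  ), header, digits = NA, auto_unbox = TRUE)
  readr::write_tsv(dplyr::mutate(tidy(bma),
                                 dplyr::across(dplyr::where(is.double), ~signif(.x, 9))),
                   table)
  invisible(c(header = header, table = table))
}
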