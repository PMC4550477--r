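#' Read a YAML analysis configuration
#'
#' Expected layout (all blocks optional; missing values fall back to the
#' package defaults):
#' \preformatted{
#' grid: {nx: 10, ny: 10, pitch_mm: 0.4}
#' layers:
#'   - {x_from_mm: 0.0, x_to_mm: 3.6, sigma_S_per_m: 0.3,
#'      eps_rel: 1.0e5, mu_rel: 1.0}
#' anisotropy_ratio: 1.0
#' reconstruction: {z_mm: 0.1, kc: 7.85, alpha: 0.2, pad_factor: 2,
#'                  upsample_factor: 3}
#' superresolution: {factor: 3, band_limit_frac: 1.0, max_iter: 500,
#'                   tol: 1.0e-8}
#' }
#'
#' @param path path to the YAML file.
#' @return named list with elements `geometry` ([neh_geometry()]),
#'   `medium` ([neh_medium()]), `reconstruction`, `superresolution`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gr <- cfg$grid
  if (is.null(gr)) gr <- list(nx = 10, ny = 10, pitch_mm = 0.4)
  geometry <- neh_geometry(gr$nx, gr$ny, gr$pitch_mm)
  medium <- if (is.null(cfg$layers)) {
    uniform_medium()
  } else {
    layers <- do.call(rbind, lapply(cfg$layers, function(l) {
      data.frame(x_from = l$x_from_mm, x_to = l$x_to_mm,
                 sigma = l$sigma_S_per_m, eps_rel = l$eps_rel,
                 mu_rel = if (is.null(l$mu_rel)) 1 else l$mu_rel)
    }))
    ar <- if (is.null(cfg$anisotropy_ratio)) 1 else cfg$anisotropy_ratio
    neh_medium(layers, anisotropy_ratio = ar)
  }
  rec_defaults <- list(z_mm = 0.1, kc = pi / geometry$pitch, alpha = 0.2,
                       pad_factor = 2L, upsample_factor = 3L)
  sr_defaults <- list(factor = 3L, band_limit_frac = 1, max_iter = 500L,
                      tol = 1e-8)
  merge <- function(defaults, given) {
    if (is.null(given)) return(defaults)
    defaults[names(given)] <- given
    defaults
  }
  list(geometry = geometry, medium = medium,
       reconstruction = merge(rec_defaults, cfg$reconstruction),
       superresolution = merge(sr_defaults, cfg$superresolution))
}

#' Write a recording to a directory of per-frame CSV matrices
#'
#' One CSV matrix per time step (`frame_000001.csv`, ...) plus a
#' `sidecar.yaml` describing the grid, sampling rate and medium. Intended
#' for small exchanges; large recordings are better regenerated from their
#' simulation configuration.
#'
#' @param recording an `neh_recording`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- recording$geometry
  side <- list(
    grid = list(nx = g$n_x, ny = g$n_y, pitch_mm = g$pitch),
    fs_hz = recording$fs,
    n_frames = dim(recording$voltage)[3],
    noise_sd = recording$noise_sd,
    seed = recording$seed,
    layers = lapply(seq_len(nrow(recording$medium$layers)), function(r) {
      l <- recording$medium$layers[r, ]
      list(x_from_mm = l$x_from, x_to_mm = l$x_to,
           sigma_S_per_m = l$sigma, eps_rel = l$eps_rel, mu_rel = l$mu_rel)
    }),
    anisotropy_ratio = recording$medium$anisotropy_ratio
  )
  yaml::write_yaml(side, file.path(dir, "sidecar.yaml"))
  nt <- dim(recording$voltage)[3]
  for (ti in seq_len(nt)) {
    utils::write.table(recording$voltage[, , ti],
                       file.path(dir, sprintf("frame_%06d.csv", ti)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing `sidecar.yaml` and `frame_*.csv`.
#' @return an `neh_recording` (without ground truth).
#' @export
read_recording <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "sidecar.yaml"))
  g <- neh_geometry(side$grid$nx, side$grid$ny, side$grid$pitch_mm)
  layers <- do.call(rbind, lapply(side$layers, function(l) {
    data.frame(x_from = l$x_from_mm, x_to = l$x_to_mm,
               sigma = l$sigma_S_per_m, eps_rel = l$eps_rel,
               mu_rel = l$mu_rel)
  }))
  medium <- neh_medium(layers, anisotropy_ratio = side$anisotropy_ratio)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) != side$n_frames) {
    stop("frame count does not match the sidecar", call. = FALSE)
  }
  vol <- array(0, dim = c(g$n_x, g$n_y, length(files)))
  for (ti in seq_along(files)) {
    vol[, , ti] <- as.matrix(utils::read.table(files[ti], sep = ","))
  }
  structure(list(voltage = vol,
                 time_s = (seq_along(files) - 1) / side$fs_hz,
                 fs = side$fs_hz, geometry = g, medium = medium,
                 noise_sd = side$noise_sd, seed = side$seed, truth = NULL),
            class = "neh_recording")
}
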