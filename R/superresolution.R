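#' Sampling mask of real electrodes on a fine grid
#'
#' @param n_x,n_y raw grid node counts.
#' @param factor integer upsample factor.
#' @return logical matrix of shape `(n_x * factor) x (n_y * factor)`, TRUE
#'   at nodes carrying a real measurement (a regular sublattice with
#'   `n_x * n_y` TRUE nodes).
#' @export
sampling_mask <- function(n_x, n_y, factor) {
  mask <- matrix(FALSE, nrow = n_x * factor, ncol = n_y * factor)
  mask[seq(1, by = factor, length.out = n_x),
       seq(1, by = factor, length.out = n_y)] <- TRUE
  mask
}

#' Papoulis-Gerchberg band-limited interpolation
#'
#' Inserts virtual electrodes between real ones by alternating projection:
#' enforce the known samples on the fine-grid sublattice, transform, zero
#' all spatial-frequency coefficients with `kr` above the band limit,
#' inverse-transform; repeat until the relative L2 change of the estimate
#' falls below `tol` or `max_iter` is reached. Known-sample nodes in the
#' output equal the raw values exactly (a final enforcement pass). The
#' mismatch to the known samples is non-increasing over iterations.
#'
#' @param frame an [neh_frame()] (or matrix with `geometry`) on the raw
#'   grid.
#' @param factor integer upsample factor per axis (1 returns the input).
#' @param band_limit radial band limit in rad/mm; default: the raw grid's
#'   Nyquist frequency `pi / pitch_eff` (the information-theoretic ceiling).
#'   Values above the fine-grid Nyquist are rejected.
#' @param max_iter,tol iteration cap and relative-change stopping tolerance.
#' @param crop_margin drop the fine-grid nodes beyond the last electrode
#'   row/column (default TRUE). The FFT-periodic interpolant extends
#'   `factor - 1` nodes past the real aperture; those nodes are wraparound
#'   extrapolation, not virtual electrodes *between* real ones, and carry
#'   seam artifacts. With cropping the output grid is
#'   `(n - 1) * factor + 1` nodes per axis.
#' @param geometry required when `frame` is a bare matrix.
#' @return an `neh_frame` on the fine grid, with attributes `converged`
#'   (logical; FALSE flags hitting `max_iter`, no exception is raised),
#'   `iterations`, and `residuals` (L2 mismatch to the known samples after
#'   each band-limiting step).
#' @export
pg_interpolate <- function(frame, factor = 3L, band_limit = NULL,
                           max_iter = 500L, tol = 1e-8, crop_margin = TRUE,
                           geometry = NULL) {
  if (inherits(frame, "neh_frame")) {
    geometry <- frame$geometry
    raw <- frame$values
    plane_z <- frame$plane_z
    label <- frame$label
  } else {
    if (is.null(geometry)) stop("geometry required for matrix input",
                                call. = FALSE)
    raw <- as.matrix(frame)
    plane_z <- 0
    label <- "potential"
  }
  if (factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  h_raw <- pitch_eff(geometry)
  nyq_raw <- pi / h_raw
  if (is.null(band_limit)) band_limit <- nyq_raw
  fine_geom <- neh_geometry(geometry$n_x * factor, geometry$n_y * factor,
                            pitch = geometry$pitch,
                            upsample_factor = geometry$upsample_factor * factor)
  nyq_fine <- pi / pitch_eff(fine_geom)
  if (band_limit > nyq_fine * (1 + 1e-12)) {
    stop("band_limit exceeds the fine-grid Nyquist frequency", call. = FALSE)
  }
  if (factor == 1L) {
    out <- neh_frame(raw, geometry, plane_z = plane_z, label = label)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    attr(out, "residuals") <- numeric(0)
    return(out)
  }
  mask <- sampling_mask(geometry$n_x, geometry$n_y, factor)
  lat <- build_frequency_lattice(fine_geom, pad_factor = 1L)
  inband <- lat$KR <= band_limit * (1 + 1e-12)
  complex_in <- is.complex(raw)

  x <- matrix(0 + 0i, nrow = fine_geom$n_x, ncol = fine_geom$n_y)
  residuals <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    x[mask] <- raw
    X <- stats::fft(x, inverse = TRUE)
    X[!inband] <- 0
    x_new <- stats::fft(X) / length(X)
    residuals <- c(residuals, sqrt(sum(Mod(x_new[mask] - raw)^2)))
    delta <- sqrt(sum(Mod(x_new - x)^2))
    ref <- sqrt(sum(Mod(x_new)^2))
    x <- x_new
    iterations <- it
    if (delta <= tol * max(ref, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  x[mask] <- raw  # final enforcement: real samples pass through exactly
  if (!complex_in) x <- Re(x)
  if (crop_margin) {
    nkx <- (geometry$n_x - 1L) * factor + 1L
    nky <- (geometry$n_y - 1L) * factor + 1L
    x <- x[seq_len(nkx), seq_len(nky), drop = FALSE]
    fine_geom <- neh_geometry(nkx, nky, pitch = geometry$pitch,
                              upsample_factor =
                                geometry$upsample_factor * factor)
  }
  out <- neh_frame(x, fine_geom, plane_z = plane_z, label = label)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "residuals") <- residuals
  out
}

#' Linear operator form of the PG interpolation
#'
#' Papoulis-Gerchberg interpolation with a fixed mask, band limit and
#' iteration schedule is a linear map from the raw samples to the fine
#' grid. This materialises that map as a dense matrix by running
#' [pg_interpolate()] on each raw-grid basis vector, so long frame stacks
#' can be interpolated by one matrix product. The columns follow R's
#' column-major vectorisation of the raw grid; rows that of the fine grid.
#'
#' @inheritParams pg_interpolate
#' @param n_x,n_y,pitch raw grid description.
#' @return numeric matrix with one column per raw node and one row per
#'   fine-grid node (shape depends on `crop_margin`).
#' @export
pg_matrix <- function(n_x, n_y, pitch, factor, band_limit = NULL,
                      max_iter = 500L, tol = 1e-8, crop_margin = TRUE) {
  g <- neh_geometry(n_x, n_y, pitch)
  n_raw <- n_x * n_y
  M <- NULL
  basis <- matrix(0, nrow = n_x, ncol = n_y)
  for (j in seq_len(n_raw)) {
    basis[j] <- 1
    fine <- pg_interpolate(basis, factor = factor, band_limit = band_limit,
                           max_iter = max_iter, tol = tol,
                           crop_margin = crop_margin, geometry = g)
    if (is.null(M)) M <- matrix(0, nrow = length(fine$values), ncol = n_raw)
    M[, j] <- as.vector(Re(fine$values))
    basis[j] <- 0
  }
  M
}

#' Downsample a frame by an integer step
#'
#' Keeps nodes 0, step, 2*step, ... along both axes (emulating recording
#' from only every step-th electrode); the result's pitch is `step` times
#' the input's effective pitch.
#'
#' @param frame an [neh_frame()].
#' @param step positive integer decimation step (1 = identity).
#' @return an `neh_frame` on the coarse geometry.
#' @export
downsample <- function(frame, step) {
  if (!inherits(frame, "neh_frame")) stop("frame must be an neh_frame",
                                          call. = FALSE)
  if (!is.numeric(step) || step < 1 || step != round(step)) {
    stop("step must be a positive integer", call. = FALSE)
  }
  if (step == 1L) return(frame)
  g <- frame$geometry
  ix <- seq(1, g$n_x, by = step)
  iy <- seq(1, g$n_y, by = step)
  coarse <- neh_geometry(length(ix), length(iy),
                         pitch = pitch_eff(g) * step)
  neh_frame(frame$values[ix, iy, drop = FALSE], coarse,
            plane_z = frame$plane_z, label = frame$label)
}
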