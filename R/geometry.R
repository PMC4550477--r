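#' Regular planar electrode-array geometry
#'
#' Describes a regular 2D sensor grid: number of columns along the
#' cortical-depth axis (`x`, column 0 at the pial surface), number of rows
#' along the layer axis (`y`), and the inter-electrode distance (pitch).
#' The geometry owns the spatial-frequency lattice used by all k-space
#' operations; an `upsample_factor` > 1 describes a fine grid carrying
#' virtual electrodes inserted between the real ones.
#'
#' Coordinate convention: node `(i, j)` (1-based) sits at
#' `x = (i - 1) * pitch_eff`, `y = (j - 1) * pitch_eff` in mm, where
#' `pitch_eff = pitch / upsample_factor`. The `z` axis points from the
#' recording plane into the tissue toward the reconstruction plane.
#'
#' @param n_x,n_y integer number of grid nodes along x and y (>= 2).
#' @param pitch inter-electrode distance of the *raw* array, in mm.
#' @param upsample_factor positive integer; 1 for the raw grid, m for a grid
#'   with m - 1 virtual nodes inserted between real electrodes.
#' @return An object of class `neh_geometry`.
#' @examples
#' g <- neh_geometry(10, 10, pitch = 0.4)
#' pitch_eff(g)
#' @export
neh_geometry <- function(n_x, n_y, pitch, upsample_factor = 1L) {
  if (!is.numeric(n_x) || !is.numeric(n_y) || n_x < 2 || n_y < 2 ||
      n_x != round(n_x) || n_y != round(n_y)) {
    stop("n_x and n_y must be integers >= 2", call. = FALSE)
  }
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0) {
    stop("pitch must be a positive length in mm", call. = FALSE)
  }
  if (!is.numeric(upsample_factor) || upsample_factor < 1 ||
      upsample_factor != round(upsample_factor)) {
    stop("upsample_factor must be a positive integer", call. = FALSE)
  }
  structure(
    list(n_x = as.integer(n_x), n_y = as.integer(n_y),
         pitch = as.numeric(pitch),
         upsample_factor = as.integer(upsample_factor)),
    class = "neh_geometry"
  )
}

#' @export
print.neh_geometry <- function(x, ...) {
  cat(sprintf("<neh_geometry> %d x %d grid, pitch %.4g mm (upsample x%d, effective %.4g mm)\n",
              x$n_x, x$n_y, x$pitch, x$upsample_factor, pitch_eff(x)))
  invisible(x)
}

#' Effective node spacing of a geometry in mm
#'
#' `pitch / upsample_factor`: the spacing of the (possibly upsampled) grid.
#' @param geometry an `neh_geometry`.
#' @export
pitch_eff <- function(geometry) geometry$pitch / geometry$upsample_factor

#' Node centre coordinates in mm
#'
#' @param geometry an `neh_geometry`.
#' @return list with vectors `x` (length n_x) and `y` (length n_y), in mm.
#' @export
node_coords <- function(geometry) {
  h <- pitch_eff(geometry)
  list(x = (seq_len(geometry$n_x) - 1) * h,
       y = (seq_len(geometry$n_y) - 1) * h)
}

#' Angular spatial-frequency values for one FFT axis
#'
#' @param n number of samples, `d` sample spacing in mm.
#' @return angular frequencies in rad/mm, in FFT coefficient order
#'   (DC first, then positive, then negative frequencies).
#' @keywords internal
fft_angular_freq <- function(n, d) {
  idx <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * idx / (n * d)
}

#' Build the spatial-frequency lattice of a (padded) grid
#'
#' Returns the angular spatial frequencies `kx`, `ky` (rad/mm) matching the
#' FFT coefficient layout of the geometry's grid after zero-padding each
#' axis by `pad_factor`. Frequency spacing is `2 * pi / (padded extent)`;
#' the largest magnitude approaches the Nyquist frequency
#' `pi / pitch_eff`.
#'
#' @param geometry an `neh_geometry`.
#' @param pad_factor positive integer; each axis is extended to
#'   `pad_factor * n` nodes before transforming.
#' @return list with vectors `kx` (length `pad_factor * n_x`), `ky`, the
#'   matrices `KX`, `KY` expanded to the padded grid shape, and `KR`
#'   (radial spatial frequency `sqrt(kx^2 + ky^2)`).
#' @export
build_frequency_lattice <- function(geometry, pad_factor = 1L) {
  if (!is.numeric(pad_factor) || length(pad_factor) != 1L ||
      pad_factor < 1 || pad_factor != round(pad_factor)) {
    stop("pad_factor must be a positive integer", call. = FALSE)
  }
  h <- pitch_eff(geometry)
  nx <- geometry$n_x * pad_factor
  ny <- geometry$n_y * pad_factor
  kx <- fft_angular_freq(nx, h)
  ky <- fft_angular_freq(ny, h)
  KX <- matrix(kx, nrow = nx, ncol = ny)
  KY <- matrix(ky, nrow = nx, ncol = ny, byrow = TRUE)
  list(kx = kx, ky = ky, KX = KX, KY = KY, KR = sqrt(KX^2 + KY^2))
}

#' Layered tissue electromagnetic property model
#'
#' A piecewise-constant model of tissue electromagnetic properties as bands
#' along the cortical-depth (`x`) axis: each layer carries a conductivity
#' `sigma` (S/m), relative permittivity `eps_rel` and relative permeability
#' `mu_rel`. Bands must tile the grid extent with no gaps or overlaps.
#' The shipped defaults are placeholders on the scale reported for cortical
#' grey matter, not measured ground truth.
#'
#' @param layers a data.frame with columns `x_from`, `x_to` (mm), `sigma`
#'   (S/m, >= 0), `eps_rel` (> 0), `mu_rel` (> 0). A single row describes a
#'   uniform medium.
#' @param anisotropy_ratio optional scalar: across-layer / along-layer
#'   conductivity ratio. Enters only as a rescaling of sigma in the
#'   dissipation map and wavenumber; default 1 (isotropic).
#' @return An object of class `neh_medium`.
#' @examples
#' uniform_medium(sigma = 0.3)
#' @export
neh_medium <- function(layers, anisotropy_ratio = 1) {
  req <- c("x_from", "x_to", "sigma", "eps_rel", "mu_rel")
  if (!is.data.frame(layers) || !all(req %in% names(layers))) {
    stop("layers must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  layers <- layers[order(layers$x_from), , drop = FALSE]
  if (any(layers$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(layers$eps_rel <= 0)) stop("eps_rel must be > 0", call. = FALSE)
  if (any(layers$mu_rel <= 0)) stop("mu_rel must be > 0", call. = FALSE)
  if (any(layers$x_to <= layers$x_from)) {
    stop("each layer needs x_to > x_from", call. = FALSE)
  }
  if (!is.numeric(anisotropy_ratio) || anisotropy_ratio <= 0) {
    stop("anisotropy_ratio must be > 0", call. = FALSE)
  }
  structure(list(layers = layers,
                 anisotropy_ratio = as.numeric(anisotropy_ratio)),
            class = "neh_medium")
}

#' @rdname neh_medium
#' @param sigma,eps_rel,mu_rel properties of a single uniform layer.
#' @param x_extent extent in mm covered by the layer (generous default so
#'   any desk-scale grid is covered).
#' @export
uniform_medium <- function(sigma = 0.3, eps_rel = 1e5, mu_rel = 1,
                           x_extent = 1e3) {
  neh_medium(data.frame(x_from = -x_extent, x_to = x_extent,
                        sigma = sigma, eps_rel = eps_rel, mu_rel = mu_rel))
}

#' @export
print.neh_medium <- function(x, ...) {
  cat(sprintf("<neh_medium> %d layer band(s), anisotropy ratio %.3g\n",
              nrow(x$layers), x$anisotropy_ratio))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Evaluate the layered medium on a grid
#'
#' Maps each grid node to the properties of the layer band containing its
#' centre x coordinate. Layer bands must cover the grid's x extent with no
#' gaps or overlaps; a node falling in a gap or in two bands raises a
#' configuration error naming the offending band edge.
#'
#' @param medium an `neh_medium`.
#' @param geometry an `neh_geometry`.
#' @return list of three `n_x x n_y` matrices: `sigma`, `eps_rel`, `mu_rel`.
#' @export
medium_at_plane <- function(medium, geometry) {
  xs <- node_coords(geometry)$x
  L <- medium$layers
  sig <- eps <- mu <- numeric(length(xs))
  for (i in seq_along(xs)) {
    # half-open bands [x_from, x_to); the last band is closed at its top edge
    inband <- which(L$x_from <= xs[i] &
                      (xs[i] < L$x_to | (xs[i] == L$x_to & L$x_to == max(L$x_to))))
    if (length(inband) == 0L) {
      stop(sprintf("medium layer bands leave a gap: node centre x = %.4g mm is uncovered",
                   xs[i]), call. = FALSE)
    }
    if (length(inband) > 1L) {
      stop(sprintf("medium layer bands overlap at x = %.4g mm (bands starting at %s mm)",
                   xs[i], paste(L$x_from[inband], collapse = ", ")),
           call. = FALSE)
    }
    sig[i] <- L$sigma[inband]
    eps[i] <- L$eps_rel[inband]
    mu[i] <- L$mu_rel[inband]
  }
  ny <- geometry$n_y
  list(sigma = matrix(sig, nrow = geometry$n_x, ncol = ny),
       eps_rel = matrix(eps, nrow = geometry$n_x, ncol = ny),
       mu_rel = matrix(mu, nrow = geometry$n_x, ncol = ny))
}

#' Plane-mean medium properties
#'
#' The k-space propagator assumes a laterally homogeneous plane, so the
#' characteristic wavenumber is built from the spatial mean of the property
#' maps; the per-node sigma map is used only by the dissipation formula.
#'
#' @inheritParams medium_at_plane
#' @return list with scalars `sigma`, `eps_rel`, `mu_rel`.
#' @export
mean_medium <- function(medium, geometry) {
  m <- medium_at_plane(medium, geometry)
  list(sigma = mean(m$sigma), eps_rel = mean(m$eps_rel),
       mu_rel = mean(m$mu_rel))
}
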