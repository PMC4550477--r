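#' Scalar field frame on a grid
#'
#' A complex-valued scalar field sampled on the nodes of an
#' [neh_geometry()] grid at one time instant or one temporal frequency.
#'
#' @param values numeric or complex matrix of shape `n_x x n_y`.
#' @param geometry the `neh_geometry` the values are sampled on.
#' @param plane_z depth of the plane in mm (0 = recording plane).
#' @param label role tag: "potential", "esd", "dissipation",
#'   "kspace-magnitude" or any descriptive string.
#' @return object of class `neh_frame`.
#' @export
neh_frame <- function(values, geometry, plane_z = 0, label = "potential") {
  if (!inherits(geometry, "neh_geometry")) {
    stop("geometry must be an neh_geometry", call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_x || ncol(values) != geometry$n_y) {
    stop(sprintf("values shape %d x %d does not match geometry %d x %d",
                 nrow(values), ncol(values), geometry$n_x, geometry$n_y),
         call. = FALSE)
  }
  structure(list(values = values, geometry = geometry,
                 plane_z = plane_z, label = label),
            class = "neh_frame")
}

#' @export
print.neh_frame <- function(x, ...) {
  cat(sprintf("<neh_frame '%s'> %d x %d at z = %.4g mm, %s values\n",
              x$label, nrow(x$values), ncol(x$values), x$plane_z,
              if (is.complex(x$values)) "complex" else "real"))
  invisible(x)
}

#' Vector field frame on a grid
#'
#' Three complex components per node: `x` (cortical depth), `y`
#' (along-layer), `z` (plane normal). All three matrices share the grid
#' shape.
#'
#' @param vx,vy,vz matrices of shape `n_x x n_y` (numeric or complex).
#' @inheritParams neh_frame
#' @return object of class `neh_vfield`.
#' @export
neh_vfield <- function(vx, vy, vz, geometry, plane_z = 0, label = "E") {
  if (!inherits(geometry, "neh_geometry")) {
    stop("geometry must be an neh_geometry", call. = FALSE)
  }
  comps <- lapply(list(vx, vy, vz), as.matrix)
  for (m in comps) {
    if (nrow(m) != geometry$n_x || ncol(m) != geometry$n_y) {
      stop("all vector components must match the geometry grid shape",
           call. = FALSE)
    }
  }
  structure(list(vx = comps[[1]], vy = comps[[2]], vz = comps[[3]],
                 geometry = geometry, plane_z = plane_z, label = label),
            class = "neh_vfield")
}

#' @export
print.neh_vfield <- function(x, ...) {
  cat(sprintf("<neh_vfield '%s'> %d x %d x 3 at z = %.4g mm\n",
              x$label, nrow(x$vx), ncol(x$vx), x$plane_z))
  invisible(x)
}

#' Forward spatial Fourier transform of a frame
#'
#' Transforms grid values to the spatial-frequency domain with the kernel
#' `exp(+i kx x) exp(+i ky y)` (the convention used throughout the k-space
#' pipeline; note this is the sign-conjugate of R's `fft` default).
#' Optionally zero-pads each axis by an integer factor first. The inverse,
#' [kspace_inverse()], restores the original frame to floating precision.
#'
#' @param values numeric/complex matrix.
#' @param pad_factor positive integer zero-padding factor per axis.
#' @return object of class `neh_kspace`: list with complex `coef` (padded
#'   shape), `pre_pad_shape`, `pad_factor`.
#' @export
kspace_forward <- function(values, pad_factor = 1L) {
  values <- as.matrix(values)
  n <- dim(values)
  if (pad_factor < 1 || pad_factor != round(pad_factor)) {
    stop("pad_factor must be a positive integer", call. = FALSE)
  }
  if (pad_factor > 1) {
    padded <- matrix(0 + 0i, nrow = n[1] * pad_factor, ncol = n[2] * pad_factor)
    padded[seq_len(n[1]), seq_len(n[2])] <- values
    values <- padded
  }
  # kernel e^{+ik.x}: R's fft(inverse = TRUE) is the unnormalised +i transform
  structure(list(coef = stats::fft(values, inverse = TRUE),
                 pre_pad_shape = n, pad_factor = as.integer(pad_factor)),
            class = "neh_kspace")
}

#' Inverse spatial Fourier transform
#'
#' @param ks an `neh_kspace` from [kspace_forward()].
#' @param crop if TRUE (default) remove the zero-padding region, returning
#'   the pre-pad shape.
#' @return complex matrix.
#' @export
kspace_inverse <- function(ks, crop = TRUE) {
  vals <- stats::fft(ks$coef) / length(ks$coef)
  if (crop && ks$pad_factor > 1) {
    vals <- vals[seq_len(ks$pre_pad_shape[1]), seq_len(ks$pre_pad_shape[2]),
                 drop = FALSE]
  }
  vals
}
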