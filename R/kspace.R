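#' Physical constants (SI)
#' @keywords internal
.eps0 <- 8.8541878128e-12  # vacuum permittivity, F/m
#' @keywords internal
.mu0 <- 4e-7 * pi          # vacuum permeability, H/m

#' Complex permittivity of a conductive medium
#'
#' `eps_hat = eps * (1 + i * sigma / (omega * eps)) = eps + i * sigma / omega`.
#' Conduction enters as the imaginary part `sigma / omega`, independent of
#' `eps`. The function is unit-agnostic: pass absolute permittivity to get
#' absolute complex permittivity (see [tissue_wavenumber()] for the version
#' that applies the vacuum-permittivity factor to a relative value).
#'
#' @param sigma conductivity (>= 0).
#' @param eps permittivity (> 0).
#' @param omega angular temporal frequency in rad/s (> 0; a DC value has no
#'   finite loss tangent and is rejected).
#' @return complex permittivity.
#' @export
complex_permittivity <- function(sigma, eps, omega) {
  if (any(omega <= 0)) stop("omega must be > 0", call. = FALSE)
  if (any(eps <= 0)) stop("eps must be > 0", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  eps + 1i * sigma / omega
}

#' Characteristic wavenumber of a (lossy) medium
#'
#' `k = omega * sqrt(mu * eps_hat)`, principal square-root branch
#' (`Re(k) >= 0`). For `sigma > 0` the imaginary part of `k` is positive:
#' the medium attenuates. Unit-agnostic companion of [tissue_wavenumber()].
#'
#' @param eps_hat complex permittivity (from [complex_permittivity()]).
#' @param mu permeability (> 0).
#' @param omega angular temporal frequency in rad/s.
#' @return complex wavenumber.
#' @export
characteristic_wavenumber <- function(eps_hat, mu, omega) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  omega * sqrt(as.complex(mu * eps_hat))
}

#' Characteristic wavenumber of tissue, in rad/mm
#'
#' Applies the vacuum permittivity/permeability factors to relative
#' properties and converts to the package's internal spatial unit
#' (rad/mm). At delta-band frequencies and physiological conductivities
#' `|k|` is tiny compared with the array's spatial-frequency lattice, so
#' virtually all lattice modes are evanescent (near-field).
#'
#' @param sigma conductivity in S/m.
#' @param eps_rel relative permittivity.
#' @param mu_rel relative permeability.
#' @param omega angular temporal frequency in rad/s.
#' @param anisotropy_ratio optional scalar rescaling of sigma (across/along
#'   layer conductivity ratio folded into the effective wavenumber).
#' @return complex wavenumber in rad/mm.
#' @export
tissue_wavenumber <- function(sigma, eps_rel, mu_rel = 1, omega,
                              anisotropy_ratio = 1) {
  eps_hat <- complex_permittivity(sigma * anisotropy_ratio,
                                  .eps0 * eps_rel, omega)
  k_si <- characteristic_wavenumber(eps_hat, .mu0 * mu_rel, omega)  # rad/m
  k_si / 1000
}

#' Normal (out-of-plane) wavenumber per lattice node
#'
#' For each spatial-frequency node, `kz = sqrt(k^2 - kx^2 - ky^2)` on the
#' far-field branch (`kx^2 + ky^2 <= |k|^2`) and
#' `kz = -i * sqrt(kx^2 + ky^2 - k^2)` on the evanescent near-field branch.
#' Principal square roots throughout; with the `-i` near-field sign the
#' propagator `exp(-i kz z)` always decays with distance on evanescent
#' nodes. For lossy media (`k` complex) the branch comparison uses
#' `|k|^2`, which reduces continuously to the printed lossless rule.
#'
#' @param k complex characteristic wavenumber (rad/mm).
#' @param KX,KY matrices of angular spatial frequencies (rad/mm) from
#'   [build_frequency_lattice()].
#' @return list with complex matrix `kz` and character matrix `branch`
#'   ("far-field" or "near-field").
#' @export
normal_wavenumber <- function(k, KX, KY) {
  kr2 <- KX^2 + KY^2
  far <- kr2 <= Mod(k)^2
  kz <- matrix(0 + 0i, nrow = nrow(KX), ncol = ncol(KX))
  kz[far] <- sqrt(as.complex(k^2 - kr2[far]))
  kz[!far] <- -1i * sqrt(as.complex(kr2[!far] - k^2))
  branch <- matrix("near-field", nrow = nrow(KX), ncol = ncol(KX))
  branch[far] <- "far-field"
  list(kz = kz, branch = branch)
}

#' Smooth k-space low-pass filter
#'
#' The reconstruction filter controlling how much amplified evanescent
#' content enters the back-projection:
#' \deqn{gain = 1 - 0.5 e^{(k_r/k_c - 1)/\alpha} \quad (k_r \le k_c)}
#' \deqn{gain = 0.5 e^{(1 - k_r/k_c)/\alpha} \quad (k_r > k_c)}
#' with `kr = sqrt(kx^2 + ky^2)`. The gain is continuous (both branches
#' give 0.5 at `kr = kc`), bounded in [0, 1], and monotonically
#' non-increasing in `kr`; larger `alpha` flattens the transition.
#'
#' @param KR matrix of radial spatial frequencies (rad/mm), or a numeric
#'   vector for pointwise evaluation.
#' @param kc cutoff spatial frequency in rad/mm (> 0).
#' @param alpha dimensionless roll-off steepness (> 0).
#' @return gain array of the same shape as `KR`.
#' @export
kspace_filter <- function(KR, kc, alpha) {
  if (!is.numeric(kc) || length(kc) != 1L || kc <= 0) {
    stop("kc must be a positive spatial frequency", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be > 0", call. = FALSE)
  }
  u <- KR / kc
  ifelse(u <= 1, 1 - 0.5 * exp((u - 1) / alpha), 0.5 * exp((1 - u) / alpha))
}

#' K-space propagator gain per node
#'
#' `Gz = exp(-i kz z)`: unit modulus on real-kz (far-field) nodes and
#' `exp(-kappa z) < 1` on evanescent nodes (`kz = -i kappa`), for `z > 0`.
#'
#' @param kz complex normal wavenumber (rad/mm), from [normal_wavenumber()].
#' @param z propagation distance in mm (>= 0).
#' @return complex gain array shaped like `kz`.
#' @export
propagator_gain <- function(kz, z) {
  if (z < 0) stop("z must be >= 0 (propagation direction is fixed)",
                  call. = FALSE)
  exp(-1i * kz * z)
}

#' Propagate a field frame between parallel planes in k-space
#'
#' Implements the angular-spectrum step shared by the forward simulator and
#' the holographic back-projection: remove the frame mean, zero-pad each
#' axis by `pad_factor` (to limit spectral leakage), forward-transform,
#' multiply nodewise by the propagator `exp(-i kz z)` and the k-space
#' filter gain, inverse-transform, crop the padding, and route the mean
#' through the DC channel (DC propagator times DC filter gain). With
#' `z = 0` and an all-pass filter the output equals the input.
#'
#' With `invert = FALSE` (the default) the decaying propagator `Gz` carries
#' fields away from their sources, as in the forward simulator. With
#' `invert = TRUE` the inverse propagator `1/Gz = exp(+i kz z)` is applied:
#' this is the holographic back-projection, which undoes the evanescent
#' decay accumulated over depth `z` and thereby refocuses source structure;
#' the amplification it implies on high spatial frequencies is tamed by the
#' k-space filter, which is mandatory in that mode. In both modes `z >= 0`
#' is the distance between the planes.
#'
#' @param frame an [neh_frame()], or a plain matrix together with
#'   `geometry`.
#' @param z propagation distance in mm (>= 0).
#' @param k complex characteristic wavenumber in rad/mm (see
#'   [tissue_wavenumber()]).
#' @param filter either NULL (all-pass) or a list with elements `kc` and
#'   `alpha` for [kspace_filter()]. Required when `invert = TRUE`.
#' @param pad_factor zero-padding factor per axis (default 2).
#' @param invert apply the inverse propagator `exp(+i kz z)`
#'   (back-projection) instead of the decaying `exp(-i kz z)`.
#' @param geometry required when `frame` is a bare matrix.
#' @return propagated frame of the same class as the input, `plane_z`
#'   advanced by `z` when the input is an `neh_frame`.
#' @export
propagate <- function(frame, z, k, filter = NULL, pad_factor = 2L,
                      invert = FALSE, geometry = NULL) {
  if (inherits(frame, "neh_frame")) {
    geometry <- frame$geometry
    values <- frame$values
  } else {
    if (is.null(geometry)) stop("geometry required for matrix input",
                                call. = FALSE)
    values <- as.matrix(frame)
    if (nrow(values) != geometry$n_x || ncol(values) != geometry$n_y) {
      stop("frame shape does not match geometry", call. = FALSE)
    }
  }
  if (z < 0) stop("z must be >= 0 (propagation direction is fixed)",
                  call. = FALSE)
  if (invert && z > 0 && is.null(filter)) {
    stop("back-projection (invert = TRUE) requires a k-space filter to bound the evanescent amplification",
         call. = FALSE)
  }
  lat <- build_frequency_lattice(geometry, pad_factor = pad_factor)
  kz <- normal_wavenumber(k, lat$KX, lat$KY)$kz
  gain <- propagator_gain(kz, z)
  if (invert) gain <- 1 / gain
  if (!is.null(filter)) {
    gain <- gain * kspace_filter(lat$KR, filter$kc, filter$alpha)
  }
  m <- mean(values)
  ks <- kspace_forward(values - m, pad_factor = pad_factor)
  ks$coef <- ks$coef * gain
  out <- kspace_inverse(ks, crop = TRUE)
  # re-centre the residual and route the mean through the DC channel so the
  # propagated frame never gains energy
  out <- out - mean(out) + m * gain[1, 1]
  if (inherits(frame, "neh_frame")) {
    neh_frame(out, geometry, plane_z = frame$plane_z + z, label = frame$label)
  } else {
    out
  }
}

#' Propagate a vector field frame component-wise
#'
#' @param vfield an [neh_vfield()].
#' @inheritParams propagate
#' @return an `neh_vfield` at `plane_z + z`.
#' @export
propagate_vfield <- function(vfield, z, k, filter = NULL, pad_factor = 2L,
                             invert = FALSE) {
  g <- vfield$geometry
  comps <- lapply(list(vfield$vx, vfield$vy, vfield$vz), propagate,
                  z = z, k = k, filter = filter, pad_factor = pad_factor,
                  invert = invert, geometry = g)
  neh_vfield(comps[[1]], comps[[2]], comps[[3]], g,
             plane_z = vfield$plane_z + z, label = vfield$label)
}
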