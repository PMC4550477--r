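#' Continuous wavelet transform with an analytic Morlet wavelet
#'
#' FFT-based CWT at the requested centre frequencies (Torrence-Compo style
#' scale/frequency relation for the Morlet wavelet with centre-frequency
#' parameter `omega0`). The series is mean-removed and zero-padded to the
#' next power of two before transforming.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param freqs centre frequencies in Hz at which to evaluate.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return list with complex matrix `W` (`length(x)` rows, one column per
#'   frequency), `freqs`, `scales` (s), and `coi_s` (cone-of-influence
#'   e-folding time per scale, seconds).
#' @export
cwt_morlet <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  npad <- 2^ceiling(log2(max(n, 2)))
  xx <- c(x - mean(x), rep(0, npad - n))
  fx <- stats::fft(xx)
  kk <- 0:(npad - 1)
  w <- 2 * pi * ifelse(kk <= npad / 2, kk, kk - npad) / (npad * dt)
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (freqs * fourier_factor)
  W <- matrix(0 + 0i, nrow = n, ncol = length(freqs))
  pos <- w > 0
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- numeric(npad)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * w[pos] - omega0)^2)
    W[, si] <- (stats::fft(fx * psi, inverse = TRUE) / npad)[seq_len(n)]
  }
  list(W = W, freqs = freqs, scales = scales, coi_s = sqrt(2) * scales)
}

#' Cone-of-influence validity mask for a CWT
#' @param n series length, `fs` sampling rate, `coi_s` e-folding times per
#'   scale (from [cwt_morlet()]).
#' @return logical matrix `n x length(coi_s)`: TRUE where edge effects are
#'   negligible.
#' @keywords internal
coi_mask <- function(n, fs, coi_s) {
  t <- (seq_len(n) - 1) / fs
  edge_dist <- pmin(t, t[n] - t)
  outer(edge_dist, coi_s, ">=")
}

#' Wavelet phase semblance between two time series
#'
#' Cosine of the local phase difference of the two series' Morlet wavelet
#' transforms, per time and scale: `cos(arg(Wx * conj(Wy)))^nexp`.
#' Values lie in [-1, 1]; identical series give 1 wherever amplitude is
#' nonzero, sign-flipped series give -1. The statistic is phase-only and
#' invariant to positive rescaling of either series.
#'
#' @param x,y equal-length time series at the same sampling rate.
#' @param fs sampling rate in Hz.
#' @param freqs centre frequencies (Hz); default 6 log-spaced voices over
#'   the delta band 0.5-2 Hz.
#' @param nexp odd exponent applied to the cosine (default 1).
#' @param omega0 Morlet parameter.
#' @return object of class `neh_semblance`: list with matrix `values`
#'   (time x scale), `freqs`, logical `valid` (outside the cone of
#'   influence) and scalar `mean` (mean over valid nodes).
#' @export
semblance <- function(x, y, fs, freqs = NULL, nexp = 1, omega0 = 6) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (is.null(freqs)) freqs <- exp(seq(log(0.5), log(2), length.out = 6))
  if (any(freqs <= 0) || any(freqs > fs / 2)) {
    stop("freqs must lie in (0, fs/2]", call. = FALSE)
  }
  Wx <- cwt_morlet(x, fs, freqs, omega0)
  Wy <- cwt_morlet(y, fs, freqs, omega0)
  .semblance_from_W(Wx$W, Wy$W, length(x), fs, Wx$coi_s, freqs, nexp)
}

#' @keywords internal
.semblance_from_W <- function(Wx, Wy, n, fs, coi_s, freqs, nexp = 1) {
  vals <- cos(Arg(Wx * Conj(Wy)))^nexp
  valid <- coi_mask(n, fs, coi_s)
  structure(list(values = vals, freqs = freqs, valid = valid,
                 mean = mean(vals[valid])),
            class = "neh_semblance")
}

#' @export
print.neh_semblance <- function(x, ...) {
  cat(sprintf("<neh_semblance> %d samples x %d scales (%.3g-%.3g Hz), mean %.4f\n",
              nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs),
              x$mean))
  invisible(x)
}

## Materialise a linear per-frame operator (R^(nx*ny) -> R^(nx*ny)) as a
## dense matrix by pushing basis vectors through it.
.operator_matrix <- function(fun, n) {
  basis <- numeric(n)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    basis[j] <- 1
    M[, j] <- fun(basis)
    basis[j] <- 0
  }
  M
}

#' Downsampling experiment: holographic superresolution vs interpolation
#'
#' Emulates the virtual-electrode validation protocol: the full-grid
#' recording is spatially downsampled 2-fold (every other electrode, a
#' quarter of the channels), then restored to full resolution by two
#' branches - (A) Papoulis-Gerchberg interpolation alone, and (B) the same
#' interpolation followed by holographic back-propagation to the
#' reconstruction plane. Both branch outputs are compared per electrode
#' against the original recorded series by mean wavelet phase semblance
#' over the delta scale band (cone-of-influence nodes excluded).
#'
#' All per-frame steps are linear, so both branches are materialised as
#' matrices acting on the channel dimension and applied to the full frame
#' stack at once; results are identical to per-frame processing.
#'
#' @param recording an `neh_recording` on an even-sized full grid.
#' @param z reconstruction depth in mm for branch B.
#' @param omega angular temporal frequency for the propagator.
#' @param kc filter cutoff (rad/mm); default: the Nyquist frequency of the
#'   downsampled array (the band the retained electrodes actually measure).
#' @param alpha filter roll-off.
#' @param pad_factor zero-padding for propagation.
#' @param compare_field which reconstructed quantity stands in for the
#'   voltage series in branch B: "potential" (back-propagated potential,
#'   default), "ex", "ey" (real part of a field component) or "emag"
#'   (in-plane field magnitude).
#' @param band delta scale band in Hz for the semblance summary.
#' @param n_scales number of log-spaced scales across `band`.
#' @param pg_max_iter,pg_tol PG controls.
#' @param omega0 Morlet parameter.
#' @return data.frame with one row per full-grid electrode: `i`, `j`,
#'   `sem_interp` (branch A), `sem_neh` (branch B); parameters in
#'   `attr(, "params")`.
#' @export
superresolution_experiment <- function(recording, z = 0.1,
                                       omega = 2 * pi * 1.5, kc = NULL,
                                       alpha = 0.2, pad_factor = 2L,
                                       compare_field = c("potential", "ex",
                                                         "ey", "emag"),
                                       band = c(0.5, 2), n_scales = 6,
                                       pg_max_iter = 500L, pg_tol = 1e-8,
                                       omega0 = 6) {
  compare_field <- match.arg(compare_field)
  g <- recording$geometry
  if (g$n_x %% 2 != 0 || g$n_y %% 2 != 0) {
    stop("grid must be even-sized for 2-fold downsampling", call. = FALSE)
  }
  vol <- recording$voltage
  nt <- dim(vol)[3]
  nv <- g$n_x * g$n_y
  orig <- matrix(vol, nrow = nv, ncol = nt)
  cix <- seq(1, g$n_x, by = 2)
  ciy <- seq(1, g$n_y, by = 2)
  coarse <- matrix(vol[cix, ciy, , drop = FALSE],
                   nrow = length(cix) * length(ciy), ncol = nt)
  cpitch <- pitch_eff(g) * 2
  if (is.null(kc)) kc <- pi / cpitch

  # branch A: PG interpolation back to the full grid
  Mpg <- pg_matrix(length(cix), length(ciy), cpitch, factor = 2,
                   band_limit = pi / cpitch, max_iter = pg_max_iter,
                   tol = pg_tol, crop_margin = FALSE)
  A <- Mpg %*% coarse

  # branch B: holographic back-propagation of the interpolated frames
  props <- mean_medium(recording$medium, g)
  k <- tissue_wavenumber(props$sigma, props$eps_rel, props$mu_rel, omega,
                         anisotropy_ratio = recording$medium$anisotropy_ratio)
  flt <- list(kc = kc, alpha = alpha)
  prop_vec <- function(vec) {
    as.vector(Re(propagate(matrix(vec, g$n_x, g$n_y), z = z, k = k,
                           filter = flt, pad_factor = pad_factor,
                           invert = TRUE, geometry = g)))
  }
  grad_vec <- function(vec, comp) {
    E <- electric_field_at_measurement(
      neh_frame(matrix(vec, g$n_x, g$n_y), g))
    as.vector(if (comp == "x") E$vx else E$vy)
  }
  if (compare_field == "potential") {
    B <- .operator_matrix(prop_vec, nv) %*% A
  } else if (compare_field %in% c("ex", "ey")) {
    comp <- if (compare_field == "ex") "x" else "y"
    op <- .operator_matrix(function(v) prop_vec(grad_vec(v, comp)), nv)
    B <- op %*% A
  } else {
    Bx <- .operator_matrix(function(v) prop_vec(grad_vec(v, "x")), nv) %*% A
    By <- .operator_matrix(function(v) prop_vec(grad_vec(v, "y")), nv) %*% A
    B <- sqrt(Bx^2 + By^2)
  }

  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
  sem_a <- sem_b <- numeric(nv)
  for (e in seq_len(nv)) {
    Wo <- cwt_morlet(orig[e, ], recording$fs, freqs, omega0)
    Wa <- cwt_morlet(A[e, ], recording$fs, freqs, omega0)
    Wb <- cwt_morlet(B[e, ], recording$fs, freqs, omega0)
    sem_a[e] <- .semblance_from_W(Wo$W, Wa$W, nt, recording$fs, Wo$coi_s,
                                  freqs)$mean
    sem_b[e] <- .semblance_from_W(Wo$W, Wb$W, nt, recording$fs, Wo$coi_s,
                                  freqs)$mean
  }
  out <- data.frame(i = rep(seq_len(g$n_x), times = g$n_y),
                    j = rep(seq_len(g$n_y), each = g$n_x),
                    sem_interp = sem_a, sem_neh = sem_b)
  attr(out, "params") <- list(z = z, omega = omega, kc = kc, alpha = alpha,
                              pad_factor = pad_factor,
                              compare_field = compare_field, band = band,
                              n_scales = n_scales)
  out
}

#' Paired comparison of per-electrode semblance summaries
#'
#' Two-sided Wilcoxon signed-rank test (or paired t-test) on the
#' per-electrode differences `sem_neh - sem_interp`.
#'
#' @param pairs data.frame from [superresolution_experiment()], or any
#'   data.frame with columns `sem_neh` and `sem_interp`; alternatively a
#'   numeric vector of paired differences.
#' @param method "wilcoxon" (default) or "t".
#' @return list with `statistic`, `p_value`, `n`, `method`, `degenerate`
#'   (TRUE when every difference is exactly zero, in which case p = 1).
#' @export
paired_compare <- function(pairs, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  d <- if (is.data.frame(pairs)) pairs$sem_neh - pairs$sem_interp
       else as.numeric(pairs)
  if (length(d) < 6L) stop("need at least 6 pairs", call. = FALSE)
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = length(d),
                method = method, degenerate = TRUE))
  }
  ht <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                        correct = TRUE))
  } else {
    stats::t.test(d, mu = 0)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(d), method = method, degenerate = FALSE)
}
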