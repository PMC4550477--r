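# shared builders for the test suite

# a single complex Fourier lattice mode on an n x n grid
lattice_mode <- function(geometry, i0, j0) {
  lat <- build_frequency_lattice(geometry, pad_factor = 1L)
  co <- node_coords(geometry)
  outer(exp(1i * lat$kx[i0] * co$x), exp(1i * lat$ky[j0] * co$y))
}

# analytic kz for a single mode, matching normal_wavenumber()
mode_kz <- function(k, kx0, ky0) {
  normal_wavenumber(k, matrix(kx0), matrix(ky0))$kz[1, 1]
}

# a tiny noiseless single-source recording for pipeline tests
tiny_recording <- function(noise_sd = 0, seed = 1, duration_s = 4,
                           fs = 100) {
  src <- list(neh_source("point", centre = c(1.6, 1.6), depth = 0.15))
  simulate_recording(src, duration_s = duration_s, fs = fs,
                     noise_sd = noise_sd, seed = seed)
}
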