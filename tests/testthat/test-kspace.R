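test_that("complex permittivity follows the loss-tangent form", {
  expect_identical(complex_permittivity(0, 3.5, 10), 3.5 + 0i)
  expect_equal(complex_permittivity(2, 1, 2), 1 + 1i)
  # Im part is sigma/omega independent of eps
  for (eps in c(0.5, 1, 80)) for (sig in c(0.1, 2)) for (om in c(1, 9.42)) {
    expect_equal(Im(complex_permittivity(sig, eps, om)), sig / om,
                 tolerance = 1e-14)
  }
  expect_error(complex_permittivity(1, 1, 0), "omega")
})

test_that("characteristic wavenumber uses the principal branch", {
  # lossless unit medium: k = omega, purely real
  expect_equal(characteristic_wavenumber(1 + 0i, 1, 5), 5 + 0i)
  set.seed(7)
  for (i in 1:20) {
    sig <- runif(1, 0.01, 2); eps <- runif(1, 0.5, 10)
    om <- runif(1, 1, 50); mu <- runif(1, 0.5, 2)
    eh <- complex_permittivity(sig, eps, om)
    k <- characteristic_wavenumber(eh, mu, om)
    expect_equal(k^2, eh * mu * om^2, tolerance = 1e-12)
    expect_gt(Im(k), 0)   # attenuating medium
    expect_gte(Re(k), 0)  # principal branch
  }
})

test_that("normal wavenumber splits far-field and near-field branches", {
  k <- 2 + 0i
  # on-axis mode: kz = k
  expect_equal(normal_wavenumber(k, matrix(0), matrix(0))$kz[1, 1], k)
  # branch boundary: kz = 0
  expect_equal(normal_wavenumber(k, matrix(2), matrix(0))$kz[1, 1], 0 + 0i)
  # kr^2 = 2 k^2: kz = -i |k|
  kr <- sqrt(2) * 2
  nz <- normal_wavenumber(k, matrix(kr), matrix(0))
  expect_equal(nz$kz[1, 1], -2i, tolerance = 1e-12)
  expect_identical(nz$branch[1, 1], "near-field")
  # sigma = 0 invariants across a lattice
  g <- neh_geometry(12, 12, 0.4)
  lat <- build_frequency_lattice(g)
  nw <- normal_wavenumber(3 + 0i, lat$KX, lat$KY)
  far <- nw$branch == "far-field"
  expect_true(all(Im(nw$kz[far]) == 0) && all(Re(nw$kz[far]) >= 0))
  expect_true(all(Re(nw$kz[!far]) == 0) && all(Im(nw$kz[!far]) < 0))
})

test_that("k-space filter matches its closed form and contract", {
  expect_equal(kspace_filter(1, 1, 0.3), 0.5)         # continuity at kc
  expect_equal(kspace_filter(0, 1, 0.1), 1 - 0.5 * exp(-10))
  expect_equal(kspace_filter(2, 1, 1), 0.5 * exp(-1), tolerance = 1e-12)
  expect_error(kspace_filter(1, -1, 0.5), "kc")
  expect_error(kspace_filter(1, 1, 0), "alpha")

  set.seed(11)
  kr <- seq(0, 30, length.out = 400)
  for (i in 1:200) {
    kc <- runif(1, 0.1, 10); al <- runif(1, 0.01, 5)
    gain <- kspace_filter(kr, kc, al)
    expect_true(all(gain >= 0 & gain <= 1))
    expect_gt(gain[1], 0.5)                          # gain(0) in (0.5, 1]
    above <- kr > kc
    expect_true(all(diff(gain[above]) <= 0))         # monotone decay
    # both branches meet at kc
    expect_equal(kspace_filter(kc, kc, al), 0.5)
    # widening alpha flattens toward 0.5 on either side
    g2 <- kspace_filter(kr, kc, al * 2)
    expect_true(all(abs(g2 - 0.5) <= abs(gain - 0.5) + 1e-12))
  }
})

test_that("propagation matches the closed-form single-mode factor", {
  set.seed(3)
  n <- 16
  g <- neh_geometry(n, n, 0.4)
  lat <- build_frequency_lattice(g, 1)
  for (trial in 1:30) {
    i0 <- sample(n, 1); j0 <- sample(n, 1)
    if (i0 == 1 && j0 == 1) i0 <- 2  # DC is carried by the mean channel
    sigma <- sample(c(0, 0.1, 0.5), 1)
    omega <- 2 * pi * runif(1, 0.5, 2)
    k <- tissue_wavenumber(sigma, 1e5, 1, omega)
    mode <- lattice_mode(g, i0, j0)
    kz0 <- mode_kz(k, lat$kx[i0], lat$ky[j0])
    z <- runif(1, 0.02, 0.3)
    out <- propagate(mode, z = z, k = k, pad_factor = 1, geometry = g)
    expect_lt(max(Mod(out - mode * exp(-1i * kz0 * z))) /
                max(Mod(mode * exp(-1i * kz0 * z))), 1e-9)
  }
})

test_that("propagate honours identity, decay, and composition", {
  g <- neh_geometry(10, 10, 0.4)
  set.seed(5)
  x <- matrix(rnorm(100), 10, 10)
  fr <- neh_frame(x, g)

  # z = 0, all-pass: identity (with and without padding)
  for (pf in c(1, 2)) {
    out <- propagate(fr, z = 0, k = 1e-6 + 0i, pad_factor = pf)
    expect_lt(max(Mod(out$values - x)), 1e-10)
    expect_equal(out$plane_z, 0)
  }

  # single evanescent mode with kappa = 2: amplitude ratio e^-2 over 1 mm
  lat <- build_frequency_lattice(g, 1)
  i0 <- which.min(abs(lat$kx - 2))  # kr = 2 rad/mm at sigma = 0, k ~ 0
  mode <- lattice_mode(g, i0, 1)
  kappa <- sqrt(lat$kx[i0]^2)       # k negligible
  out <- propagate(mode, z = 1, k = 1e-9 + 0i, pad_factor = 1, geometry = g)
  expect_equal(max(Mod(out)) / max(Mod(mode)), exp(-kappa), tolerance = 1e-6)

  # energy non-amplification (decaying propagator, filter <= 1, sigma = 0)
  for (trial in 1:10) {
    y <- matrix(rnorm(100, sd = runif(1, 0.5, 2)), 10, 10) + runif(1, -2, 2)
    flt <- list(kc = runif(1, 1, 10), alpha = runif(1, 0.05, 1))
    out <- propagate(y, z = runif(1, 0, 0.5), k = 1e-6 + 0i, filter = flt,
                     pad_factor = 2, geometry = g)
    expect_lte(sum(Mod(out)^2), sum(y^2) * (1 + 1e-12))
  }

  # composition: z1 then z2 equals z1 + z2 (all-pass, unpadded)
  z1 <- 0.07; z2 <- 0.12
  k <- tissue_wavenumber(0.3, 1e5, 1, 2 * pi * 1.5)
  one <- propagate(propagate(x, z1, k, pad_factor = 1, geometry = g),
                   z2, k, pad_factor = 1, geometry = g)
  both <- propagate(x, z1 + z2, k, pad_factor = 1, geometry = g)
  expect_lt(max(Mod(one - both)) / max(Mod(both)), 1e-9)

  expect_error(propagate(fr, z = -0.1, k = k), "z must be >= 0")
  expect_error(propagate(matrix(0, 4, 4), z = 0.1, k = k, geometry = g),
               "shape")
})

test_that("forward-then-inverse propagation recovers band-limited frames", {
  # spectrum confined to the far-field branch of a large k
  g <- neh_geometry(12, 12, 0.4)
  k <- 6 + 0i  # rad/mm; lattice modes with kr < 6 are far-field
  lat <- build_frequency_lattice(g, 1)
  sel <- which(lat$KR < 0.8 * Re(k), arr.ind = TRUE)
  set.seed(9)
  x <- matrix(0 + 0i, 12, 12)
  spec <- matrix(0 + 0i, 12, 12)
  spec[sel] <- rnorm(nrow(sel)) + 1i * rnorm(nrow(sel))
  x <- stats::fft(spec) / length(spec)
  fwd <- propagate(x, z = 0.2, k = k, pad_factor = 1, geometry = g)
  # kc far above the band with a sharp roll-off: unit gain at these kr
  flt <- list(kc = 100, alpha = 0.01)
  back <- propagate(fwd, z = 0.2, k = k, filter = flt, pad_factor = 1,
                    invert = TRUE, geometry = g)
  expect_lt(max(Mod(back - x)) / max(Mod(x)), 1e-8)
})

test_that("back-projection requires a filter over nonzero distance", {
  g <- neh_geometry(10, 10, 0.4)
  x <- matrix(rnorm(100), 10, 10)
  expect_error(propagate(x, z = 0.1, k = 1 + 0i, invert = TRUE,
                         geometry = g), "filter")
})
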