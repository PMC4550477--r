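test_that("electric field is the in-plane potential gradient", {
  g <- neh_geometry(10, 10, 0.4)
  co <- node_coords(g)
  # constant potential: zero field
  E <- electric_field_at_measurement(neh_frame(matrix(3, 10, 10), g))
  expect_true(all(E$vx == 0) && all(E$vy == 0) && all(E$vz == 0))
  # linear ramp P = 2x: Ex = 2 everywhere (exact for central differences)
  P <- neh_frame(outer(2 * co$x, rep(1, 10)), g)
  E <- electric_field_at_measurement(P)
  expect_equal(max(abs(E$vx - 2)), 0, tolerance = 1e-12)
  expect_true(all(E$vy == 0))
  # sinusoid: amplitude kx*(1 - O(h^2)) with error bound h^2 kx^3 / 6
  kx0 <- 2  # rad/mm, well below Nyquist
  P <- neh_frame(outer(sin(kx0 * co$x), rep(1, 10)), g)
  E <- electric_field_at_measurement(P)
  analytic <- outer(kx0 * cos(kx0 * co$x), rep(1, 10))
  interior <- 2:9
  err <- max(abs(E$vx[interior, ] - analytic[interior, ]))
  expect_lt(err, 0.4^2 * kx0^3 / 6 + 1e-9)
  expect_error(electric_field_at_measurement(
    neh_frame(matrix(0, 2, 2), neh_geometry(2, 2, 0.4))), "3 x 3")
})

test_that("reconstruct_E trivial limits hold", {
  g <- neh_geometry(10, 10, 0.4)
  set.seed(2)
  E <- neh_vfield(matrix(rnorm(100), 10, 10), matrix(rnorm(100), 10, 10),
                  matrix(0, 10, 10), g)
  k <- tissue_wavenumber(0.3, 1e5, 1, 2 * pi * 1.5)
  same <- reconstruct_E(E, z = 0, k = k)
  expect_lt(max(Mod(same$vx - E$vx)), 1e-10)
  # a vanishing-cutoff filter annihilates everything except the mean
  # channel (the filter's DC gain is > 0.5 by construction)
  E0 <- neh_vfield(E$vx - mean(E$vx), E$vy - mean(E$vy), E$vz, g)
  annihilated <- reconstruct_E(E0, z = 0.1, k = k,
                               filter = list(kc = 1e-9, alpha = 1e-3))
  expect_lt(max(Mod(annihilated$vx)), 1e-6 * max(Mod(E0$vx)))
})

test_that("magnetic-field estimate is the wave-vector cross product", {
  g <- neh_geometry(8, 8, 0.4)
  k <- 0.5 + 0.1i
  zeros <- matrix(0 + 0i, 8, 8)
  # zero field -> zero estimate
  H0 <- estimate_H(neh_vfield(zeros, zeros, zeros, g), k)
  expect_true(all(Mod(H0$vx) == 0))
  # uniform E = x_hat: K = (0, 0, k) at DC -> H = k * y_hat
  ones <- matrix(1 + 0i, 8, 8)
  H <- estimate_H(neh_vfield(ones, zeros, zeros, g), k)
  expect_lt(max(Mod(H$vx)), 1e-12)
  expect_lt(max(Mod(H$vy - k)), 1e-12)
  expect_lt(max(Mod(H$vz)), 1e-12)
  # single mode with E parallel to K contributes nothing; modes are built
  # with the synthesis kernel e^{-i k.x}, which occupies lattice bin +k
  lat <- build_frequency_lattice(g, 1)
  i0 <- 3
  mode <- Conj(lattice_mode(g, i0, 1))
  kz0 <- mode_kz(k, lat$kx[i0], 0)
  # K = (kx0, 0, kz0); take E along K
  Epar <- neh_vfield(lat$kx[i0] * mode, zeros, kz0 * mode, g)
  Hp <- estimate_H(Epar, k)
  expect_lt(max(Mod(Hp$vx)) + max(Mod(Hp$vy)) + max(Mod(Hp$vz)),
            1e-10 * Mod(kz0) * max(Mod(mode)))
  # hand-computed: E = x_hat mode -> H = (0, kz0, -ky=0) x ... = kz0 y_hat - 0
  Ex <- neh_vfield(mode, zeros, zeros, g)
  Hx <- estimate_H(Ex, k)
  expect_lt(max(Mod(Hx$vy - kz0 * mode)), 1e-10 * Mod(kz0))
  expect_lt(max(Mod(Hx$vz)), 1e-10)
})

test_that("Poynting product follows the right-hand rule and orthogonality", {
  g <- neh_geometry(6, 6, 0.4)
  ones <- matrix(1 + 0i, 6, 6)
  zeros <- matrix(0 + 0i, 6, 6)
  S <- poynting(neh_vfield(ones, zeros, zeros, g),
                neh_vfield(zeros, ones, zeros, g))
  expect_true(all(S$vz == 1) && all(S$vx == 0) && all(S$vy == 0))
  # parallel fields: zero flow
  Sp <- poynting(neh_vfield(ones, 2 * ones, zeros, g),
                 neh_vfield(3 * ones, 6 * ones, zeros, g))
  expect_lt(max(Mod(Sp$vx)) + max(Mod(Sp$vy)) + max(Mod(Sp$vz)), 1e-12)
  # bilinear orthogonality: S . E = 0 and S . H = 0 nodewise
  set.seed(8)
  rc <- function() matrix(rnorm(36) + 1i * rnorm(36), 6, 6)
  E <- neh_vfield(rc(), rc(), rc(), g)
  H <- neh_vfield(rc(), rc(), rc(), g)
  S <- poynting(E, H)
  dotE <- S$vx * E$vx + S$vy * E$vy + S$vz * E$vz
  dotH <- S$vx * H$vx + S$vy * H$vy + S$vz * H$vz
  expect_lt(max(Mod(dotE)), 1e-10)
  expect_lt(max(Mod(dotH)), 1e-10)
})

test_that("energy source density obeys divergence identities", {
  g <- neh_geometry(10, 10, 0.4)
  co <- node_coords(g)
  ones <- matrix(1, 10, 10)
  zeros <- matrix(0, 10, 10)
  # uniform flow: zero divergence at interior nodes
  esd <- energy_source_density(neh_vfield(3 * ones, -2 * ones, zeros, g))
  expect_lt(max(abs(esd$values[2:9, 2:9])), 1e-12)
  # S = (x, y, 0): divergence 2, exact for linear components
  S <- neh_vfield(outer(co$x, rep(1, 10)), outer(rep(1, 10), co$y), zeros, g)
  esd <- energy_source_density(S)
  expect_equal(max(abs(esd$values[2:9, 2:9] - 2)), 0, tolerance = 1e-12)

  # discrete divergence theorem on a radial flow about the grid centre
  cx <- mean(range(co$x)); cy <- mean(range(co$y))
  Sx <- outer(co$x - cx, rep(1, 10))
  Sy <- outer(rep(1, 10), co$y - cy)
  esd <- energy_source_density(neh_vfield(Sx, Sy, zeros, g))$values
  h <- pitch_eff(g)
  box <- 3:8  # interior box
  vol <- sum(esd[box, box]) * h^2
  # boundary flux with midpoint normals (trapezoid on the box faces)
  fx <- sum(Sx[max(box) + 1, box] - Sx[min(box) - 1, box]) * h / 2 +
    sum(Sx[max(box), box] - Sx[min(box), box]) * h / 2
  fy <- sum(Sy[box, max(box) + 1] - Sy[box, min(box) - 1]) * h / 2 +
    sum(Sy[box, max(box)] - Sy[box, min(box)]) * h / 2
  flux <- fx + fy
  expect_lt(abs(vol - flux) / abs(flux), 0.02)
  # net source region has positive ESD integral (outward flux)
  expect_gt(vol, 0)
})

test_that("dissipation is a non-negative sigma-weighted energy density", {
  g <- neh_geometry(6, 6, 0.4)
  ones <- matrix(1 + 0i, 6, 6)
  zeros <- matrix(0 + 0i, 6, 6)
  E <- neh_vfield(ones, zeros, zeros, g)
  expect_true(all(dissipation(E, 0)$values == 0))
  expect_true(all(dissipation(E, 2)$values == 2))
  set.seed(4)
  rc <- function() matrix(rnorm(36) + 1i * rnorm(36), 6, 6)
  E <- neh_vfield(rc(), rc(), rc(), g)
  sig <- matrix(runif(36), 6, 6)
  D1 <- dissipation(E, sig)$values
  expect_true(all(D1 >= 0))
  E2 <- neh_vfield(2 * E$vx, 2 * E$vy, 2 * E$vz, g)
  expect_equal(dissipation(E2, sig)$values, 4 * D1, tolerance = 1e-12)
})

test_that("complex flow splits into propagating and resonant parts", {
  g <- neh_geometry(4, 4, 0.4)
  set.seed(6)
  rc <- function() matrix(rnorm(16) + 1i * rnorm(16), 4, 4)
  S <- neh_vfield(rc(), rc(), rc(), g, label = "S")
  parts <- split_complex_flow(S)
  expect_equal(parts$propagating$vx + 1i * parts$resonant$vx, S$vx)
  expect_equal(parts$propagating$vz + 1i * parts$resonant$vz, S$vz)
  # purely imaginary flow: no propagating part
  Si <- neh_vfield(1i * matrix(1, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4), g)
  p2 <- split_complex_flow(Si)
  expect_true(all(p2$propagating$vx == 0) && all(p2$resonant$vx == 1))
})

test_that("cycle averaging resamples and averages phase-locked cycles", {
  # identical cycles: average equals one resampled cycle
  tpl <- sin(2 * pi * (0:19) / 20)
  x <- rep(tpl, 5)
  markers <- seq(1, 101, by = 20)
  avg <- cycle_average(c(x, 0), markers, n_phasepoints = 8)
  one <- cycle_average(c(tpl, tpl[1]), c(1, 21), n_phasepoints = 8)
  expect_equal(avg, one, tolerance = 1e-12)
  # opposite cycles cancel
  y <- c(tpl, -tpl, 0)
  expect_lt(max(abs(cycle_average(y, c(1, 21, 41), 8))), 1e-12)
  # 60 noisy copies: pointwise error within 3 sd / sqrt(60) at 99% of nodes
  set.seed(123)
  s <- 0.3
  noisy <- rep(tpl, 60) + rnorm(20 * 60, sd = s)
  mk <- seq(1, 1201, by = 20)
  avg <- cycle_average(c(noisy, 0), mk, n_phasepoints = 20)
  tpl_resampled <- cycle_average(c(tpl, tpl[1]), c(1, 21), 20)
  frac_ok <- mean(abs(avg - tpl_resampled) <= 3 * s / sqrt(60))
  expect_gte(frac_ok, 0.95)
  # guards
  expect_error(cycle_average(x, 5), "markers")
  expect_error(cycle_average(x, c(10, 10)), "increasing")
  # array input: time-first stack of maps
  arr <- array(rep(tpl, each = 4), dim = c(20, 2, 2))
  arr2 <- array(0, dim = c(21, 2, 2)); arr2[1:20, , ] <- arr
  av <- cycle_average(arr2, c(1, 21), n_phasepoints = 4)
  expect_identical(dim(av), c(4L, 2L, 2L))
})

test_that("region vectors average in-plane flow over named regions", {
  g <- neh_geometry(10, 10, 0.4)
  ones <- matrix(1, 10, 10)
  zeros <- matrix(0, 10, 10)
  regions <- neh_regions(list(deep = list(x = c(1, 5), y = c(1, 5)),
                              sup = list(x = c(6, 10), y = c(6, 10))), g)
  S <- neh_vfield(ones, zeros, zeros, g, label = "S")
  rv <- region_vectors(S, regions)
  expect_equal(rv$magnitude, c(1, 1))
  expect_equal(rv$angle, c(0, 0))
  # opposite uniform fields differ by pi
  Sx <- ones; Sx[6:10, ] <- -1
  rv2 <- region_vectors(neh_vfield(Sx, zeros, zeros, g),
                        list(a = list(x = c(1, 5), y = c(1, 10)),
                             b = list(x = c(6, 10), y = c(1, 10))))
  expect_equal(abs(rv2$angle[1] - rv2$angle[2]), pi, tolerance = 1e-12)
  # region mean equals the brute-force nodewise mean
  set.seed(14)
  vx <- matrix(rnorm(100), 10, 10); vy <- matrix(rnorm(100), 10, 10)
  rv3 <- region_vectors(neh_vfield(vx, vy, zeros, g),
                        list(r = list(x = c(2, 7), y = c(3, 9))))
  expect_equal(rv3$mean_x, mean(vx[2:7, 3:9]), tolerance = 1e-14)
  expect_equal(rv3$mean_y, mean(vy[2:7, 3:9]), tolerance = 1e-14)
  # invalid regions
  expect_error(neh_regions(list(bad = list(x = c(0, 3), y = c(1, 2))), g),
               "outside")
  expect_error(neh_regions(list(a = list(x = c(1, 5), y = c(1, 5)),
                                b = list(x = c(5, 9), y = c(5, 9))), g),
               "overlap")
})

test_that("the pipeline is linear in the input potentials", {
  rec <- tiny_recording()
  P <- band_phasor(rec, freq = 1.5)
  r1 <- neh_reconstruct(P, rec$medium, z = 0.15)
  P3 <- neh_frame(3 * P$values, P$geometry)
  r3 <- neh_reconstruct(P3, rec$medium, z = 0.15)
  expect_equal(r3$Ez$vx, 3 * r1$Ez$vx, tolerance = 1e-9)
  expect_equal(r3$Hz$vy, 3 * r1$Hz$vy, tolerance = 1e-9)
  expect_equal(r3$Sz$vz, 9 * r1$Sz$vz, tolerance = 1e-9)
  expect_equal(r3$ESD$values, 9 * r1$ESD$values, tolerance = 1e-9)
  expect_equal(r3$D$values, 9 * r1$D$values, tolerance = 1e-9)
  expect_true(all(r1$D$values >= 0))
})

test_that("cycle markers are detected at negative-going zero crossings", {
  fs <- 100
  t <- (0:999) / fs
  x <- sin(2 * pi * 1.5 * t)
  mk <- detect_cycles(x, fs)
  # 1.5 Hz over 10 s: about 15 negative-going crossings, spaced ~fs/1.5
  expect_gte(length(mk), 12)
  expect_lt(max(abs(diff(mk) - fs / 1.5)), 8)
  expect_lt(abs(median(diff(mk)) - fs / 1.5), 1)
})
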