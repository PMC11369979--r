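test_that("brain mask keeps the head and drops background and minor blobs", {
  g <- small_grid(c(32, 32, 32))
  expect_true(all(compute_brain_mask(array(5, g$dims), g)))
  expect_error(compute_brain_mask(array(0, g$dims), g), "empty-mask")

  co <- nigra:::grid_coords_mm(g)
  ell <- (co$x / 10)^2 + (co$y / 12)^2 + (co$z / 9)^2 <= 1
  mag <- ifelse(ell, 1, 0) + array(abs(rnorm(prod(g$dims), 0, 0.01)), g$dims)
  mask <- compute_brain_mask(mag, g)
  interior <- (co$x / 8)^2 + (co$y / 10)^2 + (co$z / 7)^2 <= 1
  expect_true(all(mask[interior]))
  expect_false(mask[1, 1, 1])

  two <- array(0, g$dims)
  two[4:8, 4:8, 4:8] <- 1          # 125 voxels
  two[20:29, 20:29, 20:29] <- 1    # 1000 voxels
  mask2 <- compute_brain_mask(two, g, close_mm = 0)
  expect_false(any(mask2[4:8, 4:8, 4:8]))
  expect_true(all(mask2[20:29, 20:29, 20:29]))
})

test_that("Laplacian unwrapping is exact for smooth phase and recovers wraps", {
  g <- small_grid(c(48, 48, 48))
  co <- nigra:::grid_coords_mm(g)
  r2 <- co$x^2 + co$y^2 + co$z^2
  interior <- r2 <= 15^2

  phi <- 0.8 * exp(-r2 / (2 * 4^2))        # wrap-free
  u <- laplacian_unwrap(phi, g)
  err <- u - phi
  err <- err - mean(err[interior])
  expect_lt(max(abs(err[interior])), 1e-6)

  phi6 <- 6 * pi * exp(-r2 / (2 * 6^2))    # peaks at 6 pi, heavily wrapped
  u6 <- laplacian_unwrap(wrap_phase(phi6), g)
  err6 <- u6 - phi6
  err6 <- err6 - mean(err6[interior])
  expect_lt(max(abs(err6[interior])), 0.05)

  # unwrap closure on the circle
  resid <- wrap_phase(u6 - wrap_phase(phi6))
  resid <- resid - mean(resid[interior])
  expect_lt(max(abs(resid[interior])), 0.05)

  uc <- laplacian_unwrap(array(0.7, g$dims), g)
  expect_lt(diff(range(uc)), 1e-10)

  bad <- phi; bad[1] <- NA
  expect_error(laplacian_unwrap(bad, g), "data error")
})

test_that("frequency fit recovers exact slopes and absorbs intercepts", {
  g <- small_grid(c(8, 8, 8))
  te <- c(13.77, 26.39, 39)
  mask <- array(TRUE, g$dims)
  f_true <- 10
  phases <- lapply(te, function(t) array(2 * pi * f_true * t / 1000, g$dims))
  fm <- estimate_frequency(phases, te, mask, g)
  expect_equal(max(abs(fm$values - 10)), 0, tolerance = 1e-10)

  phases_off <- lapply(phases, function(p) p + 0.3)
  fm2 <- estimate_frequency(phases_off, te, mask, g)
  expect_equal(max(abs(fm2$values - 10)), 0, tolerance = 1e-10)

  expect_error(estimate_frequency(phases[1], te[1], mask, g), "single echo")
  fm1 <- estimate_frequency(phases[1], te[1], mask, g, intercept_free = TRUE)
  expect_equal(max(abs(fm1$values - 10)), 0, tolerance = 1e-10)
})

test_that("weighted frequency fit matches the normal-equations oracle", {
  g <- small_grid(c(6, 6, 6))
  te <- c(13.77, 26.39, 39)
  mask <- array(TRUE, g$dims)
  set.seed(42)
  phases <- lapply(te, function(t)
    array(rnorm(prod(g$dims)), g$dims))
  w <- c(2, 1.5, 0.8)
  fm <- estimate_frequency(phases, te, mask, g, weights = w)
  # brute-force per-voxel weighted regression
  x <- 2 * pi * te / 1000
  for (v in c(1, 57, 216)) {
    y <- vapply(phases, function(p) p[v], 0)
    slope <- stats::coef(stats::lm(y ~ x, weights = w))[["x"]]
    expect_equal(fm$values[v], slope, tolerance = 1e-10)
  }
})

test_that("SMV filtering annihilates external fields and keeps internal ones", {
  g <- small_grid(c(48, 48, 48))
  co <- nigra:::grid_coords_mm(g)
  r2 <- co$x^2 + co$y^2 + co$z^2
  mask <- r2 <= 16^2

  # constants are harmonic
  fm <- frequency_map(array(3.7, g$dims), mask, g)
  loc <- remove_background_field(fm, radius_mm = 3)
  expect_lt(max(abs(loc$values[loc$mask])), 0.05)

  # dipole source entirely outside the mask
  chi_out <- array(0, g$dims)
  chi_out[(abs(co$x - 21) <= 2) & (abs(co$y) <= 2) & (abs(co$z) <= 2)] <- 500
  f_out <- forward_field(chi_out, g)
  loc_out <- remove_background_field(frequency_map(f_out, mask, g), radius_mm = 3)
  rms_in <- sqrt(mean(f_out[loc_out$mask]^2))
  rms_local <- sqrt(mean(loc_out$values[loc_out$mask]^2))
  expect_lt(rms_local, 0.05 * rms_in)

  # interior source survives
  chi_in <- array(0, g$dims)
  chi_in[r2 <= 4^2] <- 300
  f_in <- forward_field(chi_in, g)
  loc_in <- remove_background_field(frequency_map(f_in, mask, g), radius_mm = 3)
  e_kept <- sum(loc_in$values[loc_in$mask]^2) / sum(f_in[loc_in$mask]^2)
  expect_gt(e_kept, 0.8)

  expect_error(remove_background_field(fm, radius_mm = 40), "geometry error")
})

test_that("dipole inversion is linear, validated, and zero maps to zero", {
  g <- small_grid(c(24, 24, 24))
  mask <- array(TRUE, g$dims)
  z <- invert_dipole(frequency_map(array(0, g$dims), mask, g), n_iter = 3)
  expect_equal(max(abs(z$values)), 0, tolerance = 1e-12)

  set.seed(11)
  chi <- array(0, g$dims)
  chi[8:16, 8:16, 8:16] <- rnorm(9^3, 50, 20)
  f <- forward_field(chi, g)
  a <- invert_dipole(frequency_map(f, mask, g), n_iter = 5)
  b <- invert_dipole(frequency_map(3 * f, mask, g), n_iter = 5)
  expect_equal(b$values, 3 * a$values, tolerance = 1e-8)

  expect_error(invert_dipole(frequency_map(f, mask, g), delta = 0.5),
               "parameter error")
  expect_equal(mean(a$values[mask]), 0, tolerance = 1e-10)  # referenced
})

test_that("iterative refinement does not increase phantom error", {
  g <- small_grid(c(32, 32, 32))
  co <- nigra:::grid_coords_mm(g)
  r2 <- co$x^2 + co$y^2 + co$z^2
  chi <- ifelse(r2 <= 6^2, 100, 0)
  mask <- r2 <= 13^2
  set.seed(2)
  f <- forward_field(chi, g) + array(rnorm(prod(g$dims), 0, 0.01), g$dims)
  fm <- frequency_map(f, mask, g)
  truth <- chi - mean(chi[mask])
  rmse <- function(n) {
    s <- invert_dipole(fm, delta = 0.1, n_iter = n)
    sqrt(mean((s$values[mask] - truth[mask])^2))
  }
  expect_lte(rmse(30), rmse(0) + 1e-9)
})
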