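test_that("phantom masks satisfy the containment and disjointness invariants", {
  g <- phantom_grid()
  ph <- render_phantom(list(degeneration_L = 0.1, degeneration_R = 0.1), g,
                       seed = 2)
  expect_true(all(ph$masks$SN_L[ph$masks$N1_L]))   # N1 inside SN
  expect_true(all(ph$masks$SN_R[ph$masks$N1_R]))
  expect_false(any(ph$masks$SN_L & ph$masks$SN_R)) # hemispheres disjoint
  for (m in ph$masks) expect_gt(sum(m), 0)
  expect_true(all(ph$head[ph$masks$SN_L | ph$masks$SN_R]))
})

test_that("intact phantoms keep a low-susceptibility N1 and full loss removes it", {
  g <- phantom_grid()
  slices_of <- function(ph) select_analysis_slices(ph$masks$RN_L | ph$masks$RN_R, g)
  ph0 <- render_phantom(list(degeneration_L = 0, degeneration_R = 0), g, seed = 4)
  s0 <- slices_of(ph0)
  for (side in c("L", "R")) {
    v <- thresholded_volume(ph0$chi, ph0$masks[[paste0("SN_", side)]], s0,
                            threshold = 60, direction = "below", grid = g)
    expect_gt(v, 0)
  }
  ph1 <- render_phantom(list(degeneration_L = 1, degeneration_R = 1), g, seed = 4)
  s1 <- slices_of(ph1)
  for (side in c("L", "R")) {
    v <- thresholded_volume(ph1$chi, ph1$masks[[paste0("SN_", side)]], s1,
                            threshold = 60, direction = "below", grid = g)
    expect_equal(v, 0)
  }
})

test_that("phantom rendering is seeded-deterministic and validates inputs", {
  g <- phantom_grid()
  lat <- list(degeneration_L = 0.5, degeneration_R = 0.4)
  expect_identical(render_phantom(lat, g, seed = 8)$chi,
                   render_phantom(lat, g, seed = 8)$chi)
  expect_error(render_phantom(lat, voxel_grid(c(16, 16, 8), c(0.5, 0.5, 1))),
               "geometry error")
  expect_error(render_phantom(list(degeneration_L = 1.4, degeneration_R = 0), g),
               "degeneration")
})

test_that("rendered cohorts preserve the PD-below-HC ordering of low-chi SN volume", {
  g <- phantom_grid()
  co <- generate_cohort(cohort_spec(n_pd = 12, n_hc = 12, seed = 21))
  vols <- vapply(seq_len(nrow(co$latent)), function(i) {
    ph <- render_phantom(co$latent[i, ], g, seed = co$subjects$seed[i])
    s <- select_analysis_slices(ph$masks$RN_L | ph$masks$RN_R, g)
    thresholded_volume(ph$chi, ph$masks$SN_L | ph$masks$SN_R, s, 60, "below", g)
  }, 0)
  expect_lt(median(vols[co$subjects$group == "PD"]),
            median(vols[co$subjects$group == "HC"]))
})

test_that("zero susceptibility with no noise yields pure channel-offset phase", {
  g <- small_grid(c(16, 16, 16))
  ser <- simulate_multiecho_gre(array(0, g$dims), g, n_channels = 2,
                                noise_sd = 0, seed = 3, background_hz = 0)
  expect_equal(max(abs(ser$field)), 0, tolerance = 1e-12)
  for (ch in 1:2) for (e in 1:3) {
    p <- ser$phase[[ch]][[e]]
    expect_lt(diff(range(p)), 1e-12)   # constant per channel
    expect_true(all(p > -pi & p <= pi))
  }
})

test_that("simulated phase is always wrapped into the principal interval", {
  g <- small_grid(c(16, 16, 16))
  chi <- array(rnorm(prod(g$dims), 0, 100), g$dims)
  ser <- simulate_multiecho_gre(chi, g, n_channels = 3, noise_sd = 0.05, seed = 6)
  for (ch in seq_along(ser$phase)) for (e in seq_along(ser$te_list))
    expect_true(all(ser$phase[[ch]][[e]] > -pi & ser$phase[[ch]][[e]] <= pi))
  expect_error(simulate_multiecho_gre(chi, g, te_list = numeric(0)), "config error")
  expect_error(simulate_multiecho_gre(chi, g, te_list = c(39, 13.77)),
               "increasing")
})

test_that("the dipole field inside a uniform sphere vanishes (closed form)", {
  g <- small_grid(c(64, 64, 64))
  co <- nigra:::grid_coords_mm(g)
  r2 <- co$x^2 + co$y^2 + co$z^2
  chi <- ifelse(r2 <= 8^2, 100, 0)
  f <- forward_field(chi, g, b0 = 3)
  # interior away from the boundary: the 1/3 Lorentz and -1/3 demagnetizing
  # terms cancel under the D(0) = 0 convention
  expect_lt(max(abs(f[r2 <= 5^2])), 0.06)
  expect_lt(abs(mean(f[r2 <= 5^2])), 1e-10)
})

test_that("wrapping closure: stored phase equals wrap of the true phase", {
  g <- small_grid(c(16, 16, 16))
  chi <- array(rnorm(prod(g$dims), 0, 150), g$dims)
  ser <- simulate_multiecho_gre(chi, g, n_channels = 1, noise_sd = 0, seed = 5,
                                background_hz = 2)
  co <- nigra:::grid_coords_mm(g)
  fov <- g$dims * g$voxel_size
  bg <- 2 * ((2 * co$x / fov[1])^2 + (2 * co$y / fov[2])^2 - (2 * co$z / fov[3])^2)
  set.seed(5)
  off <- runif(1, -pi, pi)
  for (e in 1:3) {
    true_phase <- 2 * pi * (ser$field + bg) * ser$te_list[e] / 1000 + off
    expect_equal(ser$phase[[1]][[e]], wrap_phase(true_phase), tolerance = 1e-12)
  }
})
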