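test_that("homogeneous slab reproduces Ohm's law E = J/sigma", {
  sl <- slab_problem(n = c(16, 12, 12), spacing = c(2, 2, 2),
                     sigma_profile = rep(0.1, 16))
  J <- 100                                   # A/m^2
  target_mA <- J * sl$cross_area_m2 * 1000
  sol <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, target_mA)
  E <- field_magnitude(sol$phi, sl$spacing)
  interior <- E[3:14, , ]
  expect_rel_equal(interior, array(10, dim(interior)), 0.01)  # 10 V/cm
  expect_lt(abs(sol$injected_mA - sol$extracted_mA) / sol$injected_mA, 0.005)
  expect_equal(sol$injected_mA, target_mA, tolerance = 1e-9)
})

test_that("two-layer slab obeys current continuity: E2/E1 = sigma1/sigma2", {
  prof <- c(rep(0.2, 8), rep(0.1, 8))
  sl <- slab_problem(n = c(16, 10, 10), spacing = c(2, 2, 2),
                     sigma_profile = prof)
  sol <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 500)
  E <- field_magnitude(sol$phi, sl$spacing)
  e1 <- mean(E[3:6, , ]); e2 <- mean(E[11:14, , ])
  expect_equal(e2 / e1, 2, tolerance = 0.01)
})

test_that("iterative solution matches a dense direct solve", {
  set.seed(7)
  for (rep in 1:3) {
    n <- sample(8:12, 1)
    sigma <- random_sigma(n)
    d <- dim(sigma)
    src <- ijk_to_lin(as.matrix(expand.grid(1, 1:d[2], 1:d[3])), d)
    snk <- ijk_to_lin(as.matrix(expand.grid(d[1], 1:d[2], 1:d[3])), d)
    it <- solve_pair(sigma, c(2, 2, 2), src, snk, 100)
    de <- ttfplan:::solve_pair_dense(sigma, c(2, 2, 2), src, snk, 100)
    expect_rel_equal(it$phi, de$phi, 1e-6)
  }
})

test_that("solutions scale linearly with target current", {
  sl <- slab_problem(n = c(10, 8, 8), sigma_profile = runif(10, 0.1, 0.5))
  s1 <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 100)
  s2 <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 200)
  expect_equal(s2$phi, 2 * s1$phi, tolerance = 1e-9)
})

test_that("swapping source and sink negates phi and preserves |E|", {
  sl <- slab_problem(n = c(10, 8, 8), sigma_profile = runif(10, 0.1, 0.5))
  fwd <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 100)
  rev <- solve_pair(sl$sigma, sl$spacing, sl$sink, sl$source, 100)
  expect_equal(rev$phi, -fwd$phi, tolerance = 1e-6)
  expect_equal(field_magnitude(rev$phi, sl$spacing),
               field_magnitude(fwd$phi, sl$spacing), tolerance = 1e-6)
})

test_that("current is conserved through every cross-sectional plane", {
  set.seed(11)
  prof <- runif(12, 0.05, 0.6)
  sl <- slab_problem(n = c(12, 9, 9), spacing = c(3, 2, 2),
                     sigma_profile = prof)
  sol <- solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 250)
  phi <- sol$phi
  sp_m <- sl$spacing / 1000
  a_over_h <- sp_m[2] * sp_m[3] / sp_m[1]
  for (i in 1:11) {
    g_face <- 2 * sl$sigma[i, , ] * sl$sigma[i + 1, , ] /
      (sl$sigma[i, , ] + sl$sigma[i + 1, , ]) * a_over_h
    flux_mA <- sum(g_face * (phi[i, , ] - phi[i + 1, , ])) * 1000
    expect_lt(abs(flux_mA - 250) / 250, 0.005)
  }
})

test_that("mirrored problems give mirrored fields", {
  g <- generate_phantom(fixture_spec("asymmetric"))
  sigma <- conductivity_grid(g, conductivity_table())
  d <- dim(sigma)
  arrays <- place_reference_arrays(tumor_centroid(g))
  surf <- surface_mask(body_mask(g))
  sv <- unlist(lapply(realize_array(arrays[[1]], g, surf), `[[`, "voxels"))
  kv <- unlist(lapply(realize_array(arrays[[2]], g, surf), `[[`, "voxels"))
  sol <- solve_pair(sigma, g$spacing, sv, kv, 500, tol = 1e-10)
  E <- field_magnitude(sol$phi, g$spacing)

  sigma_m <- sigma[d[1]:1, , ]
  sv_m <- mirror_voxels(sv, d); kv_m <- mirror_voxels(kv, d)
  sol_m <- solve_pair(sigma_m, g$spacing, sv_m, kv_m, 500, tol = 1e-10)
  E_m <- field_magnitude(sol_m$phi, g$spacing)
  expect_equal(E_m[d[1]:1, , ], E, tolerance = 1e-6)
})

test_that("degenerate drive configurations are rejected", {
  sl <- slab_problem(n = c(8, 6, 6))
  expect_error(solve_pair(sl$sigma, sl$spacing, sl$source, sl$sink, 0),
               "target current")
  expect_error(solve_pair(sl$sigma, sl$spacing, integer(0), sl$sink, 10),
               "empty")
  expect_error(solve_pair(sl$sigma, sl$spacing, sl$source, sl$source, 10),
               "share")
  # disconnected source/sink: two separated conducting blocks
  sigma2 <- array(0, c(9, 5, 5))
  sigma2[1:4, , ] <- 0.2; sigma2[6:9, , ] <- 0.2
  src <- ijk_to_lin(as.matrix(expand.grid(1, 1:5, 1:5)), c(9, 5, 5))
  snk <- ijk_to_lin(as.matrix(expand.grid(9, 1:5, 1:5)), c(9, 5, 5))
  expect_error(solve_pair(sigma2, c(2, 2, 2), src, snk, 10))
})

test_that("target current follows the printed device output", {
  arrays <- place_reference_arrays(c(0, 0, 0))
  # 20-disc array at 31 mA/cm^2 delivers the device maximum ~1414 mA
  expect_equal(target_current(arrays[[1]], 31), 1414, tolerance = 1e-6)
  # 13-disc array scales with area
  expect_equal(target_current(arrays[[3]], 31), 1414 * 13 / 20,
               tolerance = 1e-6)
  # unit area at 31 mA/cm^2 -> 31 mA; doubling area doubles current
  one_cm2 <- place_reference_arrays(
    c(0, 0, 0), electrode_layout(disc_radius_mm = sqrt(1 / (20 * pi)) * 10))[[1]]
  expect_equal(target_current(one_cm2, 31), 31 * 20 / 20 * 1,
               tolerance = 1e-9)
  big <- one_cm2; big$disc_radius_mm <- one_cm2$disc_radius_mm * sqrt(2)
  expect_equal(target_current(big, 31), 2 * target_current(one_cm2, 31),
               tolerance = 1e-9)
})

test_that("field magnitude matches brute-force finite differences", {
  # constant potential -> zero field
  phi_c <- array(3.5, c(6, 6, 6))
  expect_true(all(field_magnitude(phi_c, c(2, 2, 2)) == 0))
  # linear ramp of 1 V/cm along x (0.1 V/mm at 1 mm spacing)
  nx <- 10
  phi_l <- array(rep(0.1 * (1:nx), times = 64), c(nx, 8, 8))
  E_l <- field_magnitude(phi_l, c(1, 1, 1))
  expect_equal(E_l, array(1, dim(E_l)), tolerance = 1e-12)
  # random 8^3 potential: per-voxel check against direct differencing
  set.seed(3)
  phi_r <- array(rnorm(512), c(8, 8, 8))
  E_r <- field_magnitude(phi_r, c(2, 3, 4))
  for (v in sample(512, 40)) {
    ijk <- lin_to_ijk(v, c(8, 8, 8))
    i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
    gx <- if (i > 1 && i < 8) (phi_r[i + 1, j, k] - phi_r[i - 1, j, k]) / 4 else if (i == 1) (phi_r[2, j, k] - phi_r[1, j, k]) / 2 else (phi_r[8, j, k] - phi_r[7, j, k]) / 2
    gy <- if (j > 1 && j < 8) (phi_r[i, j + 1, k] - phi_r[i, j - 1, k]) / 6 else if (j == 1) (phi_r[i, 2, k] - phi_r[i, 1, k]) / 3 else (phi_r[i, 8, k] - phi_r[i, 7, k]) / 3
    gz <- if (k > 1 && k < 8) (phi_r[i, j, k + 1] - phi_r[i, j, k - 1]) / 8 else if (k == 1) (phi_r[i, j, 2] - phi_r[i, j, 1]) / 4 else (phi_r[i, j, 8] - phi_r[i, j, 7]) / 4
    expect_equal(E_r[i, j, k], sqrt(gx^2 + gy^2 + gz^2) * 10,
                 tolerance = 1e-12)
  }
})

test_that("pair combination rules behave as configured", {
  a <- array(2, c(4, 4, 4)); b <- array(4, c(4, 4, 4))
  expect_equal(combine_pairs(a, b, c(0.5, 0.5), "mean"),
               array(3, c(4, 4, 4)))
  expect_equal(combine_pairs(a, b, c(1, 0), "mean"), a)
  expect_equal(combine_pairs(a, b, c(0.5, 0.5), "max"), b)
  expect_error(combine_pairs(a, array(1, c(3, 3, 3))), "shape")
  expect_error(combine_pairs(a, b, c(0.7, 0.7)), "sum to 1")
})
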