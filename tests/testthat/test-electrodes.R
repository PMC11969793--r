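test_that("tumor centroid is the mean of GTV voxel centers", {
  d <- c(12, 12, 12)
  labels <- array(1L, d)
  names12 <- c("0" = "body-exterior", "1" = "muscle", "2" = "GTV")
  # single GTV voxel: centroid is that voxel's world position
  l1 <- labels; l1[6, 7, 8] <- 2L
  g1 <- tissue_grid(l1, c(2, 2, 2), c(0, 6, 14), names12)
  expect_equal(tumor_centroid(g1), c(10, 18, 28))
  # two voxels differing in x only: centroid at the midpoint
  l2 <- labels; l2[3, 5, 5] <- 2L; l2[5, 5, 5] <- 2L
  g2 <- tissue_grid(l2, c(2, 2, 2), c(0, 0, 0), names12)
  expect_equal(tumor_centroid(g2), c(6, 8, 8))
  l3 <- labels; l3[1, 1, 1] <- 0L  # no GTV
  expect_error(tissue_grid(l3, c(2, 2, 2), NULL,
                           c("0" = "body-exterior", "1" = "muscle")),
               "GTV")
})

test_that("spherical GTV centroid matches a brute-force average", {
  g <- generate_phantom(phantom_spec(shape = c(32, 32, 32), spacing = 3,
                                     body_semiaxes = c(42, 42, 42),
                                     organs = list(),
                                     tumor_center = c(4, -5, 7),
                                     tumor_radius_mm = 12))
  idx <- which(gtv_mask(g))
  acc <- c(0, 0, 0)
  for (v in idx) {
    v0 <- v - 1
    ijk <- c(v0 %% 32, (v0 %/% 32) %% 32, v0 %/% (32 * 32)) + 1
    acc <- acc + g$origin + (ijk - 1) * g$spacing
  }
  expect_equal(tumor_centroid(g), acc / length(idx), tolerance = 1e-12)
  expect_true(all(abs(tumor_centroid(g) - c(4, -5, 7)) <= g$spacing / 2))
})

test_that("reference montage carries 20/20/13/13 discs with opposite polarity", {
  arrays <- place_reference_arrays(c(0, 0, 0))
  expect_equal(vapply(arrays, function(a) nrow(a$offsets), 0L),
               c(20L, 20L, 13L, 13L))
  expect_equal(vapply(arrays, `[[`, "", "pair_id"), c("AP", "AP", "LR", "LR"))
  for (pair in c("AP", "LR")) {
    pol <- vapply(Filter(function(a) a$pair_id == pair, arrays),
                  `[[`, "", "polarity")
    expect_setequal(pol, c("source", "sink"))
  }
})

test_that("AP array centers align with the tumor center on a centered phantom", {
  g <- sphere_phantom()
  center <- tumor_centroid(g)
  # narrow layout so every disc ray starts inside the 40 mm sphere
  arrays <- place_reference_arrays(center, electrode_layout(spacing_mm = 10))
  surf <- surface_mask(body_mask(g))
  ant <- realize_array(arrays[[1]], g, surf)
  pts <- do.call(rbind, lapply(ant, `[[`, "center"))
  # array center (mean disc position) shares x and z with the tumor center
  expect_lt(abs(mean(pts[, 1]) - center[1]), max(g$spacing))
  expect_lt(abs(mean(pts[, 3]) - center[3]), max(g$spacing))
})

test_that("all contact voxels lie on the body surface", {
  g <- generate_phantom(fixture_spec("asymmetric"))
  surf <- surface_mask(body_mask(g))
  arrays <- place_reference_arrays(tumor_centroid(g))
  for (a in arrays) {
    patches <- realize_array(a, g, surf)
    vox <- unlist(lapply(patches, `[[`, "voxels"))
    expect_true(all(surf[vox]))
    # no voxel shared between discs
    expect_false(any(duplicated(vox)))
  }
})

test_that("surface projection recovers sphere geometry", {
  g <- sphere_phantom(spacing = 2, n = 45)
  p_plus <- project_to_surface(c(0, 0, 0), c(1, 0, 0), g, 9)
  expect_lt(abs(p_plus$point[1] - 40), 2)
  expect_lt(abs(p_plus$point[2]), 1e-9)
  p_minus <- project_to_surface(c(0, 0, 0), c(-1, 0, 0), g, 9)
  expect_lt(abs(p_plus$point[1] + p_minus$point[1]), 2)
  expect_error(project_to_surface(c(100, 0, 0), c(1, 0, 0), g, 9),
               "not inside")
})

test_that("patch voxel set matches a brute-force surface scan", {
  g <- sphere_phantom(spacing = 2, n = 45)
  r_patch <- 9
  p <- project_to_surface(c(0, 0, 0), c(0, 1, 0), g, r_patch)
  d <- dim(g$labels)
  body <- g$labels != 0L
  found <- integer(0)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!body[i, j, k]) next
    on_surf <- i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 ||
      k == d[3] || !body[i - 1, j, k] || !body[i + 1, j, k] ||
      !body[i, j - 1, k] || !body[i, j + 1, k] || !body[i, j, k - 1] ||
      !body[i, j, k + 1]
    if (!on_surf) next
    w <- g$origin + (c(i, j, k) - 1) * g$spacing
    if (sum((w - p$point)^2) <= r_patch^2)
      found <- c(found, ijk_to_lin(c(i, j, k), d))
  }
  # implementation additionally guarantees the nearest surface voxel
  expect_true(all(found %in% p$voxels))
  expect_lte(length(setdiff(p$voxels, found)), 1L)
})

test_that("plan rotation is an isometry with exact identity and inverse", {
  arrays <- place_reference_arrays(c(5, 5, 0))
  ref_dirs <- t(vapply(arrays, `[[`, numeric(3), "d"))

  same <- rotate_plan(arrays, plan_spec("p", "none", 0))
  expect_equal(t(vapply(same, `[[`, numeric(3), "d")), ref_dirs)

  fwd <- rotate_plan(arrays, plan_spec("p", "axial", 15))
  back <- rotate_plan(fwd, plan_spec("p", "axial", -15))
  expect_equal(t(vapply(back, `[[`, numeric(3), "d")), ref_dirs,
               tolerance = 1e-12)

  for (pl in list(plan_spec("a", "axial", 30), plan_spec("s", "sagittal", 10))) {
    rot <- rotate_plan(arrays, pl)
    for (k in seq_along(arrays)) {
      expect_equal(sqrt(sum(rot[[k]]$d^2)), 1, tolerance = 1e-12)
      # pairs stay perpendicular: AP . LR directions unchanged
    }
    expect_equal(sum(rot[[1]]$d * rot[[3]]$d), sum(arrays[[1]]$d * arrays[[3]]$d),
                 tolerance = 1e-12)
    # disc counts and radii never change under rotation
    expect_equal(vapply(rot, function(a) nrow(a$offsets), 0L),
                 vapply(arrays, function(a) nrow(a$offsets), 0L))
    expect_equal(vapply(rot, `[[`, 0, "disc_radius_mm"),
                 vapply(arrays, `[[`, 0, "disc_radius_mm"))
  }
})

test_that("the protocol defines exactly 7 plans with the published angles", {
  plans <- protocol_plans()
  expect_length(plans, 7)
  expect_equal(vapply(plans, `[[`, "", "plan_id"), paste0("Plan", 1:7))
  expect_equal(vapply(plans, `[[`, "", "plane"),
               c("none", rep("axial", 4), rep("sagittal", 2)))
  expect_equal(vapply(plans, `[[`, 0, "angle_deg"),
               c(0, 15, -15, 30, -30, 10, -10))
  expect_error(plan_spec("x", "none", 5), "angle 0")
})

test_that("rotated montages mirror across the mid-sagittal plane", {
  g <- generate_phantom(fixture_spec("symmetric"))
  arrays <- place_reference_arrays(tumor_centroid(g))
  surf <- surface_mask(body_mask(g))
  d <- dim(g$labels)
  # under x-reflection the +theta montage maps onto the -theta montage
  # (anterior<->anterior, posterior<->posterior, left<->right)
  pairing <- c(1, 2, 4, 3)
  for (ang in c(15, 30)) {
    plus <- rotate_plan(arrays, plan_spec("p", "axial", ang))
    minus <- rotate_plan(arrays, plan_spec("m", "axial", -ang))
    for (k in 1:4) {
      vp <- unlist(lapply(realize_array(plus[[k]], g, surf), `[[`, "voxels"))
      vm <- unlist(lapply(realize_array(minus[[pairing[k]]], g, surf),
                          `[[`, "voxels"))
      expect_setequal(mirror_voxels(vp, d), vm)
    }
  }
})

test_that("unknown rotation planes are rejected", {
  arrays <- place_reference_arrays(c(0, 0, 0))
  expect_error(rotate_plan(arrays, list(plane = "coronal", angle_deg = 5)),
               "unknown rotation plane")
})
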