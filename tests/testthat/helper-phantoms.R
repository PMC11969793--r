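# Shared fixtures, all generated in code.

# spherical body of radius 40 mm, tiny central tumor; used for ray
# projection geometry
sphere_phantom <- function(spacing = 2, n = 45) {
  generate_phantom(phantom_spec(shape = rep(n, 3), spacing = spacing,
                                body_semiaxes = c(40, 40, 40),
                                organs = list(),
                                tumor_center = c(0, 0, 0),
                                tumor_radius_mm = 6))
}

# shipped fixture specs (text configs under inst/extdata)
fixture_spec <- function(which = c("asymmetric", "symmetric")) {
  which <- match.arg(which)
  read_phantom_spec(system.file("extdata",
                                paste0("synthetic_", which, "_phantom.yaml"),
                                package = "ttfplan"))
}

# homogeneous (or layered) rectangular slab with full-face plate
# electrodes on the x faces; returns everything needed for solve_pair
slab_problem <- function(n = c(16, 12, 12), spacing = c(2, 2, 2),
                         sigma_profile = rep(0.1, n[1])) {
  sigma <- array(rep(sigma_profile, times = prod(n[2:3])), n)
  d <- n
  idx <- function(i) {
    g <- as.matrix(expand.grid(j = seq_len(d[2]), k = seq_len(d[3])))
    ijk_to_lin(cbind(i, g[, 1], g[, 2]), d)
  }
  list(sigma = sigma, spacing = spacing,
       source = idx(1), sink = idx(d[1]),
       cross_area_m2 = prod(n[2:3] * spacing[2:3]) * 1e-6)
}

# independent linear-index helpers mirroring the package's convention
ijk_to_lin <- function(ijk, d) {
  ijk <- matrix(ijk, ncol = 3)
  (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + ijk[, 1]
}

lin_to_ijk <- function(lin, d) {
  lin0 <- lin - 1
  cbind(lin0 %% d[1] + 1, (lin0 %/% d[1]) %% d[2] + 1,
        lin0 %/% (d[1] * d[2]) + 1)
}

# mirror a linear-index set across the mid-sagittal (x) plane
mirror_voxels <- function(v, d) {
  ijk <- lin_to_ijk(v, d)
  ijk[, 1] <- d[1] + 1 - ijk[, 1]
  ijk_to_lin(ijk, d)
}

# random connected conductivity grid for solver oracle checks: a cube
# body with smoothly varying random tissue conductivities
random_sigma <- function(n, contrast = c(0.05, 1.5)) {
  labs <- sample(1:4, prod(rep(n, 3)), replace = TRUE)
  vals <- sort(stats::runif(4, contrast[1], contrast[2]))
  array(vals[labs], rep(n, 3))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
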