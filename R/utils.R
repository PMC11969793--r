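# Internal helpers shared across modules.

# Unit conventions: world coordinates and spacings are millimetres; the
# solver works in SI (metres, volts, siemens, amperes); fields are reported
# in V/cm and currents in mA (RMS).

MM_PER_M <- 1000
VCM_PER_VMM <- 10   # 1 V/mm = 10 V/cm

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# world position (mm) of 1-based voxel indices; a voxel's world position is
# its center and voxel (1,1,1) sits at `origin`
voxel_to_world <- function(ijk, spacing, origin) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, c(1, 1, 1)) , 2, spacing, `*`) +
    matrix(origin, nrow(ijk), 3, byrow = TRUE)
}

world_to_voxel <- function(xyz, spacing, origin) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, origin), 2, spacing, `/`) + 1
}

# world coordinate grids along each axis (vectors, mm)
axis_coords <- function(dim, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * spacing[a])
}

# shift a 3-D array by one voxel along `axis` in direction `dir` (+1/-1),
# padding with `fill`; shift_array(x, 1, +1)[i,,] == x[i-1,,]
shift_array <- function(x, axis, dir, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n < 2) return(out)
  if (dir > 0) {
    idx_src[[axis]] <- 1:(n - 1); idx_dst[[axis]] <- 2:n
  } else {
    idx_src[[axis]] <- 2:n; idx_dst[[axis]] <- 1:(n - 1)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Body-surface mask
#'
#' In-body voxels with at least one face neighbour outside the mask
#' (the grid boundary counts as exterior). Electrode contact voxels are
#' always surface voxels.
#'
#' @param body logical 3-D body mask.
#' @return logical array of surface voxels.
#' @export
surface_mask <- function(body) {
  stopifnot(is.logical(body), length(dim(body)) == 3)
  surf <- array(FALSE, dim(body))
  for (a in 1:3) for (s in c(-1, 1)) {
    nb <- shift_array(body, a, s, fill = FALSE)
    surf <- surf | (body & !nb)
  }
  surf
}

# single face-connected component check via vectorized flood fill
is_connected <- function(mask) {
  n_total <- sum(mask)
  if (n_total == 0L) return(FALSE)
  seed <- which(mask)[1]
  reached <- array(FALSE, dim(mask))
  reached[seed] <- TRUE
  repeat {
    grown <- reached
    for (a in 1:3) for (s in c(-1, 1)) {
      grown <- grown | shift_array(reached, a, s, fill = FALSE)
    }
    grown <- grown & mask
    if (sum(grown) == sum(reached)) break
    reached <- grown
  }
  sum(reached) == n_total
}

# linear index <-> (i,j,k) for dim d
lin_to_ijk <- function(lin, d) {
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i + 1, j + 1, k + 1)
}

ijk_to_lin <- function(ijk, d) {
  ijk <- matrix(ijk, ncol = 3)
  (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + ijk[, 1]
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector")
  v / n
}
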