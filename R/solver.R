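#' Quasi-static conduction solver
#'
#' At TTFields frequencies (~150 kHz) the electric field inside the body
#' obeys the conduction equation div(sigma grad phi) = 0 with E =
#' -grad(phi) (displacement currents neglected). The discretization is
#' cell-centered finite volumes on the voxel grid with a 7-point stencil
#' and harmonic averaging of the conductivity on cell faces, which
#' conserves current flux exactly across tissue interfaces. Electrode
#' patches are driven as equipotential Dirichlet surfaces (+1 V source,
#' -1 V sink); by linearity the solution is rescaled afterwards so that
#' the injected current equals the requested target. The exterior
#' boundary is zero-flux (no current leaves the skin outside the
#' electrodes).
#'
#' @name solver
NULL

#' Solve one electrode pair
#'
#' @param sigma 3-D conductivity array (S/m); 0 marks the exterior.
#' @param spacing voxel spacing, mm (length 3).
#' @param source_voxels,sink_voxels linear indices of the contact voxels
#'   of the source and sink arrays (all patches of an array are held
#'   equipotential).
#' @param target_mA requested injected current, mA RMS.
#' @param tol relative residual tolerance of the conjugate-gradient
#'   solve.
#' @param maxit iteration cap; defaults to the number of unknowns.
#' @return list with `phi` (potential, V, NA outside the body),
#'   `injected_mA`, `extracted_mA`, `residual`, `iterations`.
#' @export
solve_pair <- function(sigma, spacing, source_voxels, sink_voxels,
                       target_mA, tol = 1e-8, maxit = NULL) {
  d <- dim(sigma)
  if (target_mA <= 0) stop("target current must be > 0")
  if (!length(source_voxels) || !length(sink_voxels))
    stop("empty electrode voxel set")
  if (length(intersect(source_voxels, sink_voxels)))
    stop("source and sink share voxels")
  body_idx <- which(sigma > 0)
  if (!all(sigma[source_voxels] > 0) || !all(sigma[sink_voxels] > 0))
    stop("electrode voxels must lie on conducting tissue")

  sp_m <- spacing / MM_PER_M
  # collect faces between conducting voxels
  from <- integer(0); to <- integer(0); g <- numeric(0)
  for (a in 1:3) {
    area_over_h <- prod(sp_m[-a]) / sp_m[a]
    s2 <- shift_array(sigma, a, -1, fill = 0)
    idx <- which(sigma > 0 & s2 > 0)
    gi <- 2 * sigma[idx] * s2[idx] / (sigma[idx] + s2[idx]) * area_over_h
    stride <- c(1L, d[1], d[1] * d[2])[a]
    from <- c(from, idx); to <- c(to, idx + stride); g <- c(g, gi)
  }

  phi_d <- numeric(prod(d))
  is_dir <- logical(prod(d))
  is_dir[source_voxels] <- TRUE; phi_d[source_voxels] <- 1
  is_dir[sink_voxels] <- TRUE; phi_d[sink_voxels] <- -1

  free <- body_idx[!is_dir[body_idx]]
  n <- length(free)
  if (n == 0) stop("no free voxels between electrodes")
  rank <- integer(prod(d)); rank[free] <- seq_len(n)

  ff <- !is_dir[from] & !is_dir[to]     # free-free faces
  fd <- xor(is_dir[from], is_dir[to])   # free-dirichlet faces

  i_ff <- rank[from[ff]]; j_ff <- rank[to[ff]]; g_ff <- g[ff]
  # diagonal: every face (incl. to Dirichlet) adds g to both/one endpoint
  diag_v <- numeric(n)
  add_diag <- function(idx, val) {
    r <- rank[idx]
    keep <- r > 0
    if (any(keep)) {
      tab <- rowsum(val[keep], r[keep])
      diag_v[as.integer(rownames(tab))] <<- diag_v[as.integer(rownames(tab))] + tab[, 1]
    }
  }
  add_diag(from, g); add_diag(to, g)

  rhs <- numeric(n)
  if (any(fd)) {
    f_free <- ifelse(is_dir[from[fd]], to[fd], from[fd])
    f_dir <- ifelse(is_dir[from[fd]], from[fd], to[fd])
    tab <- rowsum(g[fd] * phi_d[f_dir], rank[f_free])
    rhs[as.integer(rownames(tab))] <- tab[, 1]
  }

  A <- Matrix::sparseMatrix(i = c(i_ff, j_ff, seq_len(n)),
                            j = c(j_ff, i_ff, seq_len(n)),
                            x = c(-g_ff, -g_ff, diag_v),
                            dims = c(n, n))
  if (is.null(maxit)) maxit <- max(1000L, n)
  sol <- pcg_solve(A, rhs, tol = tol, maxit = maxit)
  if (sol$residual > tol)
    stop(sprintf("solver did not converge: relative residual %.3e after %d iterations (source and sink may be disconnected through the body)",
                 sol$residual, sol$iterations))

  phi <- rep(NA_real_, prod(d))
  phi[free] <- sol$x
  phi[source_voxels] <- 1; phi[sink_voxels] <- -1

  # currents through electrode faces (A): sum g * (phi_e - phi_neighbour)
  electrode_current <- function(evox) {
    sel_f <- from %in% evox & !(to %in% evox)
    sel_t <- to %in% evox & !(from %in% evox)
    sum(g[sel_f] * (phi[from[sel_f]] - phi[to[sel_f]])) +
      sum(g[sel_t] * (phi[to[sel_t]] - phi[from[sel_t]]))
  }
  i_src <- electrode_current(source_voxels)
  i_snk <- -electrode_current(sink_voxels)
  if (i_src <= 0) stop("non-positive injected current; malformed montage")

  scale <- (target_mA / 1000) / i_src
  phi <- phi * scale
  dim(phi) <- d
  list(phi = phi,
       injected_mA = i_src * scale * 1000,
       extracted_mA = i_snk * scale * 1000,
       residual = sol$residual,
       iterations = sol$iterations)
}

# Jacobi-preconditioned conjugate gradients; deterministic.
pcg_solve <- function(A, b, tol = 1e-8, maxit = length(b)) {
  n <- length(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(n), residual = 0, iterations = 0L))
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    if (res <= tol) return(list(x = x, residual = res, iterations = it))
    z <- dinv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, residual = sqrt(sum(r^2)) / nb, iterations = maxit)
}

#' Target current from current density
#'
#' The drive current of a pair is the prescribed current density times
#' the (analytic) contact area of its array.
#'
#' @param array an `electrode_array`.
#' @param current_density_mA_cm2 current density, mA RMS per cm^2.
#' @return target current, mA RMS.
#' @export
target_current <- function(array, current_density_mA_cm2) {
  current_density_mA_cm2 * array_area_cm2(array)
}

#' Electric-field magnitude from a potential grid
#'
#' Central differences in the body interior, one-sided at the domain
#' boundary (where a neighbour is exterior); exterior voxels get 0.
#'
#' @param phi 3-D potential array (V) with NA outside the body.
#' @param spacing voxel spacing, mm.
#' @return 3-D array of |E| in V/cm.
#' @export
field_magnitude <- function(phi, spacing) {
  d <- dim(phi)
  inb <- !is.na(phi)
  phi0 <- phi; phi0[!inb] <- 0
  e2 <- array(0, d)
  for (a in 1:3) {
    h <- spacing[a]
    pp <- shift_array(phi0, a, +1); ip <- shift_array(inb, a, +1, fill = FALSE)
    pm <- shift_array(phi0, a, -1); im <- shift_array(inb, a, -1, fill = FALSE)
    grad <- array(0, d)
    both <- inb & ip & im
    grad[both] <- (pm[both] - pp[both]) / (2 * h)
    fwd <- inb & im & !ip
    grad[fwd] <- (pm[fwd] - phi0[fwd]) / h
    bwd <- inb & ip & !im
    grad[bwd] <- (phi0[bwd] - pp[bwd]) / h
    e2 <- e2 + grad^2
  }
  sqrt(e2) * VCM_PER_VMM
}

#' Combine the two sequential field orientations
#'
#' The device energizes the AP and LR pairs sequentially; a single
#' per-plan field map is formed from the two per-pair magnitude maps.
#' The default rule is the duty-weighted mean of the magnitudes
#' (weights = fraction of the cycle each pair is active); a "max" rule
#' is also available.
#'
#' @param e_ap,e_lr per-pair field-magnitude grids (V/cm).
#' @param weights nonnegative duty weights summing to 1.
#' @param rule "mean" (duty-weighted mean) or "max".
#' @return combined field-magnitude grid, V/cm.
#' @export
combine_pairs <- function(e_ap, e_lr, weights = c(0.5, 0.5),
                          rule = c("mean", "max")) {
  rule <- match.arg(rule)
  if (!identical(dim(e_ap), dim(e_lr))) stop("field grid shape mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  if (rule == "mean") weights[1] * e_ap + weights[2] * e_lr
  else pmax(e_ap, e_lr)
}

# dense direct solve of the same system; oracle for small grids
solve_pair_dense <- function(sigma, spacing, source_voxels, sink_voxels,
                             target_mA) {
  d <- dim(sigma)
  sp_m <- spacing / MM_PER_M
  from <- integer(0); to <- integer(0); g <- numeric(0)
  for (a in 1:3) {
    area_over_h <- prod(sp_m[-a]) / sp_m[a]
    s2 <- shift_array(sigma, a, -1, fill = 0)
    idx <- which(sigma > 0 & s2 > 0)
    gi <- 2 * sigma[idx] * s2[idx] / (sigma[idx] + s2[idx]) * area_over_h
    stride <- c(1L, d[1], d[1] * d[2])[a]
    from <- c(from, idx); to <- c(to, idx + stride); g <- c(g, gi)
  }
  phi_d <- numeric(prod(d)); is_dir <- logical(prod(d))
  is_dir[source_voxels] <- TRUE; phi_d[source_voxels] <- 1
  is_dir[sink_voxels] <- TRUE; phi_d[sink_voxels] <- -1
  body_idx <- which(sigma > 0)
  free <- body_idx[!is_dir[body_idx]]
  n <- length(free)
  rank <- integer(prod(d)); rank[free] <- seq_len(n)
  A <- matrix(0, n, n); rhs <- numeric(n)
  for (k in seq_along(from)) {
    f <- from[k]; t_ <- to[k]; gk <- g[k]
    rf <- rank[f]; rt <- rank[t_]
    if (rf > 0) A[rf, rf] <- A[rf, rf] + gk
    if (rt > 0) A[rt, rt] <- A[rt, rt] + gk
    if (rf > 0 && rt > 0) {
      A[rf, rt] <- A[rf, rt] - gk
      A[rt, rf] <- A[rt, rf] - gk
    } else if (rf > 0) rhs[rf] <- rhs[rf] + gk * phi_d[t_]
    else if (rt > 0) rhs[rt] <- rhs[rt] + gk * phi_d[f]
  }
  x <- solve(A, rhs)
  phi <- rep(NA_real_, prod(d))
  phi[free] <- x
  phi[source_voxels] <- 1; phi[sink_voxels] <- -1
  i_src <- {
    sel_f <- from %in% source_voxels & !(to %in% source_voxels)
    sel_t <- to %in% source_voxels & !(from %in% source_voxels)
    sum(g[sel_f] * (phi[from[sel_f]] - phi[to[sel_f]])) +
      sum(g[sel_t] * (phi[to[sel_t]] - phi[from[sel_t]]))
  }
  scale <- (target_mA / 1000) / i_src
  phi <- phi * scale
  dim(phi) <- d
  list(phi = phi, injected_mA = target_mA)
}
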