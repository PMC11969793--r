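#' Tumor centroid in world coordinates
#'
#' @param grid a [tissue_grid()] with a nonempty GTV.
#' @return numeric length-3 world position (mm) of the GTV centroid.
#' @export
tumor_centroid <- function(grid) {
  idx <- which(gtv_mask(grid))
  if (!length(idx)) stop("empty GTV")
  ijk <- lin_to_ijk(idx, dim(grid$labels))
  colMeans(voxel_to_world(ijk, grid$spacing, grid$origin))
}

#' Transducer-array layout configuration
#'
#' The clinical abdominal arrays carry 20 (anterior/posterior pair) and
#' 13 (left/right pair) disc electrodes. Disc dimensions are not public;
#' the default disc radius is chosen so that the 20-disc array area is
#' 1414/31 = 45.6 cm-squared, reproducing the device's printed maximum
#' output (1414 mA RMS at 31 mA RMS/cm-squared). The 20 discs sit in a
#' 4-row by 5-column grid, the 13 discs in rows of 4-5-4, both at 25 mm
#' center spacing. All values are configurable.
#'
#' @param disc_radius_mm electrode disc radius, mm.
#' @param spacing_mm center-to-center spacing within an array, mm.
#' @return layout configuration list.
#' @export
electrode_layout <- function(disc_radius_mm = sqrt(1414 / 31 / 20 / pi) * 10,
                             spacing_mm = 25) {
  list(disc_radius_mm = disc_radius_mm, spacing_mm = spacing_mm)
}

# patch-center offsets (u = lateral, v = superior-inferior), mm
layout_offsets <- function(kind, spacing_mm) {
  if (kind == "grid20") {          # 4 rows x 5 cols
    u <- (-2:2) * spacing_mm
    v <- (seq_len(4) - 2.5) * spacing_mm
    as.matrix(expand.grid(u = u, v = v))
  } else if (kind == "rows454") {  # rows of 4, 5, 4
    rows <- list(`-1` = (-1.5:1.5) * spacing_mm,
                 `0`  = (-2:2) * spacing_mm,
                 `1`  = (-1.5:1.5) * spacing_mm)
    do.call(rbind, lapply(names(rows), function(r)
      cbind(u = rows[[r]], v = as.numeric(r) * spacing_mm)))
  } else stop("unknown layout kind: ", kind)
}

new_array <- function(pair_id, side, polarity, d, u, v, offsets, center,
                      radius) {
  structure(list(pair_id = pair_id, side = side, polarity = polarity,
                 d = d, u = u, v = v, offsets = offsets, center = center,
                 disc_radius_mm = radius),
            class = "electrode_array")
}

#' @method print electrode_array
#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %s/%s (%s), %d discs r=%.1f mm, dir (%.2f %.2f %.2f)\n",
              x$pair_id, x$side, x$polarity, nrow(x$offsets),
              x$disc_radius_mm, x$d[1], x$d[2], x$d[3]))
  invisible(x)
}

#' Place the reference-plan arrays
#'
#' Builds the four transducer arrays of the reference montage: an
#' anterior-posterior pair (20 discs each) and a left-right pair (13
#' discs each), centered on the rays from the tumor center along the
#' +y/-y and -x/+x world axes. Geometry is stored as center + direction
#' + in-plane basis; [realize_array()] projects it onto the body
#' surface.
#'
#' @param center world mm point the montage is referenced to (tumor
#'   centroid).
#' @param layout an [electrode_layout()].
#' @return list of 4 `electrode_array` objects (anterior, posterior,
#'   left, right).
#' @export
place_reference_arrays <- function(center, layout = electrode_layout()) {
  off20 <- layout_offsets("grid20", layout$spacing_mm)
  off13 <- layout_offsets("rows454", layout$spacing_mm)
  r <- layout$disc_radius_mm
  list(
    new_array("AP", "anterior",  "source", c(0, 1, 0),  c(1, 0, 0), c(0, 0, 1),
              off20, center, r),
    new_array("AP", "posterior", "sink",   c(0, -1, 0), c(1, 0, 0), c(0, 0, 1),
              off20, center, r),
    new_array("LR", "left",  "source", c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              off13, center, r),
    new_array("LR", "right", "sink",   c(1, 0, 0),  c(0, 1, 0), c(0, 0, 1),
              off13, center, r))
}

#' Project a ray from inside the body onto the body surface
#'
#' Marches from `origin` along `direction` until the ray first leaves
#' the body mask; returns the crossing point and the set of surface
#' voxels within `patch_radius_mm` of it.
#'
#' @param origin world mm point inside the body.
#' @param direction nonzero direction vector.
#' @param grid a [tissue_grid()].
#' @param patch_radius_mm disc radius for the contact-voxel query.
#' @param surf optional precomputed [surface_mask()] of the body.
#' @return list with `point` (world mm) and `voxels` (linear indices of
#'   contact voxels).
#' @export
project_to_surface <- function(origin, direction, grid, patch_radius_mm = 9,
                               surf = NULL) {
  d <- dim(grid$labels)
  dir <- normalize3(direction)
  body <- body_mask(grid)
  step <- min(grid$spacing) / 2
  t_max <- sqrt(sum((d * grid$spacing)^2))
  ts <- seq(0, t_max, by = step)
  pts <- matrix(origin, length(ts), 3, byrow = TRUE) +
    outer(ts, dir)
  ijk <- round(world_to_voxel(pts, grid$spacing, grid$origin))
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  inside <- rep(FALSE, length(ts))
  inside[ok] <- body[ijk_to_lin(ijk[ok, , drop = FALSE], d)]
  if (!inside[1]) stop("ray origin is not inside the body")
  first_out <- which(!inside)[1]
  if (is.na(first_out)) stop("ray never exits the body mask")
  point <- (pts[first_out - 1, ] + pts[first_out, ]) / 2

  if (is.null(surf)) surf <- surface_mask(body)
  sv <- which(surf)
  svw <- voxel_to_world(lin_to_ijk(sv, d), grid$spacing, grid$origin)
  dist2 <- (svw[, 1] - point[1])^2 + (svw[, 2] - point[2])^2 +
    (svw[, 3] - point[3])^2
  # the nearest surface voxel is always part of the patch, so a disc can
  # never lose contact on coarse grids
  vox <- union(sv[which.min(dist2)], sv[dist2 <= patch_radius_mm^2])
  list(point = point, voxels = vox)
}

#' Realize an array's electrode patches on a phantom surface
#'
#' Casts one ray per disc (array center ray translated by the disc's
#' in-plane offset) to the body surface and collects the contact voxels
#' of each disc. A surface voxel claimed by several discs is assigned to
#' the disc whose surface point is nearest, so patches never share
#' voxels.
#'
#' @param array an `electrode_array`.
#' @param grid a [tissue_grid()].
#' @param surf optional precomputed [surface_mask()].
#' @return list of patches, each `list(center, radius, voxels)`, plus
#'   attribute `array` carrying the geometry.
#' @export
realize_array <- function(array, grid, surf = NULL) {
  if (is.null(surf)) surf <- surface_mask(body_mask(grid))
  n <- nrow(array$offsets)
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    o <- array$center + array$offsets[i, 1] * array$u +
      array$offsets[i, 2] * array$v
    p <- project_to_surface(o, array$d, grid, array$disc_radius_mm, surf)
    patches[[i]] <- list(center = p$point, radius = array$disc_radius_mm,
                         voxels = p$voxels)
  }
  # resolve shared voxels: nearest disc center wins
  all_v <- unlist(lapply(patches, `[[`, "voxels"))
  dup <- unique(all_v[duplicated(all_v)])
  if (length(dup)) {
    dgrid <- dim(grid$labels)
    for (v in dup) {
      w <- voxel_to_world(lin_to_ijk(v, dgrid), grid$spacing, grid$origin)
      owners <- which(vapply(patches, function(p) v %in% p$voxels, logical(1)))
      dist <- vapply(owners, function(i)
        sum((patches[[i]]$center - w)^2), numeric(1))
      keep <- owners[which.min(dist)]
      for (i in setdiff(owners, keep))
        patches[[i]]$voxels <- setdiff(patches[[i]]$voxels, v)
    }
  }
  empty <- vapply(patches, function(p) length(p$voxels) == 0L, logical(1))
  if (any(empty))
    stop(sum(empty), " electrode disc(s) have no contact voxels; ",
         "increase resolution or disc radius")
  structure(patches, array = array)
}

#' Analytic contact area of an array, cm^2
#'
#' Total disc area (number of discs times pi r^2), independent of the
#' voxelization.
#'
#' @param array an `electrode_array`.
#' @return area in cm^2.
#' @export
array_area_cm2 <- function(array) {
  n <- nrow(array$offsets)
  if (n == 0 || array$disc_radius_mm <= 0) stop("array has zero contact area")
  n * pi * array$disc_radius_mm^2 / 100
}

#' Treatment-plan specification
#'
#' One montage of the rotation-scan protocol: the reference geometry
#' rotated about the tumor center by `angle_deg` in the axial plane
#' (about the superior-inferior axis) or sagittal plane (about the
#' left-right axis). The reference plan has `plane = "none"`, angle 0.
#'
#' @param plan_id identifier (e.g. "Plan1").
#' @param plane one of "none", "axial", "sagittal".
#' @param angle_deg rotation angle, degrees; positive is clockwise (see
#'   the package vignette for the viewpoint convention).
#' @return object of class `plan_spec`.
#' @export
plan_spec <- function(plan_id, plane = c("none", "axial", "sagittal"),
                      angle_deg = 0) {
  plane <- match.arg(plane)
  if (plane == "none" && angle_deg != 0)
    stop("reference plan must have angle 0")
  structure(list(plan_id = plan_id, plane = plane,
                 angle_deg = as.numeric(angle_deg)),
            class = "plan_spec")
}

#' The 7-plan rotation-scan protocol
#'
#' One reference plan plus six trial plans: +/-15 and +/-30 degrees in
#' the axial plane and +/-10 degrees in the sagittal plane, numbered
#' Plan1..Plan7 (Plan1 = reference; Plan2..5 axial +15/-15/+30/-30;
#' Plan6..7 sagittal +10/-10).
#'
#' @return list of 7 [plan_spec()] objects.
#' @export
protocol_plans <- function() {
  list(plan_spec("Plan1", "none", 0),
       plan_spec("Plan2", "axial", 15),
       plan_spec("Plan3", "axial", -15),
       plan_spec("Plan4", "axial", 30),
       plan_spec("Plan5", "axial", -30),
       plan_spec("Plan6", "sagittal", 10),
       plan_spec("Plan7", "sagittal", -10))
}

# Rotation matrices. Positive angle = clockwise in the standard
# radiological view: axial viewed from inferior (rotation about z),
# sagittal viewed from the patient's left (rotation about x).
rotation_matrix <- function(plane, angle_deg) {
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(plane,
         none = diag(3),
         axial = matrix(c(c_, -s_, 0,
                          s_, c_, 0,
                          0, 0, 1), 3, 3, byrow = TRUE),
         sagittal = matrix(c(1, 0, 0,
                             0, c_, -s_,
                             0, s_, c_), 3, 3, byrow = TRUE),
         stop("unknown rotation plane: ", plane))
}

#' Rotate the montage for a trial plan
#'
#' Applies the plan's rotation rigidly to all four arrays (direction
#' rays and in-plane bases rotate together about the tumor center, so
#' the perpendicularity of the two pairs is preserved); patches are
#' re-projected onto the surface when the arrays are realized.
#'
#' @param arrays list of `electrode_array` from
#'   [place_reference_arrays()].
#' @param plan a [plan_spec()].
#' @return list of rotated `electrode_array` objects.
#' @export
rotate_plan <- function(arrays, plan) {
  R <- rotation_matrix(plan$plane, plan$angle_deg)
  lapply(arrays, function(a) {
    a$d <- as.numeric(R %*% a$d)
    a$u <- as.numeric(R %*% a$u)
    a$v <- as.numeric(R %*% a$v)
    a
  })
}
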