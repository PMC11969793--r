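#' Segmented tissue label grid
#'
#' The basic anatomical container: a 3-D integer label volume with voxel
#' spacing and world origin (all in mm), and a table mapping labels to
#' tissue names. Label 0 is always `"body-exterior"`; the gross tumor
#' volume carries the name `"GTV"`. World axes are ordered left-to-right
#' (x), posterior-to-anterior (y), inferior-to-superior (z); a voxel's
#' world position is the position of its center.
#'
#' @param labels 3-D integer array of tissue labels (0 = exterior).
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param origin numeric length-3, world position (mm) of the first voxel.
#' @param label_names named character vector mapping label (as name) to
#'   tissue name; must cover every label present, include `"0" =
#'   "body-exterior"`, and contain a `"GTV"` entry.
#' @return object of class `tissue_grid`.
#' @export
tissue_grid <- function(labels, spacing, origin = NULL,
                        label_names) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-D array")
  if (any(dim(labels) == 0)) stop("zero-size grid")
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (is.null(origin)) origin <- -(dim(labels) - 1) * spacing / 2
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3)
  g <- structure(list(labels = labels, spacing = spacing, origin = origin,
                      label_names = label_names),
                 class = "tissue_grid")
  validate_tissue_grid(g)
  g
}

#' @method print tissue_grid
#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid> ", paste(dim(x$labels), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  tab <- table(x$labels)
  nm <- x$label_names[names(tab)]
  cat(sprintf("  %-14s label %-3s %8d voxels\n", nm, names(tab), as.integer(tab)),
      sep = "")
  invisible(x)
}

validate_tissue_grid <- function(g, check_connectivity = FALSE) {
  present <- unique(as.vector(g$labels))
  nz <- setdiff(present, 0L)
  missing <- setdiff(as.character(nz), names(g$label_names))
  if (length(missing))
    stop("labels without a name entry: ", paste(missing, collapse = ", "))
  if (!"GTV" %in% g$label_names) stop("label_names must include a GTV entry")
  gtv_label <- as.integer(names(g$label_names)[g$label_names == "GTV"][1])
  if (!any(g$labels == gtv_label)) stop("GTV is empty")
  if (check_connectivity && !is_connected(g$labels != 0L))
    stop("body mask is not a single connected component")
  invisible(TRUE)
}

#' Body and GTV masks
#'
#' @param grid a [tissue_grid()].
#' @return logical array: voxels inside the body (`body_mask`) or in the
#'   gross tumor volume (`gtv_mask`).
#' @export
body_mask <- function(grid) grid$labels != 0L

gtv_label_of <- function(grid) {
  as.integer(names(grid$label_names)[grid$label_names == "GTV"][1])
}

#' @rdname body_mask
#' @export
gtv_mask <- function(grid) grid$labels == gtv_label_of(grid)

#' Phantom specification
#'
#' Declarative description of a synthetic segmented abdominal phantom:
#' an ellipsoidal body of background muscle containing ellipsoidal /
#' cylindrical organ inclusions and a spherical gross tumor volume. The
#' phantom stands in for segmented patient CT data, which the original
#' study did not release.
#'
#' Organs are painted in list order (later organs overwrite earlier ones
#' where they overlap); the GTV is always painted last. Organs flagged
#' `shiftable` are translated laterally (+x, toward the patient's right)
#' by `asymmetry_mm`, which breaks left-right symmetry so that rotated
#' electrode montages can genuinely outperform the reference montage.
#' `jitter_mm` adds a deterministic (seeded) normal perturbation to organ
#' centers, used to emulate inter-patient variability in cohorts.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel size mm (scalar or length 3).
#' @param body_semiaxes body ellipsoid semi-axes mm (x, y, z).
#' @param organs list of organ descriptors; see [default_organs()].
#' @param tumor_center world mm position of the tumor center.
#' @param tumor_radius_mm tumor sphere radius, mm.
#' @param asymmetry_mm lateral (+x) shift applied to shiftable organs, mm.
#' @param jitter_mm SD of the seeded perturbation of organ centers, mm.
#' @param seed integer random seed; fixed seed gives a byte-identical
#'   phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = 5,
                         body_semiaxes = c(150, 105, 170),
                         organs = default_organs(),
                         tumor_center = c(5, 5, 0),
                         tumor_radius_mm = 22,
                         asymmetry_mm = 0,
                         jitter_mm = 0,
                         seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spec <- structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                         body_semiaxes = as.numeric(body_semiaxes),
                         organs = organs,
                         tumor_center = as.numeric(tumor_center),
                         tumor_radius_mm = as.numeric(tumor_radius_mm),
                         asymmetry_mm = as.numeric(asymmetry_mm),
                         jitter_mm = as.numeric(jitter_mm),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (any(spec$shape <= 0)) stop("zero-size grid")
  spec
}

organ <- function(tissue, center, semiaxes, shape = "ellipsoid",
                  shiftable = FALSE) {
  list(tissue = tissue, center = as.numeric(center),
       semiaxes = as.numeric(semiaxes), shape = shape,
       shiftable = shiftable)
}

#' Default organ set for the abdominal phantom
#'
#' A deliberate subset of a full abdominal segmentation, sufficient to
#' produce realistic field inhomogeneity around a pancreatic tumor:
#' background muscle body, spine (cortical bone, a posterior z-cylinder),
#' liver (right), stomach (left, shiftable), spleen (far left,
#' shiftable), both kidneys (posterior), and pancreas (central,
#' hosting the GTV). Centers/semi-axes are in mm about the body center.
#'
#' @return list of organ descriptors.
#' @export
default_organs <- function() {
  list(
    organ("bone",     c(0, -60, 0),   c(18, 18, 1e4), shape = "zcylinder"),
    organ("liver",    c(60, 25, 55),  c(70, 60, 75)),
    organ("stomach",  c(-45, 30, 45), c(45, 38, 50), shiftable = TRUE),
    organ("spleen",   c(-95, -10, 50),c(30, 28, 40), shiftable = TRUE),
    organ("kidney",   c(-65, -50, -25), c(25, 22, 45)),
    organ("kidney",   c(65, -50, -25),  c(25, 22, 45)),
    organ("pancreas", c(0, 5, 0),     c(65, 22, 18))
  )
}

paint_shape <- function(labels, o, coords) {
  cx <- (coords[[1]] - o$center[1]) / o$semiaxes[1]
  cy <- (coords[[2]] - o$center[2]) / o$semiaxes[2]
  cz <- (coords[[3]] - o$center[3]) / o$semiaxes[3]
  d <- dim(labels)
  if (identical(o$shape, "zcylinder")) {
    q <- outer(cx^2, cy^2, `+`)
    inside <- array(rep(q <= 1, times = d[3]), d)
    inside[, , abs(cz) > 1] <- FALSE
  } else {
    q <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    inside <- q <= 1
  }
  inside
}

#' Generate a synthetic segmented phantom
#'
#' Rasterizes a [phantom_spec()] into a [tissue_grid()]. The grid is
#' world-centered: the body ellipsoid's center is the world origin.
#' Deterministic: the same spec (including seed) always yields the same
#' voxel grid.
#'
#' @param spec a [phantom_spec()].
#' @return a [tissue_grid()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  if (any(d <= 0)) stop("zero-size grid")
  origin <- -(d - 1) * spec$spacing / 2
  coords <- axis_coords(d, spec$spacing, origin)

  organs <- spec$organs
  if (length(organs)) {
    rng <- if (spec$jitter_mm > 0) {
      set.seed(spec$seed)
      matrix(stats::rnorm(3 * length(organs), 0, spec$jitter_mm),
             ncol = 3)
    } else matrix(0, length(organs), 3)
    for (i in seq_along(organs)) {
      organs[[i]]$center <- organs[[i]]$center + rng[i, ]
      if (isTRUE(organs[[i]]$shiftable))
        organs[[i]]$center[1] <- organs[[i]]$center[1] + spec$asymmetry_mm
    }
  }

  body <- paint_shape(array(0L, d),
                      organ("body", c(0, 0, 0), spec$body_semiaxes), coords)
  labels <- array(0L, d)
  labels[body] <- 1L
  tissues <- "muscle"

  for (o in organs) {
    inside <- paint_shape(labels, o, coords) & body
    if (!any(inside)) next
    lbl <- match(o$tissue, tissues)
    if (is.na(lbl)) { tissues <- c(tissues, o$tissue); lbl <- length(tissues) }
    labels[inside] <- lbl
  }

  # GTV last so it is never overwritten
  tum <- organ("GTV", spec$tumor_center, rep(spec$tumor_radius_mm, 3))
  inside <- paint_shape(labels, tum, coords)
  if (!any(inside)) stop("tumor contains no voxels at this resolution")
  if (any(inside & !body)) stop("tumor outside body")
  tissues <- c(tissues, "GTV")
  labels[inside] <- length(tissues)

  label_names <- c("body-exterior", tissues)
  names(label_names) <- as.character(0:length(tissues))
  tissue_grid(labels, spec$spacing, origin, label_names)
}

#' Read/write a phantom specification as YAML
#'
#' @param path file path.
#' @return `read_phantom_spec` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  s <- yaml::read_yaml(path)
  organs <- lapply(s$organs, function(o)
    organ(o$tissue, unlist(o$center), unlist(o$semiaxes),
          o$shape %||% "ellipsoid", isTRUE(o$shiftable)))
  phantom_spec(shape = unlist(s$shape), spacing = unlist(s$spacing),
               body_semiaxes = unlist(s$body_semiaxes), organs = organs,
               tumor_center = unlist(s$tumor_center),
               tumor_radius_mm = s$tumor_radius_mm,
               asymmetry_mm = s$asymmetry_mm %||% 0,
               jitter_mm = s$jitter_mm %||% 0,
               seed = s$seed %||% 1L)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Generate a cohort of phantoms emulating inter-patient variability
#'
#' Produces `n` phantoms from a base spec by re-seeding the organ-center
#' jitter, one phantom per synthetic "patient".
#'
#' @param n number of phantoms.
#' @param base a [phantom_spec()]; its `jitter_mm` should be > 0 for the
#'   cohort members to differ anatomically.
#' @param seed cohort-level seed; member i uses `seed + i`.
#' @return list of [tissue_grid()] objects.
#' @export
phantom_cohort <- function(n, base = phantom_spec(jitter_mm = 6, asymmetry_mm = 25),
                           seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    s <- base
    s$seed <- as.integer(seed + i)
    generate_phantom(s)
  })
}
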