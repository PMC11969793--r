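#' Tissue conductivity table
#'
#' Maps tissue names to electrical conductivity (S/m) at a stated
#' frequency. The shipped defaults are representative low-RF (150 kHz)
#' conduction values assembled from published human-tissue dielectric
#' compilations; they are explicit, editable configuration, not ground
#' truth, and the exterior is always non-conducting (excluded from the
#' solve domain).
#'
#' @param values named numeric vector, tissue name -> S/m. Must be > 0.
#' @param frequency_khz drive frequency the values refer to, kHz.
#' @return object of class `conductivity_table`.
#' @export
conductivity_table <- function(values = default_conductivities(),
                               frequency_khz = 150) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values <= 0)) stop("conductivity must be > 0 for every tissue")
  structure(list(frequency_khz = as.numeric(frequency_khz),
                 sigma = values),
            class = "conductivity_table")
}

#' @rdname conductivity_table
#' @export
default_conductivities <- function() {
  c(muscle   = 0.43,
    bone     = 0.021,
    lung     = 0.10,
    heart    = 0.22,
    esophagus = 0.53,
    liver    = 0.12,
    gallbladder = 0.90,
    stomach  = 0.54,
    pancreas = 0.52,
    spleen   = 0.13,
    kidney   = 0.27,
    `large intestine` = 0.55,
    `small intestine` = 0.57,
    bladder  = 0.30,
    fluid    = 1.50,
    GTV      = 0.30)
}

#' Read/write a conductivity table as YAML
#' @param path file path.
#' @export
read_conductivity_table <- function(path) {
  y <- yaml::read_yaml(path)
  conductivity_table(unlist(y$sigma), frequency_khz = y$frequency_khz %||% 150)
}

#' @rdname read_conductivity_table
#' @param table a [conductivity_table()].
#' @export
write_conductivity_table <- function(table, path) {
  yaml::write_yaml(list(frequency_khz = table$frequency_khz,
                        sigma = as.list(table$sigma)), path)
  invisible(path)
}

#' Per-voxel conductivity grid
#'
#' Looks up each voxel's tissue conductivity. Exterior voxels (label 0)
#' are set to 0 S/m, flagging them as outside the conduction domain.
#'
#' @param grid a [tissue_grid()].
#' @param table a [conductivity_table()].
#' @return 3-D numeric array, S/m.
#' @export
conductivity_grid <- function(grid, table) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(table, "conductivity_table"))
  labs <- sort(unique(as.vector(grid$labels)))
  lut <- numeric(max(labs) + 1)
  for (l in labs) {
    if (l == 0) next
    tn <- grid$label_names[[as.character(l)]]
    if (is.null(tn) || is.na(tn))
      stop("no tissue name for label ", l)
    s <- table$sigma[tn]
    if (is.na(s))
      stop("no conductivity entry for label ", l, " (tissue '", tn, "')")
    lut[l + 1] <- s
  }
  array(lut[grid$labels + 1L], dim(grid$labels))
}
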