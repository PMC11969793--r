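#' Field statistics over a structure
#'
#' Exact voxel-wise minimum, mean and maximum of the field over a mask
#' (typically the GTV).
#'
#' @param field 3-D field-magnitude array (V/cm).
#' @param mask logical array of the same shape.
#' @return named numeric: `E_min`, `E_mean`, `E_max` (V/cm).
#' @export
field_stats <- function(field, mask) {
  if (!any(mask)) stop("empty structure mask")
  v <- field[mask]
  c(E_min = min(v), E_mean = mean(v), E_max = max(v))
}

#' Homogeneity index
#'
#' HI = (E_max - E_min) / E_p, the radiotherapy homogeneity index with
#' field intensity in place of dose; lower values indicate a more
#' uniform field across the target.
#'
#' @param e_max,e_min maximum and minimum field over the GTV, V/cm.
#' @param e_p prescribed field intensity, V/cm (> 0).
#' @return dimensionless HI >= 0.
#' @export
homogeneity_index <- function(e_max, e_min, e_p) {
  if (e_p <= 0) stop("prescribed field must be > 0")
  if (e_max < e_min) stop("E_max < E_min")
  (e_max - e_min) / e_p
}

#' Coverage index
#'
#' CI = V100_GTV / V_GTV: the fraction of GTV voxels whose field is at
#' least the prescribed intensity (inclusive threshold). Values closer
#' to 1 indicate better coverage.
#'
#' @param field 3-D field-magnitude array (V/cm).
#' @param mask logical GTV mask.
#' @param e_p prescribed field intensity, V/cm (> 0).
#' @return CI in \[0, 1\].
#' @export
coverage_index <- function(field, mask, e_p) {
  if (!any(mask)) stop("empty structure mask")
  if (e_p <= 0) stop("prescribed field must be > 0")
  mean(field[mask] >= e_p)
}

#' Prescribed field intensity
#'
#' The prescription is the reference plan's mean GTV field; this single
#' value normalizes HI, CI and DVH curves for every plan of the same
#' phantom.
#'
#' @param reference_stats the reference plan's [field_stats()].
#' @return E_p in V/cm.
#' @export
prescribed_field <- function(reference_stats) {
  unname(reference_stats["E_mean"])
}

#' Dose-volume histogram (field-volume histogram)
#'
#' Cumulative curve of the fraction of a structure's volume whose field
#' is at least a given percentage of the prescribed intensity. By
#' construction the curve is 1 at 0% and monotone non-increasing, and
#' its value at the 100% bin equals the coverage index.
#'
#' @param field 3-D field-magnitude array (V/cm).
#' @param mask logical structure mask.
#' @param e_p prescribed field intensity, V/cm.
#' @param bin_pct bin width in percent of `e_p` (default 1).
#' @param max_pct upper end of the curve, percent (default 200).
#' @return data.frame with `pct` (bin edges, %) and `volume_fraction`.
#' @export
dvh <- function(field, mask, e_p, bin_pct = 1, max_pct = 200) {
  if (!any(mask)) stop("empty structure mask")
  if (e_p <= 0) stop("prescribed field must be > 0")
  v <- field[mask]
  pct <- seq(0, max_pct, by = bin_pct)
  frac <- vapply(pct, function(p) mean(v >= p / 100 * e_p), numeric(1))
  data.frame(pct = pct, volume_fraction = frac)
}

#' All plan-quality indices for one plan
#'
#' @param field combined field-magnitude grid, V/cm.
#' @param mask logical GTV mask.
#' @param e_p prescribed field, V/cm.
#' @return named numeric: E_min, E_mean, E_max, HI, CI.
#' @export
plan_metrics <- function(field, mask, e_p) {
  st <- field_stats(field, mask)
  c(st,
    HI = homogeneity_index(st[["E_max"]], st[["E_min"]], e_p),
    CI = coverage_index(field, mask, e_p))
}
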