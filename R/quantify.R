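## Geometry-to-mass conversion and cohort comparison statistics.

#' Physical constants for mass conversion
#'
#' @param phb_density_g_cm3 PHB density (default 1.170 g/cm^3).
#' @return Named list of constants.
#' @export
mass_constants <- function(phb_density_g_cm3 = 1.170) {
  if (phb_density_g_cm3 <= 0) stop("density must be > 0")
  list(phb_density_g_cm3 = phb_density_g_cm3)
}

#' Convert a volume to mass
#'
#' `mass_fg = volume_nm3 * density * 1e-6`, since 1 g/cm^3 equals
#' 1e-6 fg/nm^3.
#'
#' @param volume_nm3 Volume(s) in nm^3 (>= 0).
#' @param density_g_cm3 Density in g/cm^3.
#' @return Mass(es) in femtograms.
#' @export
#' @examples
#' volume_to_mass(1e6)  # 1.17 fg
volume_to_mass <- function(volume_nm3, density_g_cm3 = 1.170) {
  if (any(volume_nm3 < 0)) stop("volume must be >= 0")
  volume_nm3 * density_g_cm3 * 1e-6
}

#' Volume of a sphere from its diameter
#'
#' @param diameter_nm Diameter(s) in nm (> 0).
#' @return Volume(s) in nm^3 (`pi/6 d^3`).
#' @export
sphere_volume <- function(diameter_nm) {
  if (any(diameter_nm <= 0)) stop("diameter must be > 0")
  pi / 6 * diameter_nm^3
}

#' Volume-to-surface-area ratio
#'
#' @param volume_nm3 Total volume(s), nm^3.
#' @param surface_nm2 Total surface area(s), nm^2 (> 0).
#' @return Ratio(s) in nm^3/nm^2 (equals d/6 for an ideal sphere).
#' @export
v_sa_ratio <- function(volume_nm3, surface_nm2) {
  if (any(surface_nm2 <= 0)) stop("surface area must be > 0")
  volume_nm3 / surface_nm2
}

#' Fold change between condition means
#'
#' @param mean_treated,mean_untreated Positive means.
#' @return `mean_treated / mean_untreated`.
#' @export
#' @examples
#' fold_change(103.3, 7.8)  # ~13-fold PHB mass increase
fold_change <- function(mean_treated, mean_untreated) {
  if (any(mean_treated <= 0) || any(mean_untreated <= 0))
    stop("fold change requires positive means")
  mean_treated / mean_untreated
}

#' Per-cell PHB/PP volume ratio
#'
#' Ratio of total PHB volume to total PP volume for each cell; cells
#' without PP volume are skipped with a warning (such cells exist).
#'
#' @param cells Data frame of cell records (from [aggregate_cell()]).
#' @return Numeric vector of ratios, named by cell_id.
#' @export
phb_pp_volume_ratio <- function(cells) {
  ok <- cells$pp_volume_total_nm3 > 0
  if (any(!ok))
    warning(sum(!ok), " cell(s) without PP volume skipped")
  if (!any(ok)) return(numeric(0))
  stats::setNames(cells$phb_volume_total_nm3[ok] /
                    cells$pp_volume_total_nm3[ok],
                  cells$cell_id[ok])
}

#' Summarize one experimental condition
#'
#' Cohort statistics over cells and granules: mean and SD of per-cell
#' PHB mass (via [volume_to_mass()]), per-cell PP volume, per-cell PHB
#' surface area, granule diameters and counts per class, and the
#' volume/surface-area ratio. Because cohort averaging order is
#' ambiguous for ratios, both bases are reported:
#' `v_sa_ratio_per_cell` (each cell's ratio, then averaged) and
#' `v_sa_ratio_pooled` (total volume over total surface).
#'
#' @param cells Data frame of cell records ([aggregate_cell()] rows).
#' @param granules Data frame from [granule_table()].
#' @param constants [mass_constants()].
#' @param condition Label for the condition.
#' @return A `condition_summary` list.
#' @export
summarize_condition <- function(cells, granules,
                                constants = mass_constants(),
                                condition = "untreated") {
  if (!nrow(cells)) stop("no cells to summarize")
  sd <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  mass <- volume_to_mass(cells$phb_volume_total_nm3,
                         constants$phb_density_g_cm3)
  sa_ok <- cells$phb_surface_total_nm2 > 0
  per_cell_ratio <- v_sa_ratio(cells$phb_volume_total_nm3[sa_ok],
                               cells$phb_surface_total_nm2[sa_ok])
  diam <- function(cl) {
    d <- granules$eq_diameter_nm[granules$class == cl]
    c(mean = if (length(d)) mean(d) else NA_real_,
      sd = if (length(d) > 1) sd(d) else NA_real_,
      n = length(d))
  }
  structure(list(
    condition = condition,
    n_cells = nrow(cells),
    phb_mass_fg_per_cell_mean = mean(mass),
    phb_mass_fg_per_cell_sd = sd(mass),
    pp_volume_nm3_per_cell_mean = mean(cells$pp_volume_total_nm3),
    pp_volume_nm3_per_cell_sd = sd(cells$pp_volume_total_nm3),
    phb_volume_nm3_per_cell_mean = mean(cells$phb_volume_total_nm3),
    phb_surface_nm2_per_cell_mean = mean(cells$phb_surface_total_nm2),
    v_sa_ratio_per_cell = mean(per_cell_ratio),
    v_sa_ratio_pooled = sum(cells$phb_volume_total_nm3) /
      sum(cells$phb_surface_total_nm2),
    phb_diameter_nm = diam("PHB"),
    pp_diameter_nm = diam("PP"),
    n_phb_per_cell_mean = mean(cells$n_phb),
    n_pp_per_cell_mean = mean(cells$n_pp)),
    class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s (%d cells)\n", x$condition, x$n_cells))
  cat(sprintf("  PHB per cell: %.1f +/- %.1f fg, %.2g nm^3, %.2g nm^2, %.1f granules\n",
              x$phb_mass_fg_per_cell_mean, x$phb_mass_fg_per_cell_sd,
              x$phb_volume_nm3_per_cell_mean,
              x$phb_surface_nm2_per_cell_mean, x$n_phb_per_cell_mean))
  cat(sprintf("  PP per cell:  %.2g +/- %.2g nm^3, %.1f granules\n",
              x$pp_volume_nm3_per_cell_mean, x$pp_volume_nm3_per_cell_sd,
              x$n_pp_per_cell_mean))
  cat(sprintf("  diameters: PHB %.0f +/- %.0f nm (n=%d), PP %.0f +/- %.0f nm (n=%d)\n",
              x$phb_diameter_nm[["mean"]], x$phb_diameter_nm[["sd"]],
              x$phb_diameter_nm[["n"]], x$pp_diameter_nm[["mean"]],
              x$pp_diameter_nm[["sd"]], x$pp_diameter_nm[["n"]]))
  cat(sprintf("  V/SA: %.1f nm^3/nm^2 (per-cell), %.1f (pooled)\n",
              x$v_sa_ratio_per_cell, x$v_sa_ratio_pooled))
  invisible(x)
}
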