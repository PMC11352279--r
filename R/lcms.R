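## LC-MS quantification arithmetic: internal-standard normalization,
## calibration curve, percent of dry biomass and femtograms per cell.

#' Simulation spec for an LC-MS quantification run
#'
#' The generator's response model is linear with multiplicative noise:
#' each injection i carries a run-to-run response drift factor
#' `drift_i ~ N(1, is_area_cv)` applied to both the analyte and the
#' internal-standard (IS) peak, so IS normalization cancels it exactly;
#' on top of that the analyte area gets `N(1, noise_cv)` measurement
#' noise. Analyte area at concentration c is
#' `(slope * c + intercept) * drift * noise`; the IS area is
#' `is_area_mean * drift`.
#'
#' @param standard_concs_ug_ml Calibration concentrations (strictly
#'   positive, sorted; default 10-750 ug/mL).
#' @param slope Area per (ug/mL).
#' @param intercept Area at zero concentration.
#' @param noise_cv Analyte measurement noise CV (>= 0).
#' @param is_area_mean,is_area_cv Internal-standard area statistics.
#' @param true_phb_mass_ug True PHB mass per sample (vector allowed).
#' @param extract_volume_ml Extract volume the mass is dissolved in.
#' @param dry_mass_mg Lyophilized dry biomass per sample.
#' @param cfu_per_ml Viable-cell density of the source culture.
#' @param culture_volume_ml Culture volume harvested per sample.
#' @param seed Integer seed.
#' @return An `lcms_sim_spec` list.
#' @export
lcms_sim_spec <- function(standard_concs_ug_ml = c(10, 25, 50, 100,
                                                   250, 500, 750),
                          slope = 1000, intercept = 0,
                          noise_cv = 0.05,
                          is_area_mean = 5e5, is_area_cv = 0.05,
                          true_phb_mass_ug = 607,
                          extract_volume_ml = 4,
                          dry_mass_mg = 10,
                          cfu_per_ml = 5e9,
                          culture_volume_ml = 1,
                          seed) {
  if (missing(seed)) stop("`seed` is required")
  if (is.unsorted(standard_concs_ug_ml) || any(standard_concs_ug_ml <= 0))
    stop("standard concentrations must be positive and sorted")
  if (noise_cv < 0 || is_area_cv < 0) stop("noise CVs must be >= 0")
  structure(as.list(environment()), class = "lcms_sim_spec")
}

#' Generate a synthetic LC-MS run
#'
#' @param spec An [lcms_sim_spec()].
#' @return An `lcms_run` list with `standards` (conc_ug_ml, area,
#'   is_area) and `samples` (sample_id, area, is_area and the
#'   normalization fields).
#' @export
generate_lcms_dataset <- function(spec) {
  stopifnot(inherits(spec, "lcms_sim_spec"))
  set.seed(spec$seed)
  resp <- function(conc) {
    drift <- 1 + rnorm(length(conc), 0, spec$is_area_cv)
    drift <- pmax(drift, 0.1)
    noise <- 1 + rnorm(length(conc), 0, spec$noise_cv)
    list(area = (spec$slope * conc + spec$intercept) * drift * noise,
         is_area = spec$is_area_mean * drift)
  }
  r <- resp(spec$standard_concs_ug_ml)
  standards <- data.frame(conc_ug_ml = spec$standard_concs_ug_ml,
                          area = r$area, is_area = r$is_area)
  conc_s <- spec$true_phb_mass_ug / spec$extract_volume_ml
  rs <- resp(conc_s)
  samples <- data.frame(sample_id = seq_along(conc_s),
                        area = rs$area, is_area = rs$is_area,
                        extract_volume_ml = spec$extract_volume_ml,
                        dry_mass_mg = spec$dry_mass_mg,
                        cfu_per_ml = spec$cfu_per_ml,
                        culture_volume_ml = spec$culture_volume_ml)
  structure(list(standards = standards, samples = samples),
            class = "lcms_run")
}

#' Normalize a peak area to the internal standard
#'
#' `area * is_reference / is_area`, where the reference is by default
#' the mean internal-standard area over the calibration standards.
#'
#' @param area Analyte peak area(s).
#' @param is_area Internal-standard area(s) of the same injection(s)
#'   (> 0).
#' @param is_reference Reference IS area.
#' @return Normalized area(s).
#' @export
normalize_to_is <- function(area, is_area, is_reference) {
  if (any(is_area <= 0)) stop("internal-standard area must be > 0")
  area * is_reference / is_area
}

#' Fit the calibration curve
#'
#' Ordinary least squares of internal-standard-normalized analyte area
#' against concentration, with optional 1/x weighting.
#'
#' @param standards Data frame with `conc_ug_ml`, `area`, `is_area`.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return A `standard_curve` list: `slope`, `intercept`, `r_squared`,
#'   `range_ug_ml`, `is_reference` and the underlying `fit`.
#' @export
fit_standard_curve <- function(standards, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (length(unique(standards$conc_ug_ml)) < 3L)
    stop("calibration needs >= 3 distinct concentrations")
  is_ref <- mean(standards$is_area)
  y <- normalize_to_is(standards$area, standards$is_area, is_ref)
  if (stats::var(y) == 0) stop("zero variance in normalized areas")
  w <- if (weighting == "1/x") 1 / standards$conc_ug_ml else NULL
  fit <- lm(y ~ conc_ug_ml, data = data.frame(conc_ug_ml =
              standards$conc_ug_ml, y = y), weights = w)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 range_ug_ml = range(standards$conc_ug_ml),
                 is_reference = is_ref, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> area = %.4g * conc %+.4g  (R^2 = %.4f, %g-%g ug/mL)\n",
    x$slope, x$intercept, x$r_squared, x$range_ug_ml[1], x$range_ug_ml[2]))
  invisible(x)
}

#' Quantify PHB in samples against a calibration curve
#'
#' Converts normalized sample areas to concentration
#' (`(area_norm - intercept) / slope`), then to PHB mass
#' (`conc * extract volume`), percent of dry biomass
#' (`ug / (mg * 1000) * 100`) and femtograms per cell
#' (`ug * 1e9 / (cfu_per_ml * culture volume)`). Concentrations below
#' zero are clamped to zero with a warning; concentrations outside the
#' calibration range are flagged in `extrapolated`.
#'
#' @param run An `lcms_run` (or any list with a `samples` data frame).
#' @param curve A [fit_standard_curve()] result.
#' @param samples Optional samples data frame overriding `run$samples`.
#' @return Data frame: sample_id, conc_ug_ml, phb_ug, percent_biomass,
#'   fg_per_cell, extrapolated.
#' @export
quantify_sample <- function(run, curve, samples = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  s <- if (!is.null(samples)) samples else run$samples
  y <- normalize_to_is(s$area, s$is_area, curve$is_reference)
  conc <- (y - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sum(conc < 0), " sample concentration(s) below zero clamped")
    conc <- pmax(conc, 0)
  }
  extrap <- conc < curve$range_ug_ml[1] | conc > curve$range_ug_ml[2]
  phb_ug <- conc * s$extract_volume_ml
  data.frame(
    sample_id = s$sample_id,
    conc_ug_ml = conc,
    phb_ug = phb_ug,
    percent_biomass = phb_ug / (s$dry_mass_mg * 1000) * 100,
    fg_per_cell = phb_ug * 1e9 / (s$cfu_per_ml * s$culture_volume_ml),
    extrapolated = extrap)
}
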