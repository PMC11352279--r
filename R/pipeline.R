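## End-to-end orchestration: phantom generation or MRC input ->
## morphometry -> spatial statistics -> condition summary -> report.

#' Read a pipeline configuration file
#'
#' YAML layout: a `conditions` map, each entry holding either
#' `input_volumes` (list of MRC paths) or `phantom` (fields `n_cells`,
#' `voxel_size_nm`, optional `cell_length_range_nm`, `cell_radius_nm`),
#' plus optional top-level `coloc_threshold_nm`, `phb_density_g_cm3`,
#' `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("config must define at least one condition")
  for (nm in names(cfg$conditions)) {
    cc <- cfg$conditions[[nm]]
    has_vol <- !is.null(cc$input_volumes)
    has_ph <- !is.null(cc$phantom)
    if (has_vol == has_ph)
      stop("condition '", nm, "' must set exactly one of ",
           "input_volumes or phantom")
  }
  cfg$coloc_threshold_nm <- cfg$coloc_threshold_nm %||% 25
  cfg$phb_density_g_cm3 <- cfg$phb_density_g_cm3 %||% 1.170
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# attach fractional axial positions (granule centroids projected on the
# cell principal axis) so same-pole pairing can be flagged downstream
attach_axis_frac <- function(objects, vol) {
  if (!length(objects)) return(objects)
  mask <- vol$data != 0L
  idx <- which(mask) - 1L
  dims <- dim(vol$data)
  co <- cbind(idx %% dims[1], (idx %/% dims[1]) %% dims[2],
              idx %/% (dims[1] * dims[2]))
  cm <- colMeans(co)
  ax <- eigen(crossprod(sweep(co, 2, cm)) / nrow(co),
              symmetric = TRUE)$vectors[, 1]
  pr <- sweep(co, 2, cm) %*% ax
  lo <- min(pr); hi <- max(pr)
  lapply(objects, function(o) {
    p <- sum((o$centroid_nm / vol$voxel_size - cm) * ax)
    o$axis_frac <- min(1, max(0, (p - lo) / (hi - lo)))
    o
  })
}

#' Run the granule pipeline for one condition
#'
#' For each cell volume (read from MRC paths or generated as a phantom
#' cohort), extracts PHB and PP objects, measures the cell, computes
#' PP-to-PHB nearest-neighbor surface distances, and writes
#' `granules.csv`, `cells.csv`, `distances.csv` and `summary.json` to
#' `out_dir`. Filter decisions (small components dropped) are logged by
#' the morphometry stage.
#'
#' @param condition Condition name (`"untreated"` / `"cm_treated"` for
#'   phantom cohorts; free-form for volume input).
#' @param input_volumes Character vector of MRC paths (one cell each),
#'   or `NULL` to generate phantoms.
#' @param n_cells,voxel_size_nm,cell_length_range_nm,cell_radius_nm
#'   Phantom cohort parameters (see [phantom_cohort()]).
#' @param seed Integer seed for phantom generation.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param coloc_threshold_nm Co-localization threshold (nm).
#' @param constants [mass_constants()].
#' @param min_voxels Small-object filter for [extract_objects()].
#' @return List: `granules`, `cells`, `distances` (data frames),
#'   `truth` (phantom ground truth or NULL), `summary`
#'   (a `condition_summary`), `coloc` (k, n, fraction).
#' @export
run_condition <- function(condition = "untreated",
                          input_volumes = NULL,
                          n_cells = 5L, voxel_size_nm = 6, seed = 1L,
                          cell_length_range_nm = c(1800, 3600),
                          cell_radius_nm = 450,
                          out_dir = NULL,
                          coloc_threshold_nm = 25,
                          constants = mass_constants(),
                          min_voxels = 8L) {
  specs <- NULL
  if (is.null(input_volumes))
    specs <- phantom_cohort(condition, n_cells, voxel_size_nm, seed,
                            cell_length_range_nm, cell_radius_nm)
  n <- if (is.null(specs)) length(input_volumes) else length(specs)
  if (n == 0L) stop("no input cells for condition '", condition, "'")

  granules <- list(); cells <- list(); dists <- list(); truths <- list()
  for (i in seq_len(n)) {
    if (is.null(specs)) {
      vol <- read_label_volume(input_volumes[i])
      cid <- i
    } else {
      ph <- generate_phantom(specs[[i]])
      vol <- ph$volume
      truths[[i]] <- ph$truth
      cid <- specs[[i]]$cell_id
    }
    objs <- c(extract_objects(vol, "PHB", cell_id = cid,
                              min_voxels = min_voxels),
              extract_objects(vol, "PP", cell_id = cid,
                              min_voxels = min_voxels))
    objs <- attach_axis_frac(objs, vol)
    len <- cell_length(vol)
    granules[[i]] <- granule_table(objs)
    cells[[i]] <- aggregate_cell(objs, cell_length_nm = len,
                                 treated = condition == "cm_treated")
    dists[[i]] <- nearest_neighbor_table(objs, "PP", "PHB")
  }
  granules <- do.call(rbind, granules)
  cells <- do.call(rbind, cells)
  distances <- do.call(rbind, dists)
  truth <- if (length(truths)) do.call(rbind, truths) else NULL

  summ <- summarize_condition(cells, granules, constants, condition)
  coloc <- if (nrow(distances))
    colocalization_fraction(distances, coloc_threshold_nm)
  else list(k = 0L, n = 0L, fraction = NA_real_)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measurements(granules, file.path(out_dir, "granules.csv"))
    write_measurements(cells, file.path(out_dir, "cells.csv"))
    write_measurements(distances, file.path(out_dir, "distances.csv"))
    jsonlite::write_json(
      c(unclass(summ),
        list(coloc_k = coloc$k, coloc_n = coloc$n,
             coloc_fraction = coloc$fraction,
             coloc_threshold_nm = coloc_threshold_nm)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(granules = granules, cells = cells, distances = distances,
       truth = truth, summary = summ, coloc = coloc)
}

#' Compare two condition summaries
#'
#' Fold changes (treated over untreated) for per-cell PHB mass and
#' volume, PP volume, PHB surface area, and mean granule diameters,
#' plus side-by-side co-localization fractions when available.
#'
#' @param summary_untreated,summary_treated `condition_summary` objects
#'   from [summarize_condition()] or [run_condition()] results.
#' @param coloc_untreated,coloc_treated Optional co-localization lists.
#' @return List of fold changes and the two summaries' key numbers.
#' @export
compare_conditions <- function(summary_untreated, summary_treated,
                               coloc_untreated = NULL,
                               coloc_treated = NULL) {
  su <- summary_untreated; st <- summary_treated
  if (!inherits(su, "condition_summary") ||
      !inherits(st, "condition_summary"))
    stop("expected condition_summary objects")
  out <- list(
    phb_mass_fold = fold_change(st$phb_mass_fg_per_cell_mean,
                                su$phb_mass_fg_per_cell_mean),
    phb_volume_fold = fold_change(st$phb_volume_nm3_per_cell_mean,
                                  su$phb_volume_nm3_per_cell_mean),
    pp_volume_fold = fold_change(st$pp_volume_nm3_per_cell_mean,
                                 su$pp_volume_nm3_per_cell_mean),
    phb_surface_fold = fold_change(st$phb_surface_nm2_per_cell_mean,
                                   su$phb_surface_nm2_per_cell_mean),
    phb_diameter_fold = fold_change(st$phb_diameter_nm[["mean"]],
                                    su$phb_diameter_nm[["mean"]]),
    pp_diameter_fold = fold_change(st$pp_diameter_nm[["mean"]],
                                   su$pp_diameter_nm[["mean"]]))
  if (!is.null(coloc_untreated) && !is.null(coloc_treated))
    out$coloc_fractions <- c(untreated = coloc_untreated$fraction,
                             cm_treated = coloc_treated$fraction)
  out
}
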