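## Per-granule morphometry from label volumes: connected-component
## extraction, volume, surface area, equivalent spherical diameter,
## centroid, and per-cell aggregation.

#' Extract granule objects from a label volume
#'
#' Finds connected components (26-connectivity) of one granule class and
#' measures each: voxel count, volume (`voxels * voxel_size^3`), surface
#' area of the relaxed boundary mesh (see [measure_surface_area()]),
#' volume-equivalent spherical diameter, and centroid in nm. Components
#' smaller than `min_voxels` are discarded as segmentation noise (a
#' message records how many).
#'
#' @param vol A [label_volume()].
#' @param granule_class Class name present in the volume's label map.
#' @param cell_id Cell identifier attached to every object.
#' @param min_voxels Discard components below this size (default 8,
#'   below meshing resolution).
#' @param measure_surface Compute surface areas (the expensive step);
#'   set `FALSE` when only volumes are needed.
#' @param keep_mask Keep each object's cropped binary mask (needed for
#'   [surface_distance()]); set `FALSE` for measurement-only runs on
#'   tomogram-scale volumes to halve peak memory.
#' @return A list of `granule_object`s, each holding the measurement
#'   fields plus (with `keep_mask = TRUE`) the cropped binary `mask` and
#'   its 0-based voxel `offset` for downstream surface-distance work.
#'   Convert to a table with [granule_table()].
#' @export
extract_objects <- function(vol, granule_class, cell_id = 1L,
                            min_voxels = 8L, measure_surface = TRUE,
                            keep_mask = TRUE) {
  stopifnot(inherits(vol, "label_volume"))
  if (!granule_class %in% names(vol$label_map))
    stop("class '", granule_class, "' absent from label_map")
  lab_val <- vol$label_map[[granule_class]]
  vox <- vol$voxel_size
  dims <- dim(vol$data)

  lab <- .cc_label_26(vol$data, dims, as.integer(lab_val))
  k <- attr(lab, "n_components")
  if (k == 0L) return(list())

  st <- .component_stats(lab, dims, k)
  keep <- which(st$count >= min_voxels)
  if (length(keep) < k)
    message(k - length(keep), " component(s) below ", min_voxels,
            " voxels discarded as segmentation noise")
  if (!length(keep)) return(list())

  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    ci <- keep[j]
    need_sub <- keep_mask || measure_surface
    sub <- if (need_sub)
      .crop_component(lab, dims, st$bbox[ci, ], ci) else NULL
    nvox <- st$count[ci]
    volume <- nvox * vox^3
    area <- if (measure_surface)
      measure_surface_area(sub, vox) else NA_real_
    out[[j]] <- structure(list(
      cell_id = cell_id,
      granule_id = j,
      granule_class = granule_class,
      voxel_count = as.integer(nvox),
      volume_nm3 = volume,
      surface_area_nm2 = area,
      eq_diameter_nm = equivalent_diameter(volume),
      centroid_nm = st$centroid[ci, ] * vox,
      mask = if (keep_mask) sub else NULL,
      offset = st$bbox[ci, c(1, 3, 5)],
      voxel_size = vox), class = "granule_object")
  }
  out
}

#' @export
print.granule_object <- function(x, ...) {
  cat(sprintf(
    "<granule_object> cell %s %s-%d: %d voxels, V = %.4g nm^3, d_eq = %.1f nm\n",
    x$cell_id, x$granule_class, x$granule_id, x$voxel_count,
    x$volume_nm3, x$eq_diameter_nm))
  invisible(x)
}

#' Tabulate a list of granule objects
#'
#' @param objects List of `granule_object`s from [extract_objects()].
#' @return Data frame with one row per granule (units in column names).
#' @export
granule_table <- function(objects) {
  if (!length(objects))
    return(data.frame(cell_id = integer(), granule_id = integer(),
                      class = character(), voxel_count = integer(),
                      volume_nm3 = numeric(), surface_area_nm2 = numeric(),
                      eq_diameter_nm = numeric(), centroid_x_nm = numeric(),
                      centroid_y_nm = numeric(), centroid_z_nm = numeric()))
  do.call(rbind, lapply(objects, function(o) data.frame(
    cell_id = o$cell_id, granule_id = o$granule_id,
    class = o$granule_class, voxel_count = o$voxel_count,
    volume_nm3 = o$volume_nm3, surface_area_nm2 = o$surface_area_nm2,
    eq_diameter_nm = o$eq_diameter_nm,
    centroid_x_nm = o$centroid_nm[1], centroid_y_nm = o$centroid_nm[2],
    centroid_z_nm = o$centroid_nm[3])))
}

#' Surface area of a binary object
#'
#' Meshes the exposed voxel faces of the object into a watertight
#' triangle mesh and relaxes the staircase with Taubin lambda/mu
#' smoothing before summing triangle areas. On rasterized spheres of
#' diameter >= 20 voxels the estimate is within ~2.5% of the smooth
#' surface area; sharp edges are chamfered (a 10-voxel cube measures
#' ~6% under its exact area).
#'
#' @param mask 3D logical/integer array (nonzero = object).
#' @param voxel_size Voxel edge (nm).
#' @param lambda,mu,iterations Taubin smoothing parameters: shrink step
#'   `lambda`, inflate step `mu` (negative), iteration pairs.
#' @return Surface area in nm^2.
#' @export
measure_surface_area <- function(mask, voxel_size, lambda = 0.5,
                                 mu = -0.53, iterations = 20L) {
  m <- surface_mesh(mask, voxel_size, lambda, mu, iterations)
  m$area
}

#' Relaxed boundary mesh of a binary object
#'
#' @inheritParams measure_surface_area
#' @param offset 0-based voxel offset added to vertex coordinates so
#'   meshes from cropped objects live in the full-volume frame.
#' @return List with `vertices` (n x 3 matrix, nm), `triangles`
#'   (0-based index triples) and `area` (nm^2).
#' @export
surface_mesh <- function(mask, voxel_size, lambda = 0.5, mu = -0.53,
                         iterations = 20L, offset = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  storage.mode(mask) <- "integer"
  if (!any(mask != 0L)) stop("empty object: nothing to mesh")
  m <- .surface_mesh(mask, dim(mask), lambda, mu, as.integer(iterations))
  m$vertices <- sweep(m$vertices, 2, offset, "+") * voxel_size
  m$area <- m$area * voxel_size^2
  m
}

#' Volume-equivalent spherical diameter
#'
#' Diameter of the sphere with the same volume: `(6 V / pi)^(1/3)`.
#'
#' @param volume_nm3 Volume(s) in nm^3 (> 0).
#' @return Diameter(s) in nm.
#' @export
#' @examples
#' equivalent_diameter(pi / 6 * 200^3)  # 200
equivalent_diameter <- function(volume_nm3) {
  if (any(volume_nm3 <= 0)) stop("volume must be > 0")
  (6 * volume_nm3 / pi)^(1 / 3)
}

#' Cell length from a cell mask
#'
#' Projects the voxel centers of the (singly connected) cell mask onto
#' the mask's first principal axis and reports the projected extent plus
#' one voxel, in nm. Orientation-invariant; equals tip-to-tip capsule
#' length on phantoms to within ~2 voxels.
#'
#' @param x A [label_volume()] (every nonzero label is cell material,
#'   since granules sit inside the cell) or a 3D logical array.
#' @param voxel_size Required when `x` is a bare array.
#' @return Length in nm.
#' @export
cell_length <- function(x, voxel_size = NULL) {
  if (inherits(x, "label_volume")) {
    mask <- x$data
    voxel_size <- x$voxel_size
  } else {
    mask <- x
    storage.mode(mask) <- "integer"
    if (is.null(voxel_size)) stop("voxel_size required for array input")
  }
  dims <- dim(mask)
  lab <- .cc_label_26(mask, dims, -1L)  # any nonzero label is cell material
  k <- attr(lab, "n_components")
  if (k == 0L) stop("empty cell mask")
  if (k > 1L)
    stop("cell mask has ", k, " connected components; crop to one cell ",
         "before measuring length")
  idx <- which(mask != 0L) - 1L
  co <- cbind(idx %% dims[1],
              (idx %/% dims[1]) %% dims[2],
              idx %/% (dims[1] * dims[2]))
  cm <- colMeans(co)
  co <- sweep(co, 2, cm)
  ax <- eigen(crossprod(co) / nrow(co), symmetric = TRUE)$vectors[, 1]
  proj <- co %*% ax
  (diff(range(proj)) + 1) * voxel_size
}

#' Aggregate granule objects into a per-cell record
#'
#' @param objects List of `granule_object`s sharing one `cell_id`.
#' @param cell_length_nm Cell length in nm (e.g. from [cell_length()]).
#' @param treated Logical condition flag.
#' @return One-row data frame: counts, class volume/surface totals (sums
#'   over the cell's granules) and metadata.
#' @export
aggregate_cell <- function(objects, cell_length_nm = NA_real_,
                           treated = FALSE) {
  ids <- unique(vapply(objects, function(o) as.character(o$cell_id), ""))
  if (length(ids) > 1L)
    stop("objects span multiple cell_ids: ", paste(ids, collapse = ", "))
  cls <- vapply(objects, function(o) o$granule_class, "")
  vols <- vapply(objects, function(o) o$volume_nm3, 0)
  sas <- vapply(objects, function(o) o$surface_area_nm2, 0)
  phb <- cls == "PHB"; pp <- cls == "PP"
  data.frame(
    cell_id = if (length(ids)) ids else NA,
    cell_length_nm = cell_length_nm,
    n_phb = sum(phb), n_pp = sum(pp),
    phb_volume_total_nm3 = sum(vols[phb]),
    pp_volume_total_nm3 = sum(vols[pp]),
    phb_surface_total_nm2 = sum(sas[phb]),
    pp_surface_total_nm2 = sum(sas[pp]),
    treated = treated)
}
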