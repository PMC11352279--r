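## Synthetic phantom generator: capsule-shaped cells containing
## rasterized spherical granules with known ground truth. The defaults
## encode the study conditions for Rhodobacter sphaeroides storage
## granules: untreated cells carry ~7 PHB granules (diameters
## N(179, 55.6) nm) clustered at one pole within 400 nm of each other
## plus ~1 polyphosphate granule (N(106, 34) nm); chloramphenicol (Cm)
## treated cells carry 1-3 large PHB granules (N(383, 86.5) nm)
## dispersed to the poles plus ~1 PP granule (N(202, 34) nm). PP
## granules sit within a target surface gap of a PHB granule with
## probability 0.55.

#' Specify one granule population of a phantom cell
#'
#' @param granule_class `"PHB"` or `"PP"`.
#' @param count Granules per cell: a single integer (fixed), an integer
#'   vector of length 2 (inclusive uniform range), or
#'   `list(poisson = lambda)`.
#' @param diameter_mean_nm,diameter_sd_nm Normal law for true granule
#'   diameters (nm); sampling is truncated below at two voxel widths.
#' @param placement `"polar_cluster"` (all granules in one polar cap,
#'   pairwise surface gaps capped), `"dispersed_polar"` (granules
#'   alternate between the two poles), or `"near_other_class"`
#'   (placed relative to the other class's surfaces).
#' @param cluster_max_spacing_nm Pairwise surface-gap cap for
#'   `polar_cluster` (nm).
#' @param coloc_prob For `near_other_class`: probability that a granule
#'   is placed with its surface `coloc_gap_nm` from some granule of the
#'   other class.
#' @param coloc_gap_nm Target surface gap when co-localized (nm).
#' @param noncoloc_min_gap_nm Minimum surface gap to every other-class
#'   granule when not co-localized (nm); keeps the two outcomes cleanly
#'   separated around any analysis threshold between the two values.
#' @return A `granule_population` list.
#' @export
#' @examples
#' granule_population("PHB", count = 7, diameter_mean_nm = 179,
#'                    diameter_sd_nm = 55.6, placement = "polar_cluster")
granule_population <- function(granule_class = c("PHB", "PP"),
                               count,
                               diameter_mean_nm,
                               diameter_sd_nm,
                               placement = c("polar_cluster",
                                             "dispersed_polar",
                                             "near_other_class"),
                               cluster_max_spacing_nm = 400,
                               coloc_prob = 0.55,
                               coloc_gap_nm = 10,
                               noncoloc_min_gap_nm = 100) {
  granule_class <- match.arg(granule_class)
  placement <- match.arg(placement)
  if (diameter_mean_nm <= 0) stop("diameter_mean_nm must be > 0")
  if (diameter_sd_nm < 0) stop("diameter_sd_nm must be >= 0")
  if (coloc_prob < 0 || coloc_prob > 1) stop("coloc_prob must be in [0, 1]")
  ok_count <- (is.numeric(count) && length(count) %in% 1:2) ||
    (is.list(count) && identical(names(count), "poisson"))
  if (!ok_count)
    stop("count must be a single integer, a length-2 range, ",
         "or list(poisson = lambda)")
  structure(list(granule_class = granule_class, count = count,
                 diameter_mean_nm = diameter_mean_nm,
                 diameter_sd_nm = diameter_sd_nm,
                 placement = placement,
                 cluster_max_spacing_nm = cluster_max_spacing_nm,
                 coloc_prob = coloc_prob, coloc_gap_nm = coloc_gap_nm,
                 noncoloc_min_gap_nm = noncoloc_min_gap_nm),
            class = "granule_population")
}

#' Specify a phantom cell
#'
#' A sphero-cylindrical (capsule) cell with its long axis along x,
#' containing the granule populations in `populations`.
#'
#' @param cell_length_nm Tip-to-tip capsule length (nm); must be at
#'   least `2 * cell_radius_nm`.
#' @param cell_radius_nm Capsule radius (nm).
#' @param voxel_size_nm Isotropic voxel size (nm); the default 0.9202 nm
#'   matches a 9.202 Angstrom tomogram pixel.
#' @param populations List of [granule_population()] specs.
#' @param seed Integer seed; drives all sampling for this cell.
#' @param cell_id Cell identifier carried into the ground truth.
#' @return A `cell_phantom` list.
#' @export
cell_phantom <- function(cell_length_nm, cell_radius_nm = 450,
                         voxel_size_nm = 0.9202,
                         populations = list(), seed, cell_id = 1L) {
  if (cell_length_nm < 2 * cell_radius_nm)
    stop("cell_length_nm must be >= 2 * cell_radius_nm")
  if (voxel_size_nm <= 0) stop("voxel_size_nm must be > 0")
  if (missing(seed)) stop("`seed` is required")
  if (inherits(populations, "granule_population"))
    populations <- list(populations)
  structure(list(cell_length_nm = cell_length_nm,
                 cell_radius_nm = cell_radius_nm,
                 voxel_size_nm = voxel_size_nm,
                 populations = populations,
                 seed = as.integer(seed), cell_id = cell_id),
            class = "cell_phantom")
}

# truncated-normal sampler (rejection); lower bound strict
rtrunc_normal <- function(n, mean, sd, lower) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
    guard <- guard + 1L
    if (guard > 1000L)
      stop("truncated-normal sampling failed: lower bound ", lower,
           " too far above mean ", mean)
  }
  out[seq_len(n)]
}

sample_count <- function(count) {
  if (is.list(count)) return(rpois(1L, count$poisson))
  if (length(count) == 1L) return(as.integer(round(count)))
  as.integer(sample(seq.int(count[1], count[2]), 1L))
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# uniform point in a ball of radius r around center (3-vector)
runif_ball <- function(center, r) {
  center + random_unit_vector() * r * runif(1)^(1 / 3)
}

# distance from point p to the segment a-b
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  sqrt(sum((p - a - t * ab)^2))
}

#' Generate a phantom label volume with ground truth
#'
#' Rasterizes the cell capsule and its granule spheres into an integer
#' label volume (0 background, 1 cytoplasm, 2 PHB, 3 PP). A voxel
#' belongs to a sphere iff its center lies inside the sphere. Granules
#' of the same class never overlap (a two-voxel surface gap is enforced
#' so rasterized spheres stay 26-disconnected); across classes the gap
#' is >= 0. Placement rules follow each population's spec; placement
#' failure after bounded rejection sampling is an error naming the
#' granule.
#'
#' @param spec A [cell_phantom()].
#' @return A list with `volume` (a [label_volume()]) and `truth`, a data
#'   frame with one row per granule: `cell_id`, `granule_id`, `class`,
#'   `center_x_nm`, `center_y_nm`, `center_z_nm`, `diameter_nm`,
#'   `true_volume_nm3` (`pi/6 d^3`), `true_surface_nm2` (`pi d^2`) and
#'   `raster_voxels` (voxels actually labeled).
#' @export
#' @examples
#' spec <- cell_phantom(1200, 300, voxel_size_nm = 8,
#'                      populations = list(
#'                        granule_population("PHB", 3, 150, 20,
#'                                           "polar_cluster")),
#'                      seed = 1)
#' ph <- generate_phantom(spec)
#' ph$truth
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "cell_phantom"))
  set.seed(spec$seed)
  vox <- spec$voxel_size_nm
  L <- spec$cell_length_nm
  Rc <- spec$cell_radius_nm
  pad <- 2 * vox

  dims <- c(ceiling((L + 2 * pad) / vox) + 1L,
            ceiling((2 * Rc + 2 * pad) / vox) + 1L,
            ceiling((2 * Rc + 2 * pad) / vox) + 1L)
  dims <- as.integer(dims)
  # capsule axis endpoints (nm, voxel-center coordinates)
  a <- c(pad + Rc, pad + Rc, pad + Rc)
  b <- c(pad + L - Rc, pad + Rc, pad + Rc)

  vol <- integer(prod(dims))
  dim(vol) <- dims
  invisible(.fill_capsule(vol, dims, a / vox, b / vox, Rc / vox,
                          GRANULE_LABELS[["cell"]]))

  # ---- sample granules ------------------------------------------------
  pops <- spec$populations
  ord <- order(vapply(pops, function(p) p$placement == "near_other_class",
                      logical(1)))  # dependent placements last
  placed <- list()  # each: class, center (nm), r (nm)
  truth <- list()
  max_attempts <- 5000L

  min_same_gap <- 2 * vox  # keeps same-class rasterizations 26-disconnected

  fits_cell <- function(center, r) {
    point_segment_distance(center, a, b) <= Rc - r - vox
  }
  gap_to <- function(center, r, other) {
    sqrt(sum((center - other$center)^2)) - r - other$r
  }

  for (pop in pops[ord]) {
    n <- sample_count(pop$count)
    if (n == 0L) next
    diam <- rtrunc_normal(n, pop$diameter_mean_nm, pop$diameter_sd_nm,
                          lower = 2 * vox)
    pole <- if (runif(1) < 0.5) a else b  # cluster pole, chosen once
    for (g in seq_len(n)) {
      r <- diam[g] / 2
      if (diam[g] >= 2 * Rc)
        stop(sprintf("granule %s-%d: diameter %.0f nm exceeds cell diameter",
                     pop$granule_class, g, diam[g]))
      same <- Filter(function(o) o$class == pop$granule_class, placed)
      other <- Filter(function(o) o$class != pop$granule_class, placed)
      center <- NULL
      # the co-localization outcome is decided once per granule, before
      # rejection sampling: re-drawing it per attempt would bias the
      # realized fraction toward whichever branch places more easily
      coloc <- pop$placement == "near_other_class" &&
        length(other) > 0 && runif(1) < pop$coloc_prob
      for (att in seq_len(max_attempts)) {
        cand <- switch(pop$placement,
          polar_cluster = runif_ball(pole, Rc - r - vox),
          dispersed_polar = runif_ball(if (g %% 2L == 1L) pole else
                                         (a + b) - pole, Rc - r - vox),
          near_other_class = {
            if (coloc) {
              partner <- other[[sample.int(length(other), 1L)]]
              partner$center + random_unit_vector() *
                (partner$r + r + pop$coloc_gap_nm)
            } else {
              c(runif(1, a[1] - Rc + r, b[1] + Rc - r),
                runif(1, a[2] - Rc + r, a[2] + Rc - r),
                runif(1, a[3] - Rc + r, a[3] + Rc - r))
            }
          })
        if (!fits_cell(cand, r)) next
        if (length(same)) {
          sg <- vapply(same, function(o) gap_to(cand, r, o), 0)
          if (any(sg < min_same_gap)) next
          if (pop$placement == "polar_cluster" &&
              any(sg > pop$cluster_max_spacing_nm)) next
        }
        if (length(other)) {
          gaps <- vapply(other, function(o) gap_to(cand, r, o), 0)
          if (any(gaps < 0)) next
          if (pop$placement == "near_other_class") {
            if (coloc) {
              # must still realize the target gap to its nearest partner
              if (abs(min(gaps) - pop$coloc_gap_nm) > vox) next
            } else if (min(gaps) < pop$noncoloc_min_gap_nm) next
          }
        }
        center <- cand
        break
      }
      if (is.null(center))
        stop(sprintf(
          "placement failed for granule %s-%d (d = %.0f nm) after %d attempts",
          pop$granule_class, g, diam[g], max_attempts))
      placed[[length(placed) + 1L]] <-
        list(class = pop$granule_class, center = center, r = r)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = spec$cell_id,
        granule_id = length(placed),
        class = pop$granule_class,
        center_x_nm = center[1], center_y_nm = center[2],
        center_z_nm = center[3],
        diameter_nm = diam[g],
        true_volume_nm3 = pi / 6 * diam[g]^3,
        true_surface_nm2 = pi * diam[g]^2)
    }
  }

  if (length(placed)) {
    centers <- t(vapply(placed, function(o) o$center, numeric(3))) / vox
    radii <- vapply(placed, function(o) o$r, 0) / vox
    labels <- GRANULE_LABELS[vapply(placed, function(o) o$class, "")]
    counts <- .fill_spheres(vol, dims, centers, radii,
                            as.integer(labels))
    truth <- do.call(rbind, truth)
    truth$raster_voxels <- counts
  } else {
    truth <- data.frame(cell_id = integer(), granule_id = integer(),
                        class = character(), center_x_nm = numeric(),
                        center_y_nm = numeric(), center_z_nm = numeric(),
                        diameter_nm = numeric(), true_volume_nm3 = numeric(),
                        true_surface_nm2 = numeric(),
                        raster_voxels = integer())
  }
  list(volume = new_label_volume(vol, vox), truth = truth)
}

#' Rasterize a single sphere into a label volume
#'
#' Stand-alone sphere phantom used for geometry oracles and per-granule
#' recovery cohorts: one sphere of class `granule_class` centered in a
#' minimal volume with a two-voxel margin.
#'
#' @param diameter_nm True sphere diameter (nm).
#' @param voxel_size_nm Voxel size (nm).
#' @param granule_class `"PHB"` or `"PP"`.
#' @param center_jitter If `TRUE` (default) the center is offset by a
#'   uniform sub-voxel amount so rasterization error is not aligned with
#'   the grid; requires the RNG state.
#' @return A [label_volume()] containing only the sphere.
#' @export
rasterize_sphere <- function(diameter_nm, voxel_size_nm,
                             granule_class = "PHB",
                             center_jitter = TRUE) {
  if (diameter_nm <= 2 * voxel_size_nm)
    stop("diameter must exceed two voxel widths")
  vox <- voxel_size_nm
  r <- diameter_nm / 2 / vox
  n <- as.integer(ceiling(2 * r) + 5L)
  cen <- rep((n - 1) / 2, 3)
  if (center_jitter) cen <- cen + runif(3, -0.5, 0.5)
  vol <- integer(n^3)
  dim(vol) <- c(n, n, n)
  .fill_spheres(vol, dim(vol), matrix(cen, 1), r,
                GRANULE_LABELS[[granule_class]])
  new_label_volume(vol, vox)
}

#' Phantom cohort specs for the two study conditions
#'
#' Returns a list of [cell_phantom()] specs whose population parameters
#' encode the two experimental conditions: `"untreated"` (7 PHB
#' granules/cell, diameters N(179, 55.6) nm, polar cluster spaced within
#' 400 nm; 1 PP granule, N(106, 34) nm) and `"cm_treated"`
#' (chloramphenicol-arrested: 1-3 PHB granules, N(383, 86.5) nm,
#' dispersed to the poles; 1 PP granule, N(202, 34) nm). PP granules are
#' co-localized with PHB surfaces with probability 0.55. Cell lengths
#' are uniform on `cell_length_range_nm`.
#'
#' @param condition `"untreated"` or `"cm_treated"`.
#' @param n_cells Number of cells.
#' @param voxel_size_nm Voxel size (nm). Whole-cell phantoms are
#'   typically generated at 4-8 nm; per-granule cohorts at 0.9202 nm.
#' @param seed Integer seed; per-cell seeds are derived from it.
#' @param cell_length_range_nm Range of tip-to-tip lengths (nm).
#' @param cell_radius_nm Capsule radius (nm).
#' @return List of `cell_phantom` specs.
#' @export
phantom_cohort <- function(condition = c("untreated", "cm_treated"),
                           n_cells, voxel_size_nm = 6, seed,
                           cell_length_range_nm = c(1800, 3600),
                           cell_radius_nm = 450) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("`seed` is required")
  pops <- if (condition == "untreated") {
    list(granule_population("PHB", 7, 179, 55.6, "polar_cluster",
                            cluster_max_spacing_nm = 400),
         granule_population("PP", 1, 106, 34, "near_other_class"))
  } else {
    list(granule_population("PHB", c(1, 3), 383, 86.5, "dispersed_polar"),
         granule_population("PP", 1, 202, 34, "near_other_class"))
  }
  set.seed(seed)
  lens <- runif(n_cells, cell_length_range_nm[1], cell_length_range_nm[2])
  cell_seeds <- sample.int(2^30, n_cells)
  lapply(seq_len(n_cells), function(i)
    cell_phantom(lens[i], cell_radius_nm, voxel_size_nm,
                 populations = pops, seed = cell_seeds[i], cell_id = i))
}
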