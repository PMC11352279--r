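## 2D fluorescence phantom: capsule cells with a membrane outline
## channel, a foci channel (Gaussian spots at stated fractional
## positions along the cell axis) and a per-cell integer label mask.
## Images are matrices indexed [x, y].

#' Generate a synthetic fluorescence image set
#'
#' Cells are drawn as horizontal capsules stacked vertically with a
#' guaranteed gap (cells never overlap). The membrane channel outlines
#' each capsule; the foci channel holds a Gaussian spot of unit
#' amplitude at each requested fractional position along the cell's
#' major axis (0 = left tip, 1 = right tip); the mask image labels each
#' cell's interior with its integer id.
#'
#' @param cells List of [cell_phantom()] specs, or a data frame with
#'   columns `cell_length_nm` and `cell_radius_nm`.
#' @param focus_positions List (one element per cell) of fractional
#'   positions in `[0, 1]`.
#' @param pixel_size_nm Pixel size (default 65 nm, a 100x/sCMOS scale).
#' @param focus_sigma_nm Gaussian spot sigma.
#' @param membrane_thickness_nm Membrane shell thickness.
#' @param background Constant background added to both channels.
#' @param noise_sd Gaussian noise SD added to both channels.
#' @param seed Integer seed (needed only for the noise).
#' @return List with `membrane`, `foci` (numeric matrices), `mask`
#'   (integer matrix of cell labels), `pixel_size_nm`, and `cells`
#'   (per-cell geometry in pixels).
#' @export
generate_fluorescence_image <- function(cells, focus_positions,
                                        pixel_size_nm = 65,
                                        focus_sigma_nm = 150,
                                        membrane_thickness_nm = 150,
                                        background = 0.01,
                                        noise_sd = 0, seed = 1L) {
  if (is.data.frame(cells)) {
    geom <- cells
  } else {
    geom <- data.frame(
      cell_length_nm = vapply(cells, function(c) c$cell_length_nm, 0),
      cell_radius_nm = vapply(cells, function(c) c$cell_radius_nm, 0))
  }
  n <- nrow(geom)
  if (length(focus_positions) != n)
    stop("focus_positions must have one element per cell")
  bad <- vapply(focus_positions,
                function(p) length(p) && (any(p < 0) || any(p > 1)),
                logical(1))
  if (any(bad)) stop("focus positions must lie in [0, 1]")
  set.seed(seed)

  px <- pixel_size_nm
  len_px <- geom$cell_length_nm / px
  rad_px <- geom$cell_radius_nm / px
  gap <- max(rad_px) + 4
  nx <- as.integer(ceiling(max(len_px)) + 2 * gap)
  ny <- as.integer(ceiling(sum(2 * rad_px) + gap * (n + 1)))
  membrane <- matrix(background, nx, ny)
  foci <- matrix(background, nx, ny)
  mask <- matrix(0L, nx, ny)

  xs <- seq_len(nx); ys <- seq_len(ny)
  ycur <- gap
  info <- vector("list", n)
  sig_px <- focus_sigma_nm / px
  thick <- membrane_thickness_nm / px
  for (i in seq_len(n)) {
    R <- rad_px[i]; L <- len_px[i]
    yc <- ycur + R
    x0 <- gap + (max(len_px) - L) / 2          # left tip
    ax_a <- x0 + R; ax_b <- x0 + L - R          # cylinder axis ends
    # distance of each pixel to the axis segment (vectorized over grid)
    tx <- pmin(pmax(xs, ax_a), ax_b)
    dseg <- sqrt(outer((xs - tx)^2, (ys - yc)^2, "+"))
    inside <- dseg <= R
    if (any(mask[inside] != 0L)) stop("cell placement overlap")  # unreachable
    mask[inside] <- i
    shell <- abs(dseg - R) <= thick / 2
    membrane[shell] <- membrane[shell] + 1
    for (p in focus_positions[[i]]) {
      fx <- x0 + p * L; fy <- yc
      d2 <- outer((xs - fx)^2, (ys - fy)^2, "+")
      foci <- foci + exp(-d2 / (2 * sig_px^2))
    }
    info[[i]] <- data.frame(cell_id = i, length_px = L, radius_px = R,
                            tip_left_px = x0, tip_right_px = x0 + L,
                            y_px = yc)
    ycur <- ycur + 2 * R + gap
  }
  if (noise_sd > 0) {
    membrane <- membrane + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
    foci <- foci + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
  }
  list(membrane = membrane, foci = foci, mask = mask,
       pixel_size_nm = pixel_size_nm, cells = do.call(rbind, info))
}

#' Write a fluorescence image set to TIFF files
#'
#' Intensities are rescaled to `[0, 1]` for the fluorescence channels;
#' the mask is written with labels scaled by the maximum label.
#'
#' @param images List from [generate_fluorescence_image()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_fluorescence_tiff <- function(images, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  }
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("membrane", "foci", "mask"), ".tif"))
  tiff::writeTIFF(t(norm(images$membrane)), paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(t(norm(images$foci)), paths[2], bits.per.sample = 16L)
  mx <- max(images$mask, 1L)
  tiff::writeTIFF(t(images$mask / mx), paths[3], bits.per.sample = 16L)
  invisible(paths)
}
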