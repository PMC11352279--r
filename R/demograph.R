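## Foci localization along normalized cell length and demograph
## heatmaps: per-cell axis profiles oriented with the brightest pole up,
## stacked by cell length.

# Major-axis frame of one cell mask: principal axis of the pixel
# coordinates, fractional coordinate in [0, 1], flipped so the brighter
# half of `fluor` maps to 1.
cell_axis_frame <- function(mask, fluor) {
  co <- which(mask, arr.ind = TRUE)
  if (!nrow(co)) stop("empty cell mask")
  cm <- colMeans(co)
  cc <- sweep(co, 2, cm)
  ax <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax  # canonical sign
  proj <- as.vector(cc %*% ax)
  tmin <- min(proj); tmax <- max(proj)
  frac <- if (tmax > tmin) (proj - tmin) / (tmax - tmin) else rep(0.5, length(proj))
  vals <- fluor[co]
  flip <- sum(vals[frac < 0.5]) > sum(vals[frac >= 0.5])
  if (flip) frac <- 1 - frac
  list(coords = co, center = cm, axis = ax, frac = frac, vals = vals,
       flip = flip, extent_px = tmax - tmin + 1)
}

# fractional axial coordinate of arbitrary pixel positions (n x 2) in a
# cell's frame, using the same affine map as the mask pixels
frac_position <- function(frame, xy) {
  proj <- as.vector(sweep(xy, 2, frame$center) %*% frame$axis)
  pr <- as.vector(sweep(frame$coords, 2, frame$center) %*% frame$axis)
  f <- (proj - min(pr)) / (max(pr) - min(pr))
  f <- pmin(1, pmax(0, f))
  if (frame$flip) 1 - f else f
}

#' Axis intensity profile of one cell
#'
#' Bins the fluorescence of every mask pixel by fractional position
#' along the cell's major axis (principal axis of the mask) and reports
#' the mean intensity per bin, oriented so that the brighter cell half
#' is at position 1. Bins without pixels (short cells, many bins) are
#' filled by linear interpolation.
#'
#' @param mask Logical matrix for one (singly connected) cell.
#' @param fluor Numeric matrix, same size.
#' @param cell_id Identifier.
#' @param n_bins Number of axial bins (default 50).
#' @param pixel_size_nm Pixel size in nm.
#' @return A `cell_profile` list: `cell_id`, `cell_length_um`,
#'   `positions` (bin centers in [0, 1]), `intensity`, `flipped`.
#' @export
profile_cell <- function(mask, fluor, cell_id = 1L, n_bins = 50L,
                         pixel_size_nm = 65) {
  if (!any(mask)) stop("empty cell mask")
  fr <- cell_axis_frame(mask, fluor)
  bin <- pmin(n_bins, pmax(1L, ceiling(fr$frac * n_bins)))
  sums <- tapply(fr$vals, factor(bin, levels = seq_len(n_bins)), mean)
  prof <- as.numeric(sums)
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    prof <- stats::approx(ok, prof[ok], xout = seq_len(n_bins),
                          rule = 2)$y
  }
  structure(list(cell_id = cell_id,
                 cell_length_um = fr$extent_px * pixel_size_nm / 1000,
                 positions = (seq_len(n_bins) - 0.5) / n_bins,
                 intensity = prof,
                 flipped = fr$flip),
            class = "cell_profile")
}

#' Detect fluorescent foci inside a cell mask
#'
#' Gaussian-smooths the image, finds local maxima (8-neighborhood)
#' inside the mask that exceed the in-mask background (median) by
#' `prominence` times the in-mask MAD, and enforces a minimum peak
#' separation (brighter peak wins). Peak positions are mapped to
#' fractional coordinates along the cell axis with the same
#' brightest-pole-up orientation as [profile_cell()]. Zero foci is a
#' valid result.
#'
#' @param fluor Numeric matrix.
#' @param mask Logical matrix for one cell.
#' @param cell_id Identifier.
#' @param sigma_px Smoothing sigma in pixels (default 1).
#' @param min_separation_px Minimum distance between reported foci;
#'   closer maxima merge into the brighter one.
#' @param prominence Threshold in MAD units above background.
#' @return Data frame: cell_id, x_px, y_px, frac_position, intensity.
#' @export
detect_foci <- function(fluor, mask, cell_id = 1L, sigma_px = 1,
                        min_separation_px = 3, prominence = 3) {
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  sm0 <- gauss_blur(fluor, sigma_px)
  fr <- cell_axis_frame(mask, sm0)
  nx <- nrow(sm0); ny <- ncol(sm0)
  bg <- stats::median(sm0[mask])
  madv <- stats::mad(sm0[mask])
  thr <- bg + prominence * madv
  # peaks are sought within the mask only, so a spot at the very cell
  # pole is still a local maximum of the restricted image
  sm <- sm0
  sm[!mask] <- -Inf

  # interior local maxima (>= all 8 neighbors, strict above threshold)
  core <- sm[2:(nx - 1), 2:(ny - 1)]
  ismax <- core >= sm[1:(nx - 2), 2:(ny - 1)] &
           core >= sm[3:nx,       2:(ny - 1)] &
           core >= sm[2:(nx - 1), 1:(ny - 2)] &
           core >= sm[2:(nx - 1), 3:ny] &
           core >= sm[1:(nx - 2), 1:(ny - 2)] &
           core >= sm[3:nx,       1:(ny - 2)] &
           core >= sm[1:(nx - 2), 3:ny] &
           core >= sm[3:nx,       3:ny] &
           core > thr
  cand <- which(ismax, arr.ind = TRUE) + 1L   # back to full-image indices
  cand <- cand[mask[cand], , drop = FALSE]
  empty <- data.frame(cell_id = integer(), x_px = integer(),
                      y_px = integer(), frac_position = numeric(),
                      intensity = numeric())
  if (!nrow(cand)) return(empty)
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    dmin <- sqrt(min((kept[, 1] - cand[i, 1])^2 +
                     (kept[, 2] - cand[i, 2])^2))
    if (dmin >= min_separation_px) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  data.frame(cell_id = cell_id, x_px = cand[, 1], y_px = cand[, 2],
             frac_position = frac_position(fr, cand),
             intensity = vals)
}

# separable Gaussian blur with edge replication
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # convolve along rows (first index) with replicated edges
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Segment cells from a membrane image
#'
#' Otsu threshold on the membrane channel, hole filling, and connected
#' component labeling; components touching the border or smaller than
#' `min_px` are dropped. Intended for well-separated phantom or
#' agarose-pad images, not crowded fields.
#'
#' @param membrane Numeric matrix (membrane stain).
#' @param min_px Minimum cell area in pixels.
#' @return Integer label matrix.
#' @export
segment_cells <- function(membrane, min_px = 50L) {
  m <- membrane - min(membrane)
  if (max(m) > 0) m <- m / max(m)
  bw <- m > otsu_threshold(m)
  filled <- fill_holes(bw)
  lab <- label_components_2d(filled)
  keep <- which(tabulate(lab[lab > 0]) >= min_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

otsu_threshold <- function(m, breaks = 256L) {
  h <- hist(m, breaks = seq(0, 1, length.out = breaks + 1L), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- 0; thr <- mids[1]
  for (t in seq_len(breaks - 1L)) {
    w0 <- sum(w[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:t] * mids[1:t]) / w0
    m1 <- sum(w[(t + 1):breaks] * mids[(t + 1):breaks]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- mids[t] }
  }
  thr
}

# background components not reaching the border are holes: fill them
fill_holes <- function(bw) {
  lab <- label_components_2d(!bw)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                          lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  hole <- lab > 0 & !matrix(lab %in% border_labs, nrow(bw))
  bw | hole
}

# 8-connectivity labeling via the 3D engine (thickness-1 volume)
label_components_2d <- function(bw) {
  a <- array(as.integer(bw), dim = c(nrow(bw), ncol(bw), 1L))
  lab <- .cc_label_26(a, dim(a))
  matrix(lab, nrow(bw), ncol(bw))
}

#' Build a demograph from cell profiles
#'
#' Stacks per-cell axis profiles into a matrix with rows sorted by cell
#' length (ascending) and each row normalized to its maximum, the
#' standard demograph heatmap layout.
#'
#' @param profiles List of [profile_cell()] results with equal bin
#'   counts.
#' @return A `demograph`: list with `matrix` (cells x bins, values in
#'   [0, 1]), `cell_lengths_um` (sorted), `positions`.
#' @export
build_demograph <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  nb <- vapply(profiles, function(p) length(p$intensity), 0L)
  if (length(unique(nb)) != 1L)
    stop("profiles have inconsistent bin counts")
  lens <- vapply(profiles, function(p) p$cell_length_um, 0)
  ord <- order(lens)
  mat <- t(vapply(profiles[ord], function(p) {
    v <- p$intensity
    if (max(v) > 0) v / max(v) else v
  }, numeric(nb[1])))
  structure(list(matrix = mat, cell_lengths_um = lens[ord],
                 positions = profiles[[1]]$positions),
            class = "demograph")
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> %d cells x %d bins, lengths %.2f-%.2f um\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$cell_lengths_um), max(x$cell_lengths_um)))
  invisible(x)
}

#' Plot a demograph heatmap
#'
#' @param x A `demograph`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.demograph <- function(x, ...) {
  graphics::image(x = seq_len(nrow(x$matrix)), y = x$positions,
                  z = x$matrix, xlab = "cell (sorted by length)",
                  ylab = "normalized position", ...)
  invisible(x)
}
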