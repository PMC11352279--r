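#' Labeled segmentation volume
#'
#' Container for a 3D integer label volume with physical voxel size.
#' The array is indexed `[x, y, z]` with x fastest, matching MRC storage
#' order; voxel centers sit at 0-based integer coordinates so that the
#' physical position of voxel `(i, j, k)` (0-based) is
#' `c(i, j, k) * voxel_size` nm.
#'
#' @param data 3D integer array (dim `c(nx, ny, nz)`).
#' @param voxel_size Isotropic voxel edge length in nm (> 0).
#' @param label_map Named integer vector mapping class names to the
#'   integer labels present in `data`. Every nonzero label present must
#'   be covered.
#' @return An object of class `label_volume` with elements `data`,
#'   `voxel_size` (nm) and `label_map`.
#' @export
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 2L
#' v <- label_volume(a, voxel_size = 10, label_map = c(PHB = 2))
#' v
label_volume <- function(data, voxel_size,
                         label_map = default_label_map()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (nm)")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("labels must be non-negative integers")
  label_map <- as.integer(label_map) |> stats::setNames(names(label_map))
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("`label_map` must be a named integer vector")
  present <- setdiff(sort(unique(as.vector(data))), 0L)
  missing <- setdiff(present, label_map)
  if (length(missing))
    stop("labels present in data but absent from label_map: ",
         paste(missing, collapse = ", "))
  structure(list(data = data, voxel_size = voxel_size,
                 label_map = label_map),
            class = "label_volume")
}

# trusted constructor for volumes the package built itself (skips the
# full-array label scan, which dominates on tomogram-scale arrays)
new_label_volume <- function(data, voxel_size,
                             label_map = GRANULE_LABELS) {
  structure(list(data = data, voxel_size = voxel_size,
                 label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.4f nm\n",
              d[1], d[2], d[3], x$voxel_size))
  counts <- tabulate(x$data + 1L, nbins = max(x$label_map, x$data) + 1L)
  for (nm in names(x$label_map)) {
    lab <- x$label_map[[nm]]
    if (lab == 0L) next
    cat(sprintf("  %-10s label %d: %d voxels\n", nm, lab, counts[lab + 1L]))
  }
  invisible(x)
}

# ---- MRC input/output -------------------------------------------------
# Minimal MRC2014 reader/writer for integer label volumes: header words
# NX NY NZ MODE ... MX MY MZ CELLA, "MAP " magic and machine stamp.
# Voxel size is CELLA / M* in Angstrom; converted once to nm (x 0.1).

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cella <- readBin(con, "double", n = 3L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 1024L + nsymbt)
  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(data) != n) stop("truncated MRC data block in ", path)
  if (mode == 2) {
    if (any(abs(data - round(data)) > 1e-6))
      stop("MRC volume holds non-integer data; not a label volume")
    data <- as.integer(round(data))
  }
  vx <- if (mx > 0) cella[1] / mx else 0
  vy <- if (my > 0) cella[2] / my else 0
  vz <- if (mz > 0) cella[3] / mz else 0
  list(data = array(as.integer(data), dim = c(nx, ny, nz)),
       voxel_size_angstrom = c(vx, vy, vz))
}

write_mrc <- function(data, voxel_size_nm, path) {
  d <- dim(data)
  rng <- range(data)
  if (rng[1] < -32768 || rng[2] > 32767)
    stop("labels exceed int16 range; cannot write MRC mode 1")
  con <- file(path, "wb")
  on.exit(close(con))
  apix <- voxel_size_nm * 10  # nm -> Angstrom
  writeBin(as.integer(c(d, 1L, 0L, 0L, 0L, d)), con, size = 4L,
           endian = "little")                                  # words 1-10
  writeBin(as.numeric(c(d * apix, 90, 90, 90)), con, size = 4L,
           endian = "little")                                  # CELLA/CELLB
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")   # MAPC/R/S
  writeBin(as.numeric(c(rng[1], rng[2], mean(data))), con, size = 4L,
           endian = "little")                                  # DMIN/MAX/MEAN
  writeBin(c(0L, 0L), con, size = 4L, endian = "little")       # ISPG NSYMBT
  writeBin(raw(100), con)                                      # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little") # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)             # MACHST (LE)
  writeBin(as.numeric(stats::sd(as.numeric(data))), con, size = 4L,
           endian = "little")                                  # RMS
  writeBin(0L, con, size = 4L, endian = "little")              # NLABL
  writeBin(raw(800), con)                                      # labels
  writeBin(as.integer(data), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a label volume from an MRC file
#'
#' Parses the MRC header, converts the header voxel size from Angstrom
#' to nm (division by 10, applied exactly once), and validates that the
#' volume holds integer labels covered by `label_map`. The pipeline
#' assumes isotropic voxels; anisotropic headers are an error.
#'
#' @param path Path to an MRC file (modes 0, 1, 2 or 6; mode-2 float data
#'   must be integer-valued).
#' @param label_map Named integer label map (see [label_volume()]).
#' @param voxel_size_nm Optional override in nm, required when the header
#'   voxel size is zero (a warning records the fallback).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_map = default_label_map(),
                              voxel_size_nm = NULL) {
  raw <- read_mrc(path)
  vs <- raw$voxel_size_angstrom
  if (all(vs == 0)) {
    if (is.null(voxel_size_nm))
      stop("MRC header voxel size is zero and no `voxel_size_nm` override ",
           "was supplied")
    warning("MRC header voxel size is zero; using override ",
            voxel_size_nm, " nm")
    vox_nm <- voxel_size_nm
  } else {
    if (max(vs) - min(vs) > 1e-4 * max(vs))
      stop("anisotropic voxel size in MRC header (",
           paste(signif(vs, 6), collapse = ", "),
           " Angstrom); the pipeline assumes isotropy")
    vox_nm <- vs[1] / 10
  }
  label_volume(raw$data, voxel_size = vox_nm, label_map = label_map)
}

#' Write a label volume to an MRC file
#'
#' Writes MRC mode 1 (int16) with the voxel size recorded in the header
#' in Angstrom (nm times 10).
#'
#' @param vol A [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_mrc(vol$data, vol$voxel_size, path)
  invisible(path)
}

# ---- measurement tables ----------------------------------------------

#' Write a measurement table to CSV
#'
#' Writes data frames of granule, cell or distance records with a stable
#' column order and units embedded in the column names (`volume_nm3`,
#' `surface_area_nm2`, `mass_fg`, ...). An empty data frame yields a
#' header-only file.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
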