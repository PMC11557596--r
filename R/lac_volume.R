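#' LAC volume container
#'
#' Wraps a 3D grid of linear absorption coefficients (LAC, 1/um) with its
#' voxel edge length in nm and an optional integer region mask. Arrays are
#' indexed `[x, y, z]`; physical coordinates of a voxel centre are
#' `(index - 0.5) * voxel_nm` per axis.
#'
#' Mask label conventions used throughout the package:
#' 0 = unassigned, 1 = euchromatin, 2 = heterochromatin, 3 = nucleolus.
#'
#' @param data 3D numeric array of LAC values (finite).
#' @param voxel_nm voxel edge length in nm (default 13).
#' @param mask optional integer array of region labels, same shape.
#' @return an object of class `lac_volume`.
#' @export
lac_volume <- function(data, voxel_nm = 13, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, all(is.finite(data)),
            voxel_nm > 0)
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(data)))
  structure(list(data = data, voxel_nm = voxel_nm, mask = mask),
            class = "lac_volume")
}

#' @export
print.lac_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("lac_volume: %d x %d x %d voxels at %g nm (%s mask)\n",
              d[1], d[2], d[3], x$voxel_nm,
              if (is.null(x$mask)) "no" else "with"))
  invisible(x)
}

#' Restrict a volume mask to a z window
#'
#' Voxels outside `[z_min_nm, z_max_nm]` have their mask label cleared;
#' used to emulate a depth-of-field crop (e.g. an optimal z-range of
#' 1.2 um) before quantification.
#'
#' @param volume a [lac_volume()] with a mask.
#' @param z_min_nm,z_max_nm window bounds in nm.
#' @return the cropped `lac_volume`.
#' @export
crop_z_window <- function(volume, z_min_nm, z_max_nm) {
  stopifnot(inherits(volume, "lac_volume"), !is.null(volume$mask),
            z_max_nm > z_min_nm)
  z <- (seq_len(dim(volume$data)[3]) - 0.5) * volume$voxel_nm
  out <- z < z_min_nm | z > z_max_nm
  volume$mask[, , out] <- 0L
  volume
}

#' Read / write a volume as a multipage TIFF stack
#'
#' One 32-bit float page per z slice. Requires the `tiff` package.
#'
#' @param volume a [lac_volume()].
#' @param path file path.
#' @param voxel_nm voxel size to attach on read.
#' @return [write_volume_tiff()] returns `path` invisibly;
#'   [read_volume_tiff()] returns a `lac_volume`.
#' @export
write_volume_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[3]), function(k) t(volume$data[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, voxel_nm = 13) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  lac_volume(arr, voxel_nm = voxel_nm)
}
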