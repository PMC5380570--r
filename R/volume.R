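#' CT volume container
#'
#' A minimal in-memory representation of a HU-calibrated CT volume: a 3-D
#' numeric array plus voxel spacing in mm.  The third array index is the
#' cranio-caudal (slice) axis with index 1 at the cranial end; the second
#' index runs ventro-dorsal.  HU are stored as double in memory and as
#' signed 16-bit integers on disk.
#'
#' @param values 3-D numeric array of Hounsfield units (air = -1000,
#'   water = 0).
#' @param spacing numeric length-3 vector, voxel edge lengths (dx, dy, dz)
#'   in mm; all must be positive.
#' @return An object of class \code{ct_volume}: a list with elements
#'   \code{values} and \code{spacing}.
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 3)), spacing = c(1, 1, 1))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_lq("unsupported_shape_error",
            sprintf("'values' must be a 3-D array, got %d dimension(s)",
                    length(dim(values))))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_lq("invalid_parameter_error", "spacing must be 3 positive finite values (mm)")
  structure(list(values = values, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Lung mask container
#'
#' @param mask logical (or 0/1) 3-D array aligned voxel-for-voxel with its
#'   CT volume.
#' @param spacing voxel spacing in mm, as for [ct_volume()].
#' @return An object of class \code{lung_mask}.
#' @export
lung_mask <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_lq("unsupported_shape_error", "'mask' must be a 3-D array")
  m <- array(as.logical(mask), dim = dim(mask))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_lq("invalid_parameter_error", "spacing must be 3 positive values (mm)")
  structure(list(mask = m, spacing = spacing), class = "lung_mask")
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop_lq("alignment_error", "volume and mask have different dimensions")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop_lq("alignment_error", "volume and mask have different voxel spacing")
  invisible(TRUE)
}

#' Read a CT volume or lung mask from NIfTI
#'
#' Reads a 3-D NIfTI-1 image and returns it under the package's axis
#' convention (third index cranio-caudal).  Voxel spacing is taken from the
#' header \code{pixdim}.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_lq("io_error", sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_lq("unsupported_shape_error",
            sprintf("expected a 3-D volume, got %d dimensions", length(d)))
  ct_volume(array(as.numeric(img), dim = d), spacing = RNifti::pixdim(img))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lung_mask(v$values != 0, spacing = v$spacing)
}

#' Write a CT volume or lung mask to NIfTI
#'
#' Volumes are stored as signed 16-bit integers (HU rounded to the nearest
#' integer, which is lossless for integer-valued HU); masks as 8-bit 0/1.
#'
#' @param volume a [ct_volume()] or [lung_mask()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "lung_mask")) {
    img <- RNifti::asNifti(array(as.integer(volume$mask), dim = dim(volume$mask)))
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (inherits(volume, "ct_volume")) {
    img <- RNifti::asNifti(round(volume$values))
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    stop_lq("invalid_parameter_error", "expected a ct_volume or lung_mask")
  }
  invisible(path)
}

#' Write result rows to CSV
#'
#' Serializes lung quantification or agreement results to an RFC-4180 CSV
#' with a stable, documented column set.  Missing values (e.g. an undefined
#' bias with fewer than two pairs) are written as empty cells.
#'
#' @param rows a data frame, or a list of \code{lung_quant} /
#'   \code{agreement_result} objects (coerced with [as.data.frame()]).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_results_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0L) {
      df <- data.frame()
    } else {
      df <- do.call(rbind, lapply(rows, as.data.frame))
    }
  } else {
    stop_lq("invalid_parameter_error", "'rows' must be a data frame or list")
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_lq("io_error", sprintf("cannot write: %s", path))
  invisible(path)
}
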