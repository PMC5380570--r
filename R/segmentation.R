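#' Automatic lung segmentation
#'
#' Fully automatic threshold-based lung segmentation: voxels below an air
#' threshold are candidate lung, the outside-air component connected to
#' the volume border is removed, the largest remaining connected
#' components (up to two, one per lung) above a minimum volume are kept,
#' and the result is closed with a 3-D ball to recover part of the denser
#' (poorly and non-aerated) tissue that falls above the threshold.
#'
#' Dense consolidation at the pleural boundary cannot be distinguished
#' from the chest wall by thresholding, so in severely injured lungs this
#' procedure under-segments the dependent regions; its accuracy is
#' quantified against phantom ground truth rather than assumed.  For real
#' data a curated mask supplied via [read_mask()] is the recommended path.
#'
#' @param volume a [ct_volume()].
#' @param air_threshold HU below which a voxel is candidate lung
#'   (default -200 HU).
#' @param min_component_volume minimum connected-component volume (ml)
#'   retained (default 50 ml).
#' @param closing_radius radius (voxels) of the ball used for
#'   morphological closing (default 3).
#' @return A [lung_mask()].
#' @export
segment_lungs <- function(volume, air_threshold = -200,
                          min_component_volume = 50,
                          closing_radius = 3L) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$values)
  vox_ml <- prod(volume$spacing) / 1000
  air <- volume$values < air_threshold
  if (!any(air))
    stop_lq("segmentation_failed_error",
            sprintf("no voxels below %g HU: nothing to segment", air_threshold))

  labels <- .label_components_3d(as.vector(air), as.integer(d))
  lab_arr <- array(labels, dim = d)

  # outside air: any air component touching the volume border
  border_labels <- unique(c(lab_arr[c(1, d[1]), , ], lab_arr[, c(1, d[2]), ],
                            lab_arr[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  inside <- labels > 0 & !(labels %in% border_labels)
  if (!any(inside))
    stop_lq("segmentation_failed_error",
            "all sub-threshold voxels are border-connected outside air")

  sizes <- tabulate(labels[inside])
  keep <- which(sizes * vox_ml >= min_component_volume)
  if (length(keep) == 0L)
    stop_lq("segmentation_failed_error",
            sprintf("no inside-air component reaches %g ml", min_component_volume))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(2L, length(keep)))]
  cand <- array(labels %in% keep, dim = d)

  if (closing_radius > 0) {
    v <- .morph_ball_3d(as.vector(cand), as.integer(d),
                        as.integer(closing_radius), 0L)
    v <- .morph_ball_3d(v, as.integer(d), as.integer(closing_radius), 1L)
    closed <- array(v, dim = d)
  } else closed <- cand
  # closing must never leak into border-connected outside air
  outside <- array(labels %in% border_labels, dim = d)
  closed <- closed & !outside
  if (!any(closed))
    stop_lq("segmentation_failed_error", "segmentation produced an empty mask")
  lung_mask(closed, spacing = volume$spacing)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [lung_mask()] objects (or logical arrays) of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "lung_mask")) a$mask else a
  mb <- if (inherits(b, "lung_mask")) b$mask else b
  stopifnot(identical(dim(ma), dim(mb)))
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
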