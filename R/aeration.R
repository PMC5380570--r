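#' Aeration compartment thresholds
#'
#' The four HU compartments used throughout quantitative lung CT:
#' hyper-aerated (-1000 to -901 HU), normally aerated (-900 to -501 HU),
#' poorly aerated (-500 to -101 HU) and non-aerated (-100 to +100 HU).
#' The intervals are disjoint and exactly tile [-1000, +100]; on integer HU
#' each printed bound belongs to the interval that lists it, and for
#' continuous data the tiling splits halfway between printed bounds
#' (-900.5, -500.5, -100.5).
#'
#' @param breaks interior split points between the four compartments, in
#'   increasing order.  The defaults reproduce the printed integer bounds.
#' @return An object of class \code{aeration_thresholds}.
#' @examples
#' thr <- aeration_thresholds()
#' classify_voxel(c(-950, -900, -500, 0), thr)
#' @export
aeration_thresholds <- function(breaks = c(-900.5, -500.5, -100.5)) {
  breaks <- as.numeric(breaks)
  if (length(breaks) != 3L || is.unsorted(breaks, strictly = TRUE) ||
      breaks[1] <= -1000 || breaks[3] >= 100)
    stop_lq("invalid_parameter_error",
            "breaks must be 3 strictly increasing values inside (-1000, 100)")
  structure(list(breaks = breaks,
                 labels = c("hyper", "normal", "poor", "non")),
            class = "aeration_thresholds")
}

#' Voxel density from HU
#'
#' The linear HU-density model: lung tissue density in g/ml is
#' (HU + 1000) / 1000, i.e. 0 g/ml at -1000 HU (pure gas) and 1 g/ml at
#' 0 HU (water).  Input is clamped to [-1000, +100] first, the range tiled
#' by the aeration compartments; values outside it are counted at the
#' clamp, not dropped, so that lung weight is never silently biased.
#'
#' @param hu numeric vector of Hounsfield units.
#' @return numeric vector of densities (g/ml).
#' @examples
#' voxel_density(c(-1000, -500, 0))
#' @export
voxel_density <- function(hu) {
  (clamp_hu(hu) + 1000) / 1000
}

#' Classify voxels into aeration compartments
#'
#' @param hu numeric vector of Hounsfield units; clamped to [-1000, +100]
#'   before classification, which makes the function total.
#' @param thr an [aeration_thresholds()] object.
#' @return factor with levels \code{hyper}, \code{normal}, \code{poor},
#'   \code{non}.
#' @export
classify_voxel <- function(hu, thr = aeration_thresholds()) {
  stopifnot(inherits(thr, "aeration_thresholds"))
  idx <- findInterval(clamp_hu(hu), thr$breaks) + 1L
  factor(thr$labels[idx], levels = thr$labels)
}

#' Per-slice lung quantification
#'
#' Applies the voxel density model and the compartment classification to
#' every masked voxel and summarizes per axial slice: lung volume V_i
#' (masked voxel count times voxel volume), lung mass M_i (sum of density
#' times voxel volume) and the mass and volume of each aeration
#' compartment.  These per-slice masses are the M_i terms of the
#' sparse-slice extrapolation formula (see [extrapolate()]).
#'
#' @param volume a [ct_volume()].
#' @param mask a [lung_mask()] aligned with \code{volume}.
#' @param thr an [aeration_thresholds()] object.
#' @return A data frame of class \code{slice_quant} with one row per slice:
#'   \code{slice} (0-based index, cranial end first), \code{position_mm}
#'   (cranial edge of the slice), \code{thickness_mm}, \code{volume_ml},
#'   \code{mass_g}, and \code{mass_<compartment>_g} /
#'   \code{volume_<compartment>_ml} for the four compartments.
#' @export
quantify_slices <- function(volume, mask, thr = aeration_thresholds()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  check_aligned(volume, mask)
  d <- dim(volume$values)
  nz <- d[3]
  vox_ml <- prod(volume$spacing) / 1000  # mm^3 -> ml
  dz <- volume$spacing[3]

  idx <- which(mask$mask)
  labs <- thr$labels
  out <- data.frame(slice = 0:(nz - 1L),
                    position_mm = (0:(nz - 1L)) * dz,
                    thickness_mm = dz,
                    volume_ml = 0, mass_g = 0)
  for (lab in labs) {
    out[[paste0("mass_", lab, "_g")]] <- 0
    out[[paste0("volume_", lab, "_ml")]] <- 0
  }
  if (length(idx) > 0L) {
    z <- (idx - 1L) %/% (d[1] * d[2]) + 1L  # 1-based slice of each voxel
    hu <- clamp_hu(volume$values[idx])
    dens <- (hu + 1000) / 1000
    comp <- findInterval(hu, thr$breaks) + 1L
    zf <- factor(z, levels = seq_len(nz))
    out$volume_ml <- as.numeric(tabulate(z, nbins = nz)) * vox_ml
    mass_z <- vapply(split(dens, zf), sum, numeric(1)) * vox_ml
    out$mass_g <- as.numeric(mass_z)
    for (k in seq_along(labs)) {
      sel <- comp == k
      m <- vapply(split(dens[sel], factor(z[sel], levels = seq_len(nz))),
                  sum, numeric(1)) * vox_ml
      v <- tabulate(z[sel], nbins = nz) * vox_ml
      out[[paste0("mass_", labs[k], "_g")]] <- as.numeric(m)
      out[[paste0("volume_", labs[k], "_ml")]] <- as.numeric(v)
    }
  }
  class(out) <- c("slice_quant", "data.frame")
  attr(out, "compartments") <- labs
  out
}

#' Aggregate per-slice quantities into whole-lung results
#'
#' Total lung weight TLW is the sum of per-slice masses, total lung volume
#' TLV the sum of per-slice (anatomical, mask) volumes, and each
#' compartment fraction is its mass as a percentage of TLW.
#'
#' @param slices a \code{slice_quant} data frame from [quantify_slices()].
#' @return An object of class \code{lung_quant}: a list with \code{tlv_ml},
#'   \code{tlw_g} and \code{fractions_pct} (named, sums to 100).
#' @export
aggregate_slices <- function(slices) {
  stopifnot(inherits(slices, "slice_quant") || is.data.frame(slices))
  if (nrow(slices) < 1L)
    stop_lq("insufficient_data_error", "need at least one slice")
  labs <- attr(slices, "compartments")
  if (is.null(labs)) labs <- c("hyper", "normal", "poor", "non")
  tlw <- sum(slices$mass_g)
  tlv <- sum(slices$volume_ml)
  if (tlw <= 0)
    stop_lq("degenerate_input_error",
            "total lung weight is zero; compartment fractions are undefined")
  comp_mass <- vapply(labs, function(l) sum(slices[[paste0("mass_", l, "_g")]]),
                      numeric(1))
  lung_quant(tlv_ml = tlv, tlw_g = tlw,
             fractions_pct = 100 * comp_mass / tlw,
             compartment_mass_g = comp_mass)
}

#' Whole-lung quantification result
#'
#' @param tlv_ml total lung volume (ml; anatomical mask volume).
#' @param tlw_g total lung weight (g).
#' @param fractions_pct named numeric vector, compartment mass as percent
#'   of TLW; must sum to 100.
#' @param compartment_mass_g optional named numeric vector of absolute
#'   compartment masses (g).
#' @return An object of class \code{lung_quant}.
#' @export
lung_quant <- function(tlv_ml, tlw_g, fractions_pct, compartment_mass_g = NULL) {
  if (tlv_ml < 0 || tlw_g < 0)
    stop_lq("invalid_parameter_error", "TLV and TLW must be non-negative")
  structure(list(tlv_ml = tlv_ml, tlw_g = tlw_g,
                 fractions_pct = fractions_pct,
                 compartment_mass_g = compartment_mass_g),
            class = "lung_quant")
}

#' @export
print.lung_quant <- function(x, ...) {
  cat(sprintf("lung_quant: TLV %.1f ml, TLW %.1f g\n", x$tlv_ml, x$tlw_g))
  cat("  fractions (% of TLW):",
      paste(sprintf("%s %.2f", names(x$fractions_pct), x$fractions_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lung_quant <- function(x, ...) {
  df <- data.frame(tlv_ml = x$tlv_ml, tlw_g = x$tlw_g)
  for (l in names(x$fractions_pct))
    df[[paste0("frac_", l, "_pct")]] <- unname(x$fractions_pct[[l]])
  df
}

#' Whole-volume quantification
#'
#' Convenience wrapper: per-slice quantification followed by aggregation.
#'
#' @inheritParams quantify_slices
#' @return A \code{lung_quant}.
#' @export
quantify_lung <- function(volume, mask, thr = aeration_thresholds()) {
  aggregate_slices(quantify_slices(volume, mask, thr))
}
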