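#' Scan protocol description
#'
#' Describes a CT acquisition protocol for dose comparison.  Dose scales
#' linearly with the current-time product (mAs); \code{ctdi_ref} is the
#' volume CT dose index measured (or quoted) at \code{mAs_ref}.
#'
#' @param mode \code{"spiral"} or \code{"sequential"}.
#' @param mAs current-time product of the protocol (mAs), > 0.
#' @param t slice thickness (mm).
#' @param ctdi_ref reference CTDI_vol (mGy) at \code{mAs_ref}.
#' @param mAs_ref current-time product at which \code{ctdi_ref} applies.
#' @param feed feed (mm) for sequential mode; informational.
#' @param pitch pitch for spiral mode; informational.
#' @param kVp tube voltage; informational.
#' @return An object of class \code{scan_protocol}.
#' @export
scan_protocol <- function(mode = c("spiral", "sequential"), mAs, t,
                          ctdi_ref, mAs_ref = mAs, feed = NULL,
                          pitch = NULL, kVp = 120) {
  mode <- match.arg(mode)
  if (mAs <= 0 || mAs_ref <= 0)
    stop_lq("invalid_parameter_error", "mAs must be positive")
  if (ctdi_ref <= 0)
    stop_lq("invalid_parameter_error", "ctdi_ref must be positive")
  structure(list(mode = mode, mAs = mAs, t = t, ctdi_ref = ctdi_ref,
                 mAs_ref = mAs_ref, feed = feed, pitch = pitch, kVp = kVp),
            class = "scan_protocol")
}

#' CTDI at a given current-time product
#'
#' Linear scaling of the volume CT dose index with tube output:
#' CTDI(mAs) = CTDI_ref x mAs / mAs_ref.
#'
#' @param protocol a [scan_protocol()].
#' @param mAs query current-time product (mAs), > 0.
#' @return CTDI_vol in mGy.
#' @examples
#' p <- scan_protocol("spiral", mAs = 180, t = 1, ctdi_ref = 4.4, mAs_ref = 180)
#' ctdi_at(p, 50)  # 4.4 * 50/180
#' @export
ctdi_at <- function(protocol, mAs) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (!is.numeric(mAs) || mAs <= 0)
    stop_lq("invalid_parameter_error", "mAs must be positive")
  protocol$ctdi_ref * mAs / protocol$mAs_ref
}

#' Dose report for a protocol
#'
#' Idealized dosimetry: the irradiated length is the scan length for a
#' spiral acquisition or N x t for a sequential plan (nothing is
#' irradiated between slices); DLP = CTDI_vol x irradiated length (cm);
#' effective dose E = k x DLP.  Over-ranging and tube-current modulation
#' are not modeled, so the estimator is a protocol comparator rather than
#' a scanner-exact dose calculation.
#'
#' @param protocol a [scan_protocol()].
#' @param plan_or_length a [plan_sequential()] plan (sequential mode) or a
#'   scan length in mm (spiral mode).
#' @param k DLP-to-effective-dose conversion coefficient
#'   (mSv per mGy cm), > 0.  Species- and protocol-specific; no default.
#' @return An object of class \code{dose_report}: list with
#'   \code{ctdi_mGy}, \code{irradiated_length_cm}, \code{dlp_mGy_cm},
#'   \code{e_mSv} and \code{k}.
#' @export
dose_report <- function(protocol, plan_or_length, k) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (!is.numeric(k) || k <= 0)
    stop_lq("invalid_parameter_error", "conversion coefficient k must be positive")
  if (protocol$mode == "sequential") {
    if (!inherits(plan_or_length, "sequential_plan"))
      stop_lq("invalid_parameter_error",
              "sequential mode requires a sequential_plan")
    length_mm <- plan_or_length$n * plan_or_length$t
  } else {
    if (!is.numeric(plan_or_length) || plan_or_length <= 0)
      stop_lq("invalid_parameter_error",
              "spiral mode requires a positive scan length (mm)")
    length_mm <- plan_or_length
  }
  ctdi <- ctdi_at(protocol, protocol$mAs)
  dlp <- ctdi * length_mm / 10
  structure(list(ctdi_mGy = ctdi, irradiated_length_cm = length_mm / 10,
                 dlp_mGy_cm = dlp, e_mSv = k * dlp, k = k),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("dose_report: CTDI %.3g mGy, length %.3g cm, DLP %.3g mGy cm, E %.3g mSv\n",
              x$ctdi_mGy, x$irradiated_length_cm, x$dlp_mGy_cm, x$e_mSv))
  invisible(x)
}

#' @export
as.data.frame.dose_report <- function(x, ...) {
  data.frame(ctdi_mGy = x$ctdi_mGy, irradiated_length_cm = x$irradiated_length_cm,
             dlp_mGy_cm = x$dlp_mGy_cm, e_mSv = x$e_mSv, k = x$k)
}

#' Effective-dose reduction of a test protocol vs a reference
#'
#' @param reference,test [dose_report()] objects; the reference must have
#'   strictly positive effective dose.
#' @return Fractional reduction 1 - E_test / E_reference, in [0, 1] when
#'   the test dose does not exceed the reference.
#' @export
dose_reduction <- function(reference, test) {
  stopifnot(inherits(reference, "dose_report"), inherits(test, "dose_report"))
  if (reference$e_mSv <= 0)
    stop_lq("undefined_reduction_error", "reference effective dose is zero")
  1 - test$e_mSv / reference$e_mSv
}
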