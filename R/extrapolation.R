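#' Plan a sequential (axial) acquisition
#'
#' A sequential scan acquires N thin axial slices of thickness t separated
#' by a feed f along the cranio-caudal axis, irradiating nothing between
#' slices.  Slice i (i = 0..N-1) occupies [start + i f, start + i f + t)
#' mm from the cranial end, and N is the largest count for which every
#' slice fits inside the coverage [0, L).
#'
#' @param L cranio-caudal coverage (mm).
#' @param t slice thickness (mm), t > 0.
#' @param f feed, i.e. distance between consecutive slice positions (mm),
#'   f >= t.
#' @param start offset of the first slice from the cranial end (mm).
#' @return An object of class \code{sequential_plan}: list with \code{t},
#'   \code{f}, \code{L}, \code{start}, \code{n} and \code{positions_mm}.
#' @examples
#' plan_sequential(L = 240, t = 1, f = 20)$n  # 12 slices
#' @export
plan_sequential <- function(L, t, f, start = 0) {
  if (t <= 0 || f < t)
    stop_lq("invalid_parameter_error", "need t > 0 and f >= t")
  if (start < 0 || L - start < t)
    stop_lq("no_slice_error",
            "coverage too short: no slice of thickness t fits after 'start'")
  n <- floor((L - start - t) / f) + 1
  positions <- start + (seq_len(n) - 1) * f
  structure(list(t = t, f = f, L = L, start = start,
                 n = as.integer(n), positions_mm = positions),
            class = "sequential_plan")
}

#' @export
print.sequential_plan <- function(x, ...) {
  cat(sprintf("sequential_plan: %d slices of %g mm, feed %g mm, coverage %g mm\n",
              x$n, x$t, x$f, x$L))
  invisible(x)
}

#' Extract a sparse slice subset from a contiguous stack
#'
#' Retrospectively emulates a sequential acquisition from a reconstructed
#' contiguous stack: keeps every (f/t)-th slice starting at the cranial
#' end.  The feed must be an integer multiple of the slice thickness; no
#' interpolation is performed.
#'
#' @param slices a \code{slice_quant} data frame (contiguous stack,
#'   constant thickness t).
#' @param f feed in mm.
#' @param start_index 0-based index of the first retained slice.
#' @return A \code{subset_series}: a \code{slice_quant} data frame of the
#'   retained slices with attributes \code{feed_mm} and \code{t_mm}.
#' @examples
#' \dontrun{extract_subset(slices, f = 20)}
#' @export
extract_subset <- function(slices, f, start_index = 0L) {
  stopifnot(is.data.frame(slices), nrow(slices) >= 1L)
  t <- slices$thickness_mm[1]
  step <- f / t
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop_lq("incompatible_feed_error",
            sprintf("feed %g mm is not a positive integer multiple of slice thickness %g mm",
                    f, t))
  step <- as.integer(round(step))
  keep <- seq(from = start_index + 1L, to = nrow(slices), by = step)
  out <- slices[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("subset_series", "slice_quant", "data.frame")
  attr(out, "compartments") <- attr(slices, "compartments")
  attr(out, "feed_mm") <- f
  attr(out, "t_mm") <- t
  out
}

#' Extrapolate whole-lung quantities from a sparse slice series
#'
#' For a quantity Q measured on N equally spaced slices of thickness t at
#' feed f, the whole-lung value is estimated by the trapezoidal formula
#' \deqn{Q_{lung} = \sum_{i=1}^{N-1} f\,\frac{Q_i + Q_{i+1}}{2t}
#'       + \frac{Q_1 + Q_N}{2}.}
#' The same formula is applied to lung mass, lung volume and every
#' compartment mass; compartment fractions are then recomputed from the
#' extrapolated compartment masses over the extrapolated total mass.  At
#' f = t the formula telescopes to the plain sum over the full stack, so
#' extrapolation of a contiguous stack is exact.
#'
#' @param series a \code{subset_series} from [extract_subset()], or any
#'   \code{slice_quant} data frame with a known feed (supply \code{f}).
#' @param f feed in mm; defaults to the series' \code{feed_mm} attribute.
#' @return A \code{lung_quant} with extrapolated TLV, TLW and fractions.
#' @export
extrapolate <- function(series, f = attr(series, "feed_mm")) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n < 2L)
    stop_lq("insufficient_slices_error",
            "extrapolation needs at least two slices")
  if (is.null(f))
    stop_lq("invalid_parameter_error", "feed 'f' is required")
  t <- series$thickness_mm[1]
  labs <- attr(series, "compartments")
  if (is.null(labs)) labs <- c("hyper", "normal", "poor", "non")

  trap <- function(q) sum(f * (q[-n] + q[-1]) / (2 * t)) + (q[1] + q[n]) / 2
  tlw <- trap(series$mass_g)
  tlv <- trap(series$volume_ml)
  mass <- vapply(labs, function(l) trap(series[[paste0("mass_", l, "_g")]]),
                 numeric(1))
  if (tlw <= 0)
    stop_lq("degenerate_input_error",
            "extrapolated lung weight is zero; fractions undefined")
  lung_quant(tlv_ml = tlv, tlw_g = tlw, fractions_pct = 100 * mass / tlw,
             compartment_mass_g = mass)
}

#' Feed sweep: extrapolation accuracy across interleaves
#'
#' Quantifies a full contiguous stack once as the reference, then for each
#' requested feed extracts the corresponding slice subset and extrapolates
#' whole-lung quantities, mimicking retrospective validation of sequential
#' protocols against a spiral scan.
#'
#' @param volume a [ct_volume()] (contiguous stack).
#' @param mask aligned [lung_mask()].
#' @param thr an [aeration_thresholds()].
#' @param feeds numeric vector of feeds (mm), each an integer multiple of
#'   the slice thickness.
#' @return A list with \code{reference} (\code{lung_quant}),
#'   \code{extrapolated} (named list of \code{lung_quant}, one per feed)
#'   and \code{table}: a long data frame with one row per (feed, metric)
#'   holding reference value, extrapolated value and their difference.
#' @export
feed_sweep <- function(volume, mask, thr = aeration_thresholds(), feeds) {
  if (length(feeds) < 1L)
    stop_lq("invalid_parameter_error", "at least one feed is required")
  slices <- quantify_slices(volume, mask, thr)
  sweep_from_slices(slices, feeds)
}

# Core of feed_sweep, reusable when per-slice quantities are already known.
sweep_from_slices <- function(slices, feeds) {
  reference <- aggregate_slices(slices)
  ex <- lapply(feeds, function(f) extrapolate(extract_subset(slices, f)))
  names(ex) <- as.character(feeds)
  tab <- do.call(rbind, lapply(seq_along(feeds), function(i) {
    q <- ex[[i]]
    metrics <- c(tlv_ml = q$tlv_ml, tlw_g = q$tlw_g,
                 stats::setNames(q$fractions_pct,
                                 paste0("frac_", names(q$fractions_pct), "_pct")))
    refs <- c(tlv_ml = reference$tlv_ml, tlw_g = reference$tlw_g,
              stats::setNames(reference$fractions_pct,
                              paste0("frac_", names(reference$fractions_pct), "_pct")))
    data.frame(feed_mm = feeds[i], metric = names(metrics),
               reference = unname(refs), extrapolated = unname(metrics),
               difference = unname(metrics - refs), row.names = NULL)
  }))
  list(reference = reference, extrapolated = ex, table = tab)
}
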