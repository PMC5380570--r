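#' Cohort experiment configuration
#'
#' Parameters of a seeded synthetic-cohort validation run: a cohort of
#' injured-lung phantoms is generated, each is quantified on the full
#' contiguous stack (the spiral reference) and re-quantified by
#' extrapolation from sparse slice subsets at each requested feed, and
#' agreement statistics are computed across the cohort.
#'
#' Per-subject variability is drawn from the subject's seed: consolidation
#' severity uniform over \code{severity_range}, lung semi-axes jittered by
#' the \code{lung_scale_*} ranges (cranio-caudal extent about 220-250 mm
#' at the default grid).
#'
#' @param n_subjects cohort size.
#' @param seed base seed; subject i uses \code{seed + i}.
#' @param feeds feeds (mm) for the retrospective sweep.
#' @param reference_feed the feed (mm) reported in the headline agreement
#'   table.
#' @param mAs simulated current-time product for the analyzed volumes.
#' @param severity_range range of per-subject consolidation severity.
#' @param lung_scale_xy,lung_scale_z multiplicative jitter ranges applied
#'   to the default lung semi-axes.
#' @param grid list with nx, ny, nz, dx, dy, dz of the phantom grid.
#' @param dose list with dosimetry parameters: \code{ctdi_ref} (mGy),
#'   \code{mAs_ref}, \code{spiral_mAs}, \code{sequential_mAs} and \code{k}
#'   (DLP-to-effective-dose coefficient, mSv per mGy cm).
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 12L, seed = 1L,
                          feeds = 2:50, reference_feed = 20,
                          mAs = 180,
                          severity_range = c(0.9, 1.0),
                          lung_scale_xy = c(0.92, 1.08),
                          lung_scale_z = c(0.9, 1.02),
                          grid = list(nx = 160L, ny = 160L, nz = 250L,
                                      dx = 1, dy = 1, dz = 1),
                          dose = list(ctdi_ref = 4.4, mAs_ref = 180,
                                      spiral_mAs = 180, sequential_mAs = 50,
                                      k = 0.02)) {
  if (length(feeds) < 1L)
    stop_lq("config_error", "config field 'feeds' must not be empty")
  if (n_subjects < 1L)
    stop_lq("config_error", "config field 'n_subjects' must be at least 1")
  if (!(reference_feed %in% feeds))
    feeds <- sort(unique(c(feeds, reference_feed)))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 feeds = feeds, reference_feed = reference_feed, mAs = mAs,
                 severity_range = severity_range,
                 lung_scale_xy = lung_scale_xy, lung_scale_z = lung_scale_z,
                 grid = grid, dose = dose),
            class = "cohort_config")
}

# Phantom spec for subject i of a cohort, with seeded per-subject jitter.
subject_spec <- function(config, i) {
  g <- config$grid
  subj_seed <- config$seed + i
  pars <- with_local_seed(subj_seed, {
    list(severity = runif(1, config$severity_range[1], config$severity_range[2]),
         sxy = runif(2, config$lung_scale_xy[1], config$lung_scale_xy[2]),
         sz = runif(1, config$lung_scale_z[1], config$lung_scale_z[2]))
  })
  fov <- c(g$nx * g$dx, g$ny * g$dy, g$nz * g$dz)
  base_semi <- fov * c(0.175, 0.28125, 0.488)
  phantom_spec(nx = g$nx, ny = g$ny, nz = g$nz, dx = g$dx, dy = g$dy,
               dz = g$dz, severity = pars$severity,
               lung_semiaxes = base_semi * c(pars$sxy, pars$sz),
               seed = subj_seed)
}

#' Run a seeded cohort validation experiment
#'
#' Generates the phantom cohort, analyzes each subject's full stack
#' (reference) and every sparse-subset extrapolation, and summarizes
#' agreement per metric and feed across the cohort.  All randomness is
#' derived from the config seed, so reruns with the same config reproduce
#' the output tables exactly.
#'
#' @param config a [cohort_config()] (or a YAML file path holding one).
#' @param outdir optional directory; when given, the result tables, the
#'   run manifest and the config are written there as CSV/YAML.
#' @param verbose print per-stage progress.
#' @return A list with data frames \code{subjects} (per-subject reference
#'   and reference-feed extrapolated quantities), \code{agreement}
#'   (per-metric Bland-Altman at the reference feed), \code{sweep}
#'   (per-feed, per-metric agreement across the cohort),
#'   \code{dose} (spiral vs sequential dose estimates per subject), the
#'   scalar \code{n_comparisons} (subjects x feeds), and \code{manifest}.
#' @export
run_cohort_experiment <- function(config = cohort_config(), outdir = NULL,
                                  verbose = FALSE) {
  if (is.character(config)) config <- config_from_yaml(config)
  if (!inherits(config, "cohort_config"))
    stop_lq("config_error", "'config' must be a cohort_config or YAML path")
  thr <- aeration_thresholds()
  feeds <- config$feeds

  metrics <- c("tlv_ml", "tlw_g", "frac_hyper_pct", "frac_normal_pct",
               "frac_poor_pct", "frac_non_pct")
  per_subject <- vector("list", config$n_subjects)
  sweep_rows <- vector("list", config$n_subjects)
  dose_rows <- vector("list", config$n_subjects)

  for (i in seq_len(config$n_subjects)) {
    if (verbose) message(sprintf("subject %d/%d", i, config$n_subjects))
    spec <- subject_spec(config, i)
    ph <- generate_phantom(spec, mAs = config$mAs)
    slices <- quantify_slices(ph$volume, ph$mask, thr)
    sw <- sweep_from_slices(slices, feeds)

    refq <- as.data.frame(sw$reference)
    exq <- as.data.frame(sw$extrapolated[[as.character(config$reference_feed)]])
    names(refq) <- paste0("ref_", names(refq))
    names(exq) <- paste0("ext_", names(exq))
    per_subject[[i]] <- cbind(data.frame(subject = i, seed = spec$seed,
                                         severity = spec$severity),
                              refq, exq)
    sweep_rows[[i]] <- cbind(subject = i, sw$table)
    dose_rows[[i]] <- subject_dose_row(config, i, slices)
  }
  subjects <- do.call(rbind, per_subject)
  sweep_raw <- do.call(rbind, sweep_rows)

  sweep <- cohort_agreement(subjects, sweep_raw, feeds, metrics)
  agreement <- sweep[sweep$feed_mm == config$reference_feed, , drop = FALSE]
  rownames(agreement) <- NULL

  out <- list(subjects = subjects, agreement = agreement, sweep = sweep,
              sweep_raw = sweep_raw,
              dose = do.call(rbind, dose_rows),
              n_comparisons = config$n_subjects * length(feeds),
              manifest = list(package_version = as.character(
                                utils::packageVersion("lungquant")),
                              seed = config$seed,
                              subject_seeds = config$seed + seq_len(config$n_subjects),
                              n_subjects = config$n_subjects,
                              feeds = feeds,
                              reference_feed = config$reference_feed,
                              mAs = config$mAs))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(out$subjects, file.path(outdir, "subjects.csv"))
    write_results_table(out$agreement, file.path(outdir, "agreement.csv"))
    write_results_table(out$sweep, file.path(outdir, "sweep.csv"))
    write_results_table(out$dose, file.path(outdir, "dose.csv"))
    yaml::write_yaml(out$manifest, file.path(outdir, "manifest.yaml"))
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  }
  out
}

# Bland-Altman across subjects for every (feed, metric); fractions are
# compared in percentage points, TLV/TLW both absolutely and relatively.
cohort_agreement <- function(subjects, sweep_raw, feeds, metrics) {
  rows <- list()
  for (f in feeds) {
    for (m in metrics) {
      sel <- sweep_raw$feed_mm == f & sweep_raw$metric == m
      ref <- sweep_raw$reference[sel]
      ext <- sweep_raw$extrapolated[sel]
      ba <- bland_altman(ext, ref, metric = m)
      rows[[length(rows) + 1L]] <- cbind(feed_mm = f, as.data.frame(ba))
      if (m %in% c("tlv_ml", "tlw_g")) {
        bar <- bland_altman(100 * (ext - ref) / ref, rep(0, length(ref)),
                            metric = sub("_(ml|g)$", "_rel_pct", m))
        bar$rho <- ba$rho
        rows[[length(rows) + 1L]] <- cbind(feed_mm = f, as.data.frame(bar))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Spiral vs sequential dose estimate for one subject, using the lung's
# cranio-caudal extent as the scan coverage.
subject_dose_row <- function(config, i, slices) {
  d <- config$dose
  lung_slices <- which(slices$mass_g > 0)
  L <- length(lung_slices) * slices$thickness_mm[1]
  plan <- plan_sequential(L = L, t = slices$thickness_mm[1],
                          f = config$reference_feed)
  spiral <- scan_protocol("spiral", mAs = d$spiral_mAs, t = slices$thickness_mm[1],
                          ctdi_ref = d$ctdi_ref, mAs_ref = d$mAs_ref)
  seq_lo <- scan_protocol("sequential", mAs = d$sequential_mAs,
                          t = slices$thickness_mm[1],
                          ctdi_ref = d$ctdi_ref, mAs_ref = d$mAs_ref,
                          feed = config$reference_feed)
  rs <- dose_report(spiral, L, k = d$k)
  rq <- dose_report(seq_lo, plan, k = d$k)
  data.frame(subject = i, coverage_mm = L, n_slices_sequential = plan$n,
             e_spiral_mSv = rs$e_mSv, e_sequential_mSv = rq$e_mSv,
             dose_reduction = dose_reduction(rs, rq))
}

# Read a cohort_config from YAML.
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_lq("config_error", sprintf("no such config: %s", path))
  x <- yaml::read_yaml(path)
  known <- intersect(names(x), names(formals(cohort_config)))
  unknown <- setdiff(names(x), names(formals(cohort_config)))
  if (length(unknown) > 0)
    stop_lq("config_error",
            sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(cohort_config, x[known])
}
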