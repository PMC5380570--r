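#' Synthetic thorax phantom specification
#'
#' Describes a digital thorax phantom: a soft-tissue body ellipsoid
#' containing two ellipsoidal lung fields whose gas fraction decreases
#' monotonically with ventro-dorsal depth, emulating the dependent loss of
#' aeration seen in injured (ARDS-like) lungs in the supine position.
#'
#' The gas fraction at normalized depth d (0 = most ventral lung extent,
#' 1 = most dorsal) follows a logistic decay
#' \deqn{g(d) = g_{max} - (g_{max} - g_{min})\,\mathrm{logistic}((d - c)/w)}
#' where severity moves both the floor \eqn{g_{min}} and the transition
#' center c: severity 0 gives a healthy lung (gas fraction at least 0.9
#' everywhere), severity 1 a consolidated dependent quartile (gas fraction
#' at most 0.1 for d >= 0.75).  Noise-free lung HU are
#' \eqn{-1000\,g + \mathrm{hu}_{tissue}(1 - g)} and always lie in
#' [-1000, +100].
#'
#' Default geometry scales with the field of view; at the default
#' 160 x 160 x 250 grid with 1 mm isotropic voxels the lungs span about
#' 244 mm cranio-caudally and about 1.3 l total volume.
#'
#' @param nx,ny,nz grid size (voxels); third axis is cranio-caudal.
#' @param dx,dy,dz voxel spacing (mm); must be positive.
#' @param severity dependent-consolidation severity in [0, 1].
#' @param body_semiaxes,body_center body ellipsoid semi-axes and center
#'   (mm); defaults scale with the field of view.
#' @param lung_semiaxes semi-axes (mm) shared by both lung ellipsoids.
#' @param lung_centers 2 x 3 matrix of lung center coordinates (mm).
#' @param g_max maximal (ventral) gas fraction.
#' @param hu_tissue HU of fully degassed lung tissue.
#' @param hu_soft,hu_air background HU for soft tissue and outside air.
#' @param sigma_ref image noise SD (HU) at the reference current-time
#'   product \code{mAs_ref}.
#' @param gradient_width logistic transition width (normalized depth).
#' @param seed integer random seed; the same spec and seed always produce
#'   a bit-identical phantom.
#' @return An object of class \code{phantom_spec}.
#' @examples
#' spec <- phantom_spec(nx = 40, ny = 40, nz = 30, dx = 4, dy = 4, dz = 8)
#' ph <- generate_phantom(spec, mAs = 180)
#' ph$truth
#' @export
phantom_spec <- function(nx = 160L, ny = 160L, nz = 250L,
                         dx = 1, dy = 1, dz = 1,
                         severity = 0.95,
                         body_semiaxes = NULL, body_center = NULL,
                         lung_semiaxes = NULL, lung_centers = NULL,
                         g_max = 0.95, hu_tissue = 40,
                         hu_soft = 40, hu_air = -1000,
                         sigma_ref = 20, gradient_width = 0.10,
                         seed = 1L) {
  if (any(c(dx, dy, dz) <= 0))
    stop_lq("invalid_parameter_error", "voxel spacing must be positive")
  if (any(c(nx, ny, nz) < 4))
    stop_lq("invalid_parameter_error", "grid must be at least 4 voxels per axis")
  if (severity < 0 || severity > 1)
    stop_lq("invalid_parameter_error", "severity must lie in [0, 1]")
  fov <- c(nx * dx, ny * dy, nz * dz)
  # the torso extends beyond the scanned cranio-caudal range, as in a real
  # chest acquisition: its z semi-axis exceeds the field of view so the
  # body cross-section never collapses inside the grid
  if (is.null(body_semiaxes)) body_semiaxes <- fov * c(0.4375, 0.40625, 1.2)
  if (is.null(body_center)) body_center <- fov / 2
  if (is.null(lung_semiaxes)) lung_semiaxes <- fov * c(0.175, 0.28125, 0.488)
  if (is.null(lung_centers))
    lung_centers <- rbind(c(0.5 - 0.2125, 0.4875, 0.5) * fov,
                          c(0.5 + 0.2125, 0.4875, 0.5) * fov)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dx = dx, dy = dy, dz = dz,
                 severity = severity,
                 body_semiaxes = body_semiaxes, body_center = body_center,
                 lung_semiaxes = lung_semiaxes, lung_centers = lung_centers,
                 g_max = g_max, hu_tissue = hu_tissue,
                 hu_soft = hu_soft, hu_air = hu_air,
                 sigma_ref = sigma_ref, mAs_ref = 180,
                 gradient_width = gradient_width,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gas fraction as a function of normalized ventro-dorsal depth d in [0, 1].
# severity moves the consolidation floor and the transition center; the
# curve is monotone non-increasing in d for every severity.
phantom_gas_fraction <- function(d, spec) {
  g_min <- spec$g_max - (spec$g_max - 0.03) * spec$severity
  center <- 1.0 - 0.55 * spec$severity
  spec$g_max - (spec$g_max - g_min) * plogis((d - center) / spec$gradient_width)
}

# Ellipsoid membership on the voxel-center grid; returns a logical array.
ellipsoid_mask <- function(spec, center, semiaxes) {
  xs <- ((seq_len(spec$nx) - 0.5) * spec$dx - center[1]) / semiaxes[1]
  ys <- ((seq_len(spec$ny) - 0.5) * spec$dy - center[2]) / semiaxes[2]
  zs <- ((seq_len(spec$nz) - 0.5) * spec$dz - center[3]) / semiaxes[3]
  xy <- outer(xs^2, ys^2, "+")
  array(outer(xy, zs^2, "+") < 1, dim = c(spec$nx, spec$ny, spec$nz))
}

# Noise-free construction shared by generate_phantom() and
# ground_truth_quant(): HU field, lung mask and the per-column gas model.
phantom_fields <- function(spec) {
  body <- ellipsoid_mask(spec, spec$body_center, spec$body_semiaxes)
  lungs <- ellipsoid_mask(spec, spec$lung_centers[1, ], spec$lung_semiaxes) |
    ellipsoid_mask(spec, spec$lung_centers[2, ], spec$lung_semiaxes)
  lungs <- lungs & body

  # depth normalized over the lungs' ventro-dorsal bounding extent
  ylo <- min(spec$lung_centers[, 2]) - spec$lung_semiaxes[2]
  yhi <- max(spec$lung_centers[, 2]) + spec$lung_semiaxes[2]
  y_mm <- (seq_len(spec$ny) - 0.5) * spec$dy
  d <- pmin(pmax((y_mm - ylo) / (yhi - ylo), 0), 1)
  g_y <- phantom_gas_fraction(d, spec)
  hu_lung_y <- -1000 * g_y + spec$hu_tissue * (1 - g_y)

  hu <- array(spec$hu_air, dim = c(spec$nx, spec$ny, spec$nz))
  hu[body] <- spec$hu_soft
  hu_y_arr <- array(rep(rep(hu_lung_y, each = spec$nx), spec$nz),
                    dim = c(spec$nx, spec$ny, spec$nz))
  hu[lungs] <- hu_y_arr[lungs]
  list(hu = hu, lungs = lungs, body = body)
}

#' Generate a noisy phantom CT volume with ground truth
#'
#' Builds the noise-free phantom HU field, adds zero-mean Gaussian image
#' noise whose standard deviation scales with the current-time product as
#' \eqn{\sigma = \sigma_{ref}\sqrt{\mathrm{mAs}_{ref}/\mathrm{mAs}}}, and
#' returns the noisy volume together with the exact lung mask used in
#' construction and the analytic whole-lung quantification of the
#' noise-free field.
#'
#' @param spec a [phantom_spec()].
#' @param mAs current-time product of the simulated acquisition (mAs).
#' @param reference_mAs current-time product at which \code{sigma_ref}
#'   applies; defaults to the spec's reference (180 mAs).
#' @return A list with elements \code{volume} ([ct_volume()]), \code{mask}
#'   ([lung_mask()]) and \code{truth} (\code{lung_quant} computed
#'   analytically, see [ground_truth_quant()]).
#' @export
generate_phantom <- function(spec, mAs = 180, reference_mAs = spec$mAs_ref) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(mAs) || mAs <= 0 || reference_mAs <= 0)
    stop_lq("invalid_parameter_error", "mAs values must be positive")
  f <- phantom_fields(spec)
  sigma <- spec$sigma_ref * sqrt(reference_mAs / mAs)
  noisy <- f$hu + with_local_seed(spec$seed, {
    array(rnorm(length(f$hu), sd = sigma), dim = dim(f$hu))
  })
  list(volume = ct_volume(noisy, spacing = c(spec$dx, spec$dy, spec$dz)),
       mask = lung_mask(f$lungs, spacing = c(spec$dx, spec$dy, spec$dz)),
       truth = ground_truth_quant(spec, fields = f))
}

#' Analytic ground-truth lung quantification of a phantom
#'
#' Computes TLV, TLW and the compartment fractions directly from the
#' noise-free phantom density field, voxel-wise and independently of the
#' main analysis code path, so that it can serve as an oracle for the
#' pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param fields internal; precomputed phantom fields.
#' @return A \code{lung_quant}.
#' @export
ground_truth_quant <- function(spec, fields = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(fields)) fields <- phantom_fields(spec)
  hu <- fields$hu[fields$lungs]
  hu <- pmin(pmax(hu, -1000), 100)
  vox_ml <- spec$dx * spec$dy * spec$dz / 1000
  dens <- (hu + 1000) / 1000
  tlw <- sum(dens) * vox_ml
  tlv <- length(hu) * vox_ml
  if (tlw <= 0)
    stop_lq("degenerate_input_error", "phantom lung has zero weight")
  comp <- cut(hu, breaks = c(-Inf, -900.5, -500.5, -100.5, Inf),
              labels = c("hyper", "normal", "poor", "non"))
  mass <- vapply(levels(comp), function(l) sum(dens[comp == l]) * vox_ml,
                 numeric(1))
  lung_quant(tlv_ml = tlv, tlw_g = tlw, fractions_pct = 100 * mass / tlw,
             compartment_mass_g = mass)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Serialize / deserialize a phantom spec as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return \code{write_phantom_spec} returns \code{path} invisibly;
#'   \code{read_phantom_spec} returns a \code{phantom_spec}.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$lung_centers <- lapply(seq_len(nrow(spec$lung_centers)),
                           function(i) as.numeric(spec$lung_centers[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$lung_centers <- do.call(rbind, x$lung_centers)
  args <- x[intersect(names(x), names(formals(phantom_spec)))]
  spec <- do.call(phantom_spec, args)
  spec$mAs_ref <- x$mAs_ref
  spec
}
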