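# Shared fixtures: everything is generated in code at test time.

# Desk-scale phantom: same field of view as the default (160 x 160 x 240 mm)
# on a coarser grid, cheap enough for per-test generation.
small_spec <- function(severity = 0.95, seed = 1L, sigma_ref = 20, ...) {
  phantom_spec(nx = 64L, ny = 64L, nz = 80L, dx = 2.5, dy = 2.5, dz = 3,
               severity = severity, seed = seed, sigma_ref = sigma_ref, ...)
}

# A uniform-HU volume fully covered by a mask, for closed-form checks.
uniform_volume <- function(hu, dims = c(10, 10, 4), spacing = c(1, 1, 1)) {
  list(volume = ct_volume(array(hu, dims), spacing = spacing),
       mask = lung_mask(array(TRUE, dims), spacing = spacing))
}

# Hand-built per-slice table with the given masses (all in one compartment),
# mimicking quantify_slices() output for formula-level tests.
make_slices <- function(masses, t = 1, volumes = masses, compartment = "poor") {
  labs <- c("hyper", "normal", "poor", "non")
  n <- length(masses)
  df <- data.frame(slice = 0:(n - 1L), position_mm = (0:(n - 1L)) * t,
                   thickness_mm = t, volume_ml = volumes, mass_g = masses)
  for (l in labs) {
    df[[paste0("mass_", l, "_g")]] <- if (l == compartment) masses else 0
    df[[paste0("volume_", l, "_ml")]] <- if (l == compartment) volumes else 0
  }
  class(df) <- c("slice_quant", "data.frame")
  attr(df, "compartments") <- labs
  df
}

# Independent two-pass Bland-Altman oracle using explicit loops.
ba_oracle <- function(test, reference) {
  n <- length(test)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- test[i] - reference[i]
  m <- 0
  for (i in seq_len(n)) m <- m + d[i]
  m <- m / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  s <- sqrt(ss / (n - 1))
  list(bias = m, sd = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

# Independent Spearman oracle: average ranks by explicit counting, then the
# Pearson formula written out with raw sums.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# Brute-force sequential-slice placement: count slices [pos, pos+t) that fit
# wholly inside [0, L) when stepping by f from 'start'.
count_slices_brute <- function(L, t, f, start = 0) {
  n <- 0L
  pos <- start
  while (pos + t <= L) {
    n <- n + 1L
    pos <- pos + f
  }
  n
}
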