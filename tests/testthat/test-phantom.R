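test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- small_spec(seed = 42L)
  a <- generate_phantom(spec, mAs = 180)
  b <- generate_phantom(spec, mAs = 180)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$mask, b$mask$mask)
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(999)
  r1 <- runif(1)
  set.seed(999)
  invisible(generate_phantom(small_spec(seed = 5L), mAs = 180))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noise SD follows the 1/sqrt(mAs) scaling law", {
  spec <- small_spec(seed = 11L)             # > 1e5 voxels
  nf <- generate_phantom(small_spec(seed = 11L, sigma_ref = 0), mAs = 180)
  hi <- generate_phantom(spec, mAs = 180)
  lo <- generate_phantom(spec, mAs = 50)
  sd_hi <- sd(hi$volume$values - nf$volume$values)
  sd_lo <- sd(lo$volume$values - nf$volume$values)
  expect_gt(length(hi$volume$values), 1e5)
  expect_equal(sd_hi, 20, tolerance = 0.02)
  expect_equal(sd_lo / sd_hi, sqrt(180 / 50), tolerance = 0.02)
})

test_that("severity endpoints satisfy the gas-fraction invariants", {
  # noise-free lung HU = -1000 g + 40 (1 - g): g >= 0.9 <=> HU <= -896
  healthy <- generate_phantom(small_spec(severity = 0, sigma_ref = 0), mAs = 180)
  hu_lung <- healthy$volume$values[healthy$mask$mask]
  expect_true(all(hu_lung <= -896))
  expect_true(all(hu_lung >= -1000 & hu_lung <= 100))
  expect_lt(healthy$truth$fractions_pct[["non"]], 1)

  # severity 1: most dependent lung quartile has g <= 0.1 <=> HU >= -64
  severe <- generate_phantom(small_spec(severity = 1, sigma_ref = 0), mAs = 180)
  ydim <- dim(severe$mask$mask)[2]
  yidx <- slice.index(severe$mask$mask, 2)
  lung_y <- range(yidx[severe$mask$mask])
  dep <- severe$mask$mask & (yidx >= lung_y[1] + 0.75 * diff(lung_y))
  expect_gt(sum(dep), 0)
  expect_true(all(severe$volume$values[dep] >= -64))
})

test_that("ground-truth fractions sum to 100 and TLW follows the density model", {
  tr <- ground_truth_quant(small_spec(seed = 2L))
  expect_equal(sum(tr$fractions_pct), 100, tolerance = 1e-9)
  expect_true(all(tr$fractions_pct >= 0))

  # degenerate spec with all lung tissue at exactly -500 HU:
  # g = 540/1040 so that -1000 g + 40 (1 - g) = -500, hence 0.5 g/ml
  flat <- small_spec(severity = 0, g_max = 540 / 1040, sigma_ref = 0)
  tr_flat <- ground_truth_quant(flat)
  expect_equal(tr_flat$tlw_g, 0.5 * tr_flat$tlv_ml, tolerance = 1e-12)
  expect_equal(tr_flat$fractions_pct[["poor"]], 100, tolerance = 1e-9)
})

test_that("pipeline on the noise-free phantom reproduces the analytic truth", {
  ph <- generate_phantom(small_spec(seed = 3L, sigma_ref = 0), mAs = 180)
  q <- quantify_lung(ph$volume, ph$mask)
  expect_equal(q$tlw_g, ph$truth$tlw_g, tolerance = 1e-9)
  expect_equal(q$tlv_ml, ph$truth$tlv_ml, tolerance = 1e-9)
  expect_equal(q$fractions_pct, ph$truth$fractions_pct, tolerance = 1e-9)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_spec(dx = 0), class = "invalid_parameter_error")
  expect_error(phantom_spec(severity = 1.5), class = "invalid_parameter_error")
  expect_error(generate_phantom(small_spec(), mAs = 0),
               class = "invalid_parameter_error")
  expect_error(generate_phantom(small_spec(), mAs = -10),
               class = "invalid_parameter_error")
})

test_that("phantom spec round-trips through YAML", {
  spec <- small_spec(severity = 0.93, seed = 17L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$severity, spec$severity)
  expect_equal(back$lung_semiaxes, spec$lung_semiaxes)
  expect_identical(back$seed, spec$seed)
  a <- generate_phantom(spec, mAs = 180)
  b <- generate_phantom(back, mAs = 180)
  expect_identical(a$volume$values, b$volume$values)
})
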