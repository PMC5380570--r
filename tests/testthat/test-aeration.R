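test_that("voxel density is linear in HU and clamped to [-1000, 100]", {
  expect_equal(voxel_density(-1000), 0)
  expect_equal(voxel_density(0), 1)
  expect_equal(voxel_density(-500), 0.5)
  expect_equal(voxel_density(-1200), 0)      # clamped below
  expect_equal(voxel_density(250), 1.1)      # clamped to +100
})

test_that("compartment boundaries follow the printed integer thresholds", {
  thr <- aeration_thresholds()
  hu <- c(-1000, -950, -901, -900, -501, -500, -101, -100, 0, 100, 250)
  expected <- c("hyper", "hyper", "hyper", "normal", "normal", "poor",
                "poor", "non", "non", "non", "non")
  expect_equal(as.character(classify_voxel(hu, thr)), expected)
  # continuous values split halfway between printed bounds
  expect_equal(as.character(classify_voxel(c(-900.6, -900.4), thr)),
               c("hyper", "normal"))
})

test_that("a uniform -500 HU slice quantifies to the closed form", {
  u <- uniform_volume(-500, dims = c(10, 10, 4))  # 100 voxels of 1 mm^3 per slice
  sl <- quantify_slices(u$volume, u$mask)
  expect_equal(nrow(sl), 4)
  expect_equal(sl$volume_ml, rep(0.1, 4))
  expect_equal(sl$mass_g, rep(0.05, 4))
  expect_equal(sl$mass_poor_g, sl$mass_g)
  expect_equal(sl$mass_non_g, rep(0, 4))
})

test_that("slices with no lung voxels are all-zero rows", {
  u <- uniform_volume(-500, dims = c(6, 6, 3))
  u$mask$mask[, , 2] <- FALSE
  sl <- quantify_slices(u$volume, u$mask)
  expect_equal(sl$mass_g[2], 0)
  expect_equal(sl$volume_ml[2], 0)
  expect_equal(sl$mass_poor_g[2], 0)
})

test_that("aggregation computes fractions as percent of total lung weight", {
  sl <- rbind(make_slices(1, compartment = "non"),
              make_slices(1, compartment = "normal"))
  class(sl) <- c("slice_quant", "data.frame")
  attr(sl, "compartments") <- c("hyper", "normal", "poor", "non")
  q <- aggregate_slices(sl)
  expect_equal(unname(q$fractions_pct), c(0, 50, 0, 50))
  expect_equal(q$tlw_g, 2)

  single <- make_slices(3, volumes = 7)
  q1 <- aggregate_slices(single)
  expect_equal(q1$tlw_g, 3)
  expect_equal(q1$tlv_ml, 7)
  expect_equal(q1$fractions_pct[["poor"]], 100)
})

test_that("aggregate over slices equals the whole-volume computation", {
  ph <- generate_phantom(small_spec(seed = 8L), mAs = 180)
  q <- quantify_lung(ph$volume, ph$mask)
  # independent whole-volume oracle, no per-slice split
  hu <- pmin(pmax(ph$volume$values[ph$mask$mask], -1000), 100)
  vox_ml <- prod(ph$volume$spacing) / 1000
  expect_equal(q$tlw_g, sum((hu + 1000) / 1000) * vox_ml, tolerance = 1e-12)
  expect_equal(q$tlv_ml, length(hu) * vox_ml, tolerance = 1e-12)
  expect_equal(sum(q$fractions_pct), 100, tolerance = 1e-9)
})

test_that("raising HU never decreases total lung weight", {
  for (seed in 1:5) {
    set.seed(seed)
    dims <- c(8, 8, 5)
    vals <- array(runif(prod(dims), -1100, 150), dims)
    mask <- lung_mask(array(runif(prod(dims)) > 0.3, dims))
    v1 <- ct_volume(vals)
    v2 <- ct_volume(vals + runif(1, 0, 300))
    expect_gte(quantify_lung(v2, mask)$tlw_g, quantify_lung(v1, mask)$tlw_g)
  }
})

test_that("degenerate and misaligned inputs raise typed errors", {
  u <- uniform_volume(-1000, dims = c(4, 4, 2))  # pure gas: TLW = 0
  expect_error(quantify_lung(u$volume, u$mask),
               class = "degenerate_input_error")
  m_bad <- lung_mask(array(TRUE, c(4, 4, 3)))
  expect_error(quantify_slices(u$volume, m_bad), class = "alignment_error")
  expect_error(aggregate_slices(make_slices(5)[0, ]),
               class = "insufficient_data_error")
})
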