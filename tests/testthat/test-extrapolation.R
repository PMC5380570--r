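test_that("sequential planning reproduces the protocol slice counts", {
  expect_equal(plan_sequential(L = 240, t = 1, f = 20)$n, 12L)
  expect_equal(plan_sequential(L = 250, t = 1, f = 20)$n, 13L)
  expect_equal(plan_sequential(L = 100, t = 1, f = 1)$n, 100L)
  p <- plan_sequential(L = 240, t = 1, f = 20)
  expect_equal(p$positions_mm, seq(0, 220, by = 20))
  expect_true(all(p$positions_mm + p$t <= p$L))
})

test_that("planned slice count matches brute-force placement enumeration", {
  for (t in c(1, 2, 5)) {
    for (L in seq(10, 400, by = 7)) {
      for (f in unique(round(seq(t, 50, length.out = 8)))) {
        if (f < t || L < t) next
        expect_equal(plan_sequential(L, t, f)$n, count_slices_brute(L, t, f),
                     info = sprintf("L=%g t=%g f=%g", L, t, f))
      }
    }
  }
  # nonzero start offsets shift the grid but keep maximality
  expect_equal(plan_sequential(L = 240, t = 1, f = 20, start = 5)$n,
               count_slices_brute(240, 1, 20, start = 5))
})

test_that("degenerate plans are rejected", {
  expect_error(plan_sequential(L = 0.5, t = 1, f = 20), class = "no_slice_error")
  expect_error(plan_sequential(L = 100, t = 0, f = 20),
               class = "invalid_parameter_error")
  expect_error(plan_sequential(L = 100, t = 5, f = 2),
               class = "invalid_parameter_error")
})

test_that("subset extraction keeps every (f/t)-th slice from the cranial end", {
  sl <- make_slices(rep(1, 250), t = 1)
  sub <- extract_subset(sl, f = 20)
  expect_equal(nrow(sub), 13L)
  expect_equal(sub$slice, seq(0, 240, by = 20))
  expect_identical(extract_subset(sl, f = 1)$mass_g, sl$mass_g)
  expect_error(extract_subset(sl, f = 2.5), class = "incompatible_feed_error")
})

test_that("the worked three-slice example extrapolates to 820 g", {
  sl <- make_slices(c(10, 20, 30), t = 1)
  q <- extrapolate(sl, f = 20)
  expect_equal(q$tlw_g, 820)
})

test_that("constant per-slice mass extrapolates to the closed form", {
  for (n in c(2, 5, 13)) {
    for (f in c(5, 20)) {
      m <- 2.5
      sl <- make_slices(rep(m, n), t = 1)
      expect_equal(extrapolate(sl, f = f)$tlw_g, (n - 1) * f * m + m)
      # oracle: direct summation of the formula terms
      direct <- sum(rep(f * (m + m) / 2, n - 1)) + (m + m) / 2
      expect_equal(extrapolate(sl, f = f)$tlw_g, direct)
    }
  }
})

test_that("extrapolation at f = t telescopes to the full-stack aggregate", {
  ph <- generate_phantom(small_spec(seed = 4L), mAs = 180)
  sl <- quantify_slices(ph$volume, ph$mask)
  ref <- aggregate_slices(sl)
  ex <- extrapolate(extract_subset(sl, f = sl$thickness_mm[1]))
  expect_equal(ex$tlw_g, ref$tlw_g, tolerance = 1e-12)
  expect_equal(ex$tlv_ml, ref$tlv_ml, tolerance = 1e-12)
  expect_equal(ex$compartment_mass_g, ref$compartment_mass_g, tolerance = 1e-12)
})

test_that("extrapolated fractions always sum to 100", {
  ph <- generate_phantom(small_spec(seed = 6L), mAs = 180)
  sl <- quantify_slices(ph$volume, ph$mask)
  for (f in c(6, 15, 30)) {
    q <- extrapolate(extract_subset(sl, f = f))
    expect_equal(sum(q$fractions_pct), 100, tolerance = 1e-9)
  }
})

test_that("extrapolation requires at least two slices", {
  expect_error(extrapolate(make_slices(5), f = 20),
               class = "insufficient_slices_error")
})

test_that("feed sweep produces one comparison per feed with exact identity at f = t", {
  ph <- generate_phantom(small_spec(seed = 9L), mAs = 180)
  sw <- feed_sweep(ph$volume, ph$mask, feeds = c(3, 6, 9, 12))
  expect_length(sw$extrapolated, 4L)
  expect_equal(nrow(sw$table), 4L * 6L)  # 6 metrics per feed
  ident <- feed_sweep(ph$volume, ph$mask, feeds = 3)  # 3 mm = slice thickness
  expect_equal(max(abs(ident$table$difference)), 0, tolerance = 1e-10)
  expect_error(feed_sweep(ph$volume, ph$mask, feeds = numeric(0)),
               class = "invalid_parameter_error")
})
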