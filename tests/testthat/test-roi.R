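test_that("dose classification pins the inclusive 50% convention", {
  # worked example: 3600 cGy against a 6343.8 cGy maximum is the 56.7%
  # iso-dose line and a high radiation dose area
  dc <- classify_dose(3600, 6343.8)
  expect_equal(round(100 * dc$fraction, 1), 56.7)
  expect_equal(dc$class, "high")

  expect_equal(classify_dose(0, 6343.8)$class, "low")
  expect_equal(classify_dose(3171.9, 6343.8)$class, "high") # exactly 50%
  expect_equal(classify_dose(3171.89, 6343.8)$class, "low")
  expect_error(classify_dose(100, 0), "positive")
  expect_error(classify_dose(array(1, c(2, 2, 2)), 10,
                             array(FALSE, c(2, 2, 2))), "empty")
})

test_that("ROI placement satisfies footprint, exclusion and distance rules", {
  ph <- default_phantom()
  rois <- place_peritumoral_rois(ph)
  expect_length(rois, 3L)
  allowed <- ph$labels == ph$label_codes[["peritumoral"]] &
    ph$dose >= 0.5 * ph$max_dose_cgy
  w <- phantom_world(ph)
  centers <- t(vapply(rois, function(r) r$center, numeric(3)))
  for (r in rois) {
    expect_true(all(allowed[r$voxels]))
    expect_equal(length(unique(r$voxels[, 3])), 1L) # single slice
    expect_lt(abs(r$area_mm2 - r$target_area_mm2) / r$target_area_mm2, 0.15)
  }
  wx <- cbind(w$x[centers[, 1]], w$y[centers[, 2]], w$z[centers[, 3]])
  d <- as.matrix(stats::dist(wx))
  expect_true(all(d[upper.tri(d)] >= 20))
})

test_that("ROI placement is deterministic and respects n_rois = 1", {
  ph <- default_phantom()
  a <- place_peritumoral_rois(ph)
  b <- place_peritumoral_rois(ph)
  expect_identical(a, b)
  one <- place_peritumoral_rois(ph, n_rois = 1)
  expect_length(one, 1L)
})

test_that("placement fails informatively when the shell is excluded", {
  ph <- default_phantom()
  ph$enhancing <- ph$labels == ph$label_codes[["peritumoral"]]
  expect_error(place_peritumoral_rois(ph), "infeasible")
})

test_that("roi_mean is the arithmetic mean of valid voxels", {
  d <- c(6, 6, 3)
  r1 <- array(0.8, d)
  map <- list(r1 = r1, mask = array(TRUE, d))
  roi <- array(FALSE, d); roi[2:4, 2:4, 2] <- TRUE
  expect_equal(roi_mean(map, roi)$mean, 0.8)

  # half the voxels at 0.7, half at 0.9 -> 0.8 by hand
  r1b <- array(rep(c(0.7, 0.9), length.out = prod(d)), d)
  expect_equal(roi_mean(list(r1 = r1b, mask = array(TRUE, d)),
                        array(TRUE, d))$mean, 0.8)

  # masked voxels are excluded; fully masked ROI is unmeasurable
  mask <- array(TRUE, d); mask[2, 2, 2] <- FALSE
  r1c <- r1; r1c[2, 2, 2] <- 99
  expect_equal(roi_mean(list(r1 = r1c, mask = mask), roi)$mean, 0.8)
  none <- roi_mean(list(r1 = r1, mask = array(FALSE, d)), roi)
  expect_false(none$measurable)
  expect_true(is.na(none$mean))

  # bounds: min <= mean <= max over the valid ROI voxels
  set.seed(4)
  r1d <- array(runif(prod(d), 0.4, 1.2), d)
  got <- roi_mean(list(r1 = r1d, mask = array(TRUE, d)), roi)$mean
  expect_gte(got, min(r1d[roi])); expect_lte(got, max(r1d[roi]))
})

test_that("measure_patient: identity maps give ratio exactly 1", {
  ph <- effect_phantom()
  p <- acquisition_protocol()
  map <- fit_map(simulate_spgr_series(ph, p, 0, 1, "pre"))
  tab <- measure_patient(map, map, ph, "px")
  expect_equal(nrow(tab), 11L)
  expect_true(all(tab$measurable))
  expect_true(all(tab$r1_ratio == 1))
})

test_that("measure_patient recovers the configured effect exactly at zero noise", {
  ph <- effect_phantom() # routine effect, no noise
  p <- acquisition_protocol()
  pre <- fit_map(simulate_spgr_series(ph, p, 0, 1, "pre"))
  post <- fit_map(simulate_spgr_series(ph, p, 0, 1, "post"))
  tab <- measure_patient(pre, post, ph, "px")
  peri <- tab[tab$region == "peritumoral", ]
  expect_equal(peri$dose_class, "high")
  expect_equal(peri$r1_ratio, 1.0463, tolerance = 1e-9)
  # every peri-tumoral ROI is high-dose; contralateral regions are low-dose
  expect_true(all(tab$dose_class[tab$side == "left" &
                                   tab$region != "peritumoral"] == "low"))
  # fully low-dose contralateral regions show the low-dose ratio exactly
  lows <- tab[tab$side == "left", ]
  expect_equal(lows$r1_ratio, rep(0.9882, nrow(lows)), tolerance = 1e-9)
})

test_that("T2-abnormal regions are unmeasurable, other rows intact", {
  ph <- effect_phantom()
  ph$t2_abnormal <- ph$labels == ph$label_codes[["temporal_wm_left"]]
  p <- acquisition_protocol()
  pre <- fit_map(simulate_spgr_series(ph, p, 0, 1, "pre"))
  post <- fit_map(simulate_spgr_series(ph, p, 0, 1, "post"))
  tab <- measure_patient(pre, post, ph, "px")
  bad <- tab$region == "temporal_wm" & tab$side == "left"
  expect_false(any(tab$measurable[bad]))
  expect_true(all(tab$measurable[!bad]))
  expect_true(all(is.na(tab$r1_ratio[bad])))
  expect_equal(nrow(tab), 11L)
})
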