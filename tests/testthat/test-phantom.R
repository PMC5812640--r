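test_that("phantom regional baseline R1 means match configuration", {
  ph <- default_phantom()
  cfg <- ph$config
  for (nm in names(cfg$region_r1)) {
    m <- ph$labels == ph$label_codes[[nm]]
    expect_gt(sum(m), 20)
    got <- mean(ph$truth$r1_pre[m])
    expect_lt(abs(got - cfg$region_r1[[nm]]) / cfg$region_r1[[nm]], 0.01)
  }
  # peri-tumoral shell sits at its configured baseline level
  shell <- ph$labels == ph$label_codes[["peritumoral"]]
  expect_equal(mean(ph$truth$r1_pre[shell]), 0.7901, tolerance = 0.01)
})

test_that("dose geometry: shell high-dose, contralateral regions low-dose", {
  ph <- default_phantom() # tumor on the right
  shell <- ph$labels == ph$label_codes[["peritumoral"]]
  expect_true(all(ph$dose[shell] >= 0.5 * ph$max_dose_cgy))
  contra <- grep("_left$", names(ph$label_codes), value = TRUE)
  for (nm in contra) {
    m <- ph$labels == ph$label_codes[[nm]]
    expect_true(all(ph$dose[m] < 0.5 * ph$max_dose_cgy))
  }
  # T2* is comfortably above the echo time everywhere in the head
  head <- ph$labels > 0
  expect_true(all(ph$truth$t2star_ms[head] >=
                    20 * acquisition_protocol()$te_ms))
})

test_that("phantom is seed-deterministic; labels do not depend on the seed", {
  a <- build_phantom(phantom_config(), seed = 11)
  b <- build_phantom(phantom_config(), seed = 11)
  c <- build_phantom(phantom_config(), seed = 12)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$r1_pre, b$truth$r1_pre)
  expect_identical(a$labels, c$labels) # geometry is seed-independent
  expect_false(identical(a$truth$r1_pre, c$truth$r1_pre)) # jitter differs
})

test_that("zero-dose configuration yields no high-dose tissue", {
  ph0 <- build_phantom(phantom_config(max_dose_cgy = 0), seed = 1)
  expect_true(all(ph0$dose == 0))
  expect_error(place_peritumoral_rois(ph0), "zero maximum dose")
})

test_that("too-small grids raise a sizing error", {
  expect_error(build_phantom(phantom_config(grid_dim = c(24L, 24L, 8L)),
                             seed = 1),
               "too small")
})

test_that("radiation effect: identity, exact ratio, and error cases", {
  ph <- default_phantom()
  ident <- apply_radiation_effect(ph, radiation_effect(1, 1, 1), "routine")
  expect_identical(ident$truth$r1_post, ident$truth$r1_pre)

  eff <- apply_radiation_effect(ph, radiation_effect(), "routine")
  high <- ph$dose >= 0.5 * ph$max_dose_cgy
  ratio <- eff$truth$r1_post / eff$truth$r1_pre
  inside <- ph$labels > 0
  expect_equal(unique(round(ratio[high & inside], 10)), 1.0463)
  expect_equal(unique(round(ratio[!high & inside], 10)), 0.9882)

  hypo <- apply_radiation_effect(ph, radiation_effect(), "hypofractionated")
  rh <- hypo$truth$r1_post / hypo$truth$r1_pre
  expect_equal(unique(round(rh[high & inside], 10)), 0.9913)

  expect_error(radiation_effect(high_routine = -1), "positive")
  expect_error(radiation_effect(ratio_noise_sd = -0.1), ">= 0")
})

test_that("simulated series obeys the full signal equation with T2* decay", {
  ph <- default_phantom()
  p <- acquisition_protocol()
  ser <- simulate_spgr_series(ph, p, noise_sd = 0, seed = 1, "pre")
  vox <- which(ph$labels == ph$label_codes[["thalamus_right"]])[1]
  r1 <- ph$truth$r1_pre[vox]
  for (i in seq_along(p$flip_angles_deg)) {
    expected <- spgr_signal(ph$config$s0, 1000 / r1, p$tr_ms,
                            p$flip_angles_deg[i], te_ms = p$te_ms,
                            t2star_ms = ph$config$t2star_ms)
    expect_equal(ser$volumes[[i]][vox], expected, tolerance = 1e-12)
  }
  # background voxels carry zero signal
  expect_equal(ser$volumes[[1]][ph$labels == 0][1:10], rep(0, 10))
  # post-radiation series requires the effect to have been applied
  expect_error(simulate_spgr_series(ph, p, 0, 1, "post"), "effect")
})

test_that("noiseless simulate -> fit roundtrip reproduces ground truth", {
  ph <- effect_phantom()
  p <- acquisition_protocol()
  for (tp in c("pre", "post")) {
    ser <- simulate_spgr_series(ph, p, noise_sd = 0, seed = 1, tp)
    map <- fit_map(ser)
    truth <- if (tp == "pre") ph$truth$r1_pre else ph$truth$r1_post
    head <- ph$labels > 0
    expect_true(all(map$mask[head]))
    expect_lt(max(abs(map$r1[head] - truth[head])), 1e-6)
    # background (zero-signal) voxels are all masked invalid
    expect_true(all(!map$mask[!head]))
  }
})

test_that("two seeds give identical labels but different signal noise", {
  ph <- default_phantom()
  p <- acquisition_protocol()
  s1 <- simulate_spgr_series(ph, p, noise_sd = 1, seed = 5, "pre")
  s2 <- simulate_spgr_series(ph, p, noise_sd = 1, seed = 5, "pre")
  s3 <- simulate_spgr_series(ph, p, noise_sd = 1, seed = 6, "pre")
  expect_identical(s1$volumes[[1]], s2$volumes[[1]])
  expect_false(identical(s1$volumes[[1]], s3$volumes[[1]]))
})

test_that("rician noise option produces non-negative signals", {
  ph <- default_phantom()
  p <- acquisition_protocol()
  ser <- simulate_spgr_series(ph, p, noise_sd = 5, seed = 2, "pre",
                              rician = TRUE)
  expect_true(all(ser$volumes[[1]] >= 0))
})
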