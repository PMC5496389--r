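test_that("hemorrhage criterion is strict T2* < 20 ms within the myocardium", {
  vals <- array(35, dim = c(6, 6, 1))
  vals[1:3, 1, 1] <- 19   # 3-voxel line: labelled
  vals[1:3, 3, 1] <- 20   # exactly at threshold: excluded
  vals[1:3, 5, 1] <- 19   # outside myocardium: excluded
  myo <- array(TRUE, dim = dim(vals))
  myo[, 5, ] <- FALSE
  m <- segment_hemorrhage(fake_map(vals), myo)
  expect_true(all(m$mask[1:3, 1, 1]))
  expect_false(any(m$mask[, 3, 1]))
  expect_false(any(m$mask[, 5, 1]))
  expect_equal(sum(m$mask), 3)
  expect_equal(m$provenance$threshold_ms, 20)

  # invalid voxels never labelled
  valid <- array(TRUE, dim = dim(vals))
  valid[2, 1, 1] <- FALSE
  m2 <- segment_hemorrhage(fake_map(vals, valid), myo, min_size = 1)
  expect_false(m2$mask[2, 1, 1])

  # healthy uniform map -> empty
  m3 <- segment_hemorrhage(fake_map(array(35, dim = c(4, 4, 2))),
    array(TRUE, dim = c(4, 4, 2)))
  expect_equal(sum(m3$mask), 0)
})

test_that("raising the hemorrhage threshold never shrinks the mask", {
  set.seed(5)
  vals <- array(runif(4 * 4 * 3, 5, 45), dim = c(4, 4, 3))
  myo <- array(TRUE, dim = dim(vals))
  lo <- segment_hemorrhage(fake_map(vals), myo, threshold_ms = 18, min_size = 1)
  hi <- segment_hemorrhage(fake_map(vals), myo, threshold_ms = 25, min_size = 1)
  expect_true(all(hi$mask[lo$mask]))
})

test_that("edema threshold is strict > remote mean + 2 SD", {
  vals <- array(38, dim = c(6, 6, 1))
  vals[1:3, 1, 1] <- 43   # above 42: labelled
  vals[1:3, 3, 1] <- 42   # at cut-off: excluded
  myo <- array(TRUE, dim = dim(vals))
  m <- segment_edema(fake_map(vals, contrast = "t2prep"), myo, fake_remote(38, 2))
  expect_true(all(m$mask[1:3, 1, 1]))
  expect_false(any(m$mask[, 3, 1]))
  expect_equal(m$provenance$cutoff_ms, 42)

  # homogeneous map at the remote mean -> empty
  m2 <- segment_edema(fake_map(array(38, dim = c(4, 4, 2)), contrast = "t2prep"),
    array(TRUE, dim = c(4, 4, 2)), fake_remote(38, 2))
  expect_equal(sum(m2$mask), 0)

  # undefined remote stats -> directed error
  expect_error(
    segment_edema(fake_map(vals, contrast = "t2prep"), myo, fake_remote(38, NA)),
    "select_remote", class = "cmrtc_undefined_stats"
  )

  # raising n_sd never grows the threshold component
  set.seed(6)
  noisy <- array(runif(6 * 6 * 3, 35, 50), dim = c(6, 6, 3))
  myo3 <- array(TRUE, dim = dim(noisy))
  a <- segment_edema(fake_map(noisy, contrast = "t2prep"), myo3,
    fake_remote(38, 2), min_size = 1)
  b <- segment_edema(fake_map(noisy, contrast = "t2prep"), myo3,
    fake_remote(38, 3), min_size = 1)
  expect_lte(b$provenance$n_threshold, a$provenance$n_threshold)
})

test_that("hypointense cores enclosed by edema are filled in", {
  # noiseless I+HEM: hemorrhage core (T2 25 < remote 38) must be in the edema
  # mask even without companion masks, via enclosed-region growing
  gt <- build_phantom(small_spec("I+HEM"))
  t2m <- fit_exponential_map(simulate_t2prep_series(gt), gt$myocardium)
  remote_mask <- select_remote(gt$myocardium, gt$spec, gt$spec$sector_center_deg)
  remote <- remote_reference(t2m, remote_mask)
  m <- segment_edema(t2m, gt$myocardium, remote)
  expect_true(all(m$mask[gt$masks$hemorrhage]))
  expect_equal(dice(m$mask, gt$masks$edema), 1)
  expect_gt(m$provenance$n_core_fill, 0)
})

test_that("remote sector is antipodal and avoids the lesion", {
  spec <- small_spec("I+HEM")
  gt <- build_phantom(spec)
  rem <- select_remote(gt$myocardium, spec, 120, width_deg = 60)
  pg <- cmrtc:::polar_grid(spec$matrix, spec$voxel_size, spec$center)
  th <- pg$theta[which(rem[, , 1])]
  offs <- ((th - 300 + 180) %% 360) - 180
  expect_true(all(abs(offs) <= 30 + 1e-9))
  expect_error(select_remote(gt$myocardium, spec, 120, width_deg = 360),
    class = "cmrtc_config_error")
  expect_error(select_remote(array(FALSE, dim = dim(gt$myocardium)), spec, 120),
    class = "cmrtc_data_error")
  # remote never intersects ground-truth edema, any arm
  for (arm in c("+HEM", "I-HEM", "I+HEM")) {
    g <- build_phantom(small_spec(arm))
    r <- select_remote(g$myocardium, g$spec, g$spec$sector_center_deg)
    expect_equal(sum(r & g$masks$edema), 0)
  }
})

test_that("FWHM labels voxels at or above half the reference maximum", {
  img <- array(0, dim = c(8, 3, 1))
  prof <- c(10, 10, 80, 100, 60, 10, 10, 10)
  img[, 2, 1] <- prof
  myo <- array(FALSE, dim = dim(img))
  myo[, 2, 1] <- TRUE
  m <- segment_infarct_fwhm(img, myo, remote_lge = list(mean = 10, sd = 0))
  expect_equal(which(m$mask[, 2, 1]), 3:5) # {80, 100, 60} >= 50
  expect_equal(m$provenance$half_max, 50)

  # below-floor guard: no enhancement -> empty with provenance note
  flat <- array(10, dim = dim(img))
  m2 <- segment_infarct_fwhm(flat, myo, remote_lge = list(mean = 10, sd = 1))
  expect_equal(sum(m2$mask), 0)
  expect_true(m2$provenance$below_floor)

  expect_error(segment_infarct_fwhm(img, array(FALSE, dim = dim(img))),
    class = "cmrtc_data_error")
})

test_that("+HEM phantom yields an empty infarct mask", {
  gt <- build_phantom(small_spec("+HEM"))
  lge <- simulate_lge_image(gt)
  rem <- select_remote(gt$myocardium, gt$spec, gt$spec$sector_center_deg)
  m <- segment_infarct_fwhm(lge, gt$myocardium,
    remote_lge = list(mean = mean(lge$data[rem]), sd = stats::sd(lge$data[rem])))
  expect_equal(sum(m$mask), 0)
  expect_true(m$provenance$below_floor)
})

test_that("FWHM equals a brute-force half-maximum scan on random phantoms", {
  set.seed(31)
  for (rep in 1:10) {
    spec <- small_spec(sample(c("I-HEM", "I+HEM"), 1),
      sector_width_deg = runif(1, 50, 110),
      transmurality = runif(1, 0.55, 0.9),
      sector_center_deg = runif(1, 0, 359))
    gt <- build_phantom(spec)
    lge <- simulate_lge_image(gt)
    m <- segment_infarct_fwhm(lge, gt$myocardium, min_size = 1)
    oracle <- gt$myocardium & lge$data >= 0.5 * max(lge$data[gt$myocardium])
    expect_identical(m$mask, oracle)
  }
})

test_that("MVO is the enclosed hypoenhanced core, seeded or automatic", {
  gt <- build_phantom(small_spec("I+HEM"))
  lge <- simulate_lge_image(gt)
  inf <- segment_infarct_fwhm(lge, gt$myocardium)
  m <- segment_mvo(lge, inf)
  expect_gte(dice(m$mask, gt$masks$mvo), 0.95)
  expect_true(!any(m$mask & !(gt$masks$infarct))) # containment in true infarct

  # seeded growth from a ground-truth MVO voxel gives the same region
  seed <- arrayInd(which(gt$masks$mvo)[1], dim(lge$data))[1, ]
  m2 <- segment_mvo(lge, inf, seed_point = seed)
  expect_identical(m2$mask, m$mask)

  # seed outside the infarct bounding region -> error
  expect_error(segment_mvo(lge, inf, seed_point = c(1L, 1L, 1L)),
    class = "cmrtc_config_error")

  # I-HEM: enhanced but no enclosed hypointensity -> empty
  gt2 <- build_phantom(small_spec("I-HEM"))
  lge2 <- simulate_lge_image(gt2)
  inf2 <- segment_infarct_fwhm(lge2, gt2$myocardium)
  expect_equal(sum(segment_mvo(lge2, inf2)$mask), 0)

  expect_error(segment_mvo(lge, array(FALSE, dim = dim(lge$data))),
    class = "cmrtc_config_error")
})

test_that("hypointense regions touching unenclosed tissue are excluded", {
  # carve a dark channel from the MVO core through the infarct rim so the
  # core connects to the nulled remote myocardium: no longer enclosed
  gt <- build_phantom(small_spec("I+HEM"))
  lge <- simulate_lge_image(gt)
  d <- dim(lge$data)
  core <- which(gt$masks$mvo)
  ai <- arrayInd(core, d)
  z <- ai[1, 3]
  row <- ai[1, 1]
  img <- lge$data
  img[row, , z] <- 0 # dark line across the whole slice row
  inf <- segment_infarct_fwhm(img, gt$myocardium)
  m <- segment_mvo(img, inf)
  expect_equal(sum(m$mask), 0)
})

test_that("segmentations are idempotent and audit their thresholds", {
  gt <- build_phantom(small_spec("I+HEM", noise = list(model = "rician", snr = 20)))
  t2sm <- fit_exponential_map(simulate_gre_series(gt), gt$myocardium)
  a <- segment_hemorrhage(t2sm, gt$myocardium, threshold_ms = 20, min_size = 3)
  b <- segment_hemorrhage(t2sm, gt$myocardium, threshold_ms = 20, min_size = 3)
  expect_identical(a$mask, b$mask)
  expect_equal(a$provenance$threshold_ms, 20)
  expect_equal(a$provenance$min_component_size, 3)
  # noise robustness at SNR 20
  expect_gte(dice(a$mask, gt$masks$hemorrhage), 0.8)
})

test_that("connected-component labelling uses 6-connectivity", {
  m <- array(FALSE, dim = c(3, 3, 2))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE # diagonal: separate component
  m[2, 2, 2] <- TRUE # stacked through-plane: same as [2,2,1]
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2, 1], lab[2, 2, 2])
  expect_false(lab[1, 1, 1] == lab[2, 2, 1])
})
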