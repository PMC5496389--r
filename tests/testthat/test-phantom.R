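test_that("arm determines which lesion components exist", {
  gt <- build_phantom(small_spec("healthy"))
  expect_true(all(vapply(gt$masks, function(m) sum(m) == 0, logical(1))))
  expect_length(unique(gt$t2[gt$myocardium]), 1L)
  expect_length(unique(gt$t2star[gt$myocardium]), 1L)

  gt <- build_phantom(small_spec("+HEM"))
  expect_equal(sum(gt$masks$infarct), 0)
  expect_equal(sum(gt$masks$mvo), 0)
  expect_gt(sum(gt$masks$hemorrhage), 0)
  expect_gt(sum(gt$masks$edema), 0)

  gt <- build_phantom(small_spec("I-HEM"))
  expect_equal(sum(gt$masks$hemorrhage), 0)
  expect_gt(sum(gt$masks$infarct), 0)

  gt <- build_phantom(small_spec("I+HEM"))
  expect_true(all(vapply(gt$masks, function(m) sum(m) > 0, logical(1))))
})

test_that("inconsistent arm/component combinations are configuration errors", {
  expect_error(small_spec("I-HEM", hemorrhage_fraction = 0.2),
    "hemorrhagic", class = "cmrtc_config_error")
  expect_error(small_spec("+HEM", mvo_fraction = 0.1),
    "MVO", class = "cmrtc_config_error")
  expect_error(small_spec("I+HEM", hemorrhage_fraction = 0),
    class = "cmrtc_config_error")
  expect_error(small_spec("I+HEM", tissue = list(hemorrhage_t2star = 25)),
    class = "cmrtc_config_error")
  expect_error(small_spec("I+HEM", tissue = list(edema_t2 = 30)),
    class = "cmrtc_config_error")
})

test_that("mvo fraction of infarct is honoured to rasterization tolerance", {
  for (frac in c(0.1, 0.2)) {
    gt <- build_phantom(small_spec("I+HEM", mvo_fraction = frac))
    n_inf <- sum(gt$masks$infarct)
    expect_lte(abs(sum(gt$masks$mvo) - frac * n_inf), 1)
  }
  # full-size grid, the stock configuration
  gt <- build_phantom(phantom_spec("I+HEM", mvo_fraction = 0.2,
    noise = list(model = "none")))
  expect_lte(abs(sum(gt$masks$mvo) - 0.2 * sum(gt$masks$infarct)), 1)
  # mvo is one connected blob
  lab <- label_components(gt$masks$mvo)
  expect_equal(max(lab), 1L)
})

test_that("mask algebra holds on every arm", {
  for (arm in c("healthy", "+HEM", "I-HEM", "I+HEM")) {
    gt <- build_phantom(small_spec(arm))
    m <- gt$masks
    expect_true(all(m$mvo[m$mvo] & gt$masks$infarct[m$mvo]))
    expect_true(!any(m$hemorrhage & !m$edema))       # hemorrhage in edema
    expect_true(!any(m$mvo & !m$infarct))            # mvo in infarct
    expect_true(!any(m$infarct & !m$edema))          # infarct in edema shell
    for (lb in names(m)) expect_true(!any(m[[lb]] & !gt$myocardium))
    sel <- gt$myocardium
    expect_true(all(is.finite(gt$t2[sel]) & gt$t2[sel] > 0))
    expect_true(all(is.finite(gt$t2star[sel]) & gt$t2star[sel] > 0))
    expect_true(all(gt$amplitude[sel] > 0))
  }
})

test_that("noiseless signals match the closed-form decay model", {
  spec <- small_spec("healthy", tissue = list(remote_t2 = 50, remote_t2star = 20))
  gt <- build_phantom(spec)
  proto <- acquisition_protocol("t2prep", c(2.9, 184.2),
    voxel_size = spec$voxel_size, n_slices = spec$n_slices, matrix = spec$matrix)
  ser <- simulate_t2prep_series(gt, proto)
  vox <- which(gt$myocardium)[1]
  expect_equal(ser$data[, , , 2][vox], 100 * exp(-184.2 / 50), tolerance = 1e-12)
  expect_equal(round(ser$data[, , , 2][vox], 2), 2.51)

  gproto <- acquisition_protocol("me_gre", c(1.4, 15.8),
    voxel_size = spec$voxel_size, n_slices = spec$n_slices, matrix = spec$matrix)
  gser <- simulate_gre_series(gt, gproto)
  expect_equal(gser$data[, , , 2][vox], 100 * exp(-15.8 / 20), tolerance = 1e-12)
  expect_equal(round(gser$data[, , , 2][vox], 1), 45.4)
})

test_that("hemorrhagic core is darker than remote at the last echo", {
  gt <- build_phantom(small_spec("I+HEM"))
  ser <- simulate_gre_series(gt, noise = list(model = "none"))
  last <- ser$data[, , , dim(ser$data)[4]]
  remote <- gt$myocardium & !gt$masks$edema
  expect_lt(max(last[gt$masks$hemorrhage]), min(last[remote]))
})

test_that("series are deterministic under a fixed seed and differ across seeds", {
  gt <- build_phantom(small_spec("I+HEM", noise = list(model = "rician", snr = 20)))
  a <- simulate_t2prep_series(gt, seed = 7)
  b <- simulate_t2prep_series(gt, seed = 7)
  c <- simulate_t2prep_series(gt, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("magnitude images are non-negative under any noise model", {
  gt <- build_phantom(small_spec("I+HEM"))
  for (model in c("rician", "gaussian")) {
    ser <- simulate_gre_series(gt, noise = list(model = model, snr = 5), seed = 3)
    expect_gte(min(ser$data), 0)
  }
})

test_that("Rician noise biases low signals upward", {
  s0 <- 5 # remote amplitude 100, SNR 20 -> sigma 5: signal at noise floor
  draws <- cmrtc:::apply_noise(rep(s0, 1e4), list(model = "rician", snr = 20),
    100, seed = 1)
  expect_gt(mean(draws), s0)
})

test_that("grid and protocol mismatches are rejected", {
  gt <- build_phantom(small_spec("healthy"))
  bad <- acquisition_protocol("t2prep", c(2.9, 184.2), n_slices = 3L,
    matrix = c(48L, 48L))
  expect_error(simulate_t2prep_series(gt, bad), class = "cmrtc_dim_error")
  lge_like <- acquisition_protocol("lge", numeric(), n_slices = 6L)
  expect_error(simulate_t2prep_series(gt, lge_like), class = "cmrtc_config_error")
  expect_error(acquisition_protocol("me_gre", c(5, 3)), class = "cmrtc_config_error")
  expect_error(acquisition_protocol("me_gre", c(5)), class = "cmrtc_config_error")
  expect_error(simulate_lge_image(gt, inversion_time = -1),
    class = "cmrtc_config_error")
})

test_that("LGE compartments null, enhance and hypoenhance as configured", {
  gt <- build_phantom(small_spec("I+HEM"))
  lge <- simulate_lge_image(gt, noise = list(model = "none"))
  remote <- gt$myocardium & !gt$masks$edema
  expect_lt(max(lge$data[remote]), 1e-9) # exp(-TI/T1) = 1/2 -> nulled
  rim <- gt$masks$infarct & !gt$masks$mvo
  expect_lt(mean(lge$data[gt$masks$mvo]), mean(lge$data[rim]) / 2)

  # short-T1 limit: full recovery to A
  gt2 <- build_phantom(small_spec("I-HEM", tissue = list(t1_infarct = 1)))
  lge2 <- simulate_lge_image(gt2, noise = list(model = "none"))
  expect_equal(max(lge2$data[gt2$masks$infarct]), 100, tolerance = 1e-6)
})

test_that("cine masks hit EDV/ESV and conserve myocardium", {
  spec <- small_spec("healthy")
  cine <- simulate_cine_masks(spec, n_phases = 8)
  vml <- prod(spec$voxel_size) / 1000
  vols <- vapply(cine$cavity, function(m) sum(m) * vml, numeric(1))
  expect_equal(vols[1], spec$cine$edv_ml, tolerance = 0.03 * spec$cine$edv_ml)
  expect_equal(min(vols), spec$cine$esv_ml, tolerance = 0.03 * spec$cine$esv_ml)
  myo <- vapply(cine$myocardium, sum, numeric(1))
  expect_lt(diff(range(myo)) / mean(myo), 0.03)
  # cavity and myocardium never overlap
  expect_true(!any(cine$cavity[[3]] & cine$myocardium[[3]]))

  single <- simulate_cine_masks(spec, n_phases = 1)
  expect_length(single$cavity, 1L)
  expect_equal(single$volumes_ml[1], spec$cine$edv_ml,
    tolerance = 0.03 * spec$cine$edv_ml)

  bad <- small_spec("healthy")
  bad$cine$esv_ml <- 80
  expect_error(simulate_cine_masks(bad), class = "cmrtc_config_error")
})

test_that("masks survive a NIfTI round trip bit-identically", {
  gt <- build_phantom(small_spec("I+HEM"))
  p <- withr::local_tempfile(fileext = ".nii")
  write_nifti(gt$masks$edema, p)
  expect_identical(array(read_nifti(p)$data > 0, dim = dim(gt$masks$edema)),
    gt$masks$edema)
})

test_that("noiseless series fitted back give the true maps to 1e-6", {
  gt <- build_phantom(small_spec("I+HEM"))
  t2m <- fit_exponential_map(simulate_t2prep_series(gt), gt$myocardium)
  rel <- abs(t2m$relaxation_time - gt$t2) / gt$t2
  expect_lt(max(rel[gt$myocardium]), 1e-6)
  t2sm <- fit_exponential_map(simulate_gre_series(gt), gt$myocardium)
  rel <- abs(t2sm$relaxation_time - gt$t2star) / gt$t2star
  expect_lt(max(rel[gt$myocardium]), 1e-6)
})
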