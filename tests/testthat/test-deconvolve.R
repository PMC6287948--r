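test_that("convolution matrix is the causal Toeplitz discretisation", {
  dt <- 1.47
  # unit impulse kernel -> dt * identity
  A <- build_convolution_matrix(c(1, 0, 0, 0), dt)
  expect_equal(A, dt * diag(4))
  aif <- c(0, 1, 3, 2, 1, 0.5)
  A <- build_convolution_matrix(aif, dt)
  expect_true(all(A[upper.tri(A)] == 0))
  # matrix-vector product reproduces the generator's discrete convolution
  pbv <- 20; pbf <- 240
  x <- (pbf / 6000) * (1 - dt / 5)^(0:5)
  expect_equal(as.numeric(A %*% x),
               tissue_curve_from_truth(aif, pbf, pbv, dt), tolerance = 1e-10)
})

test_that("near-untruncated SVD inverts a consistent system to numerical precision", {
  # a decaying bolus kernel gives a well-conditioned consistent system; a
  # rising first-pass edge makes the triangular system near-singular, which
  # is exactly what the truncation threshold exists for
  aif <- 3 * 0.6^(0:11)
  A <- build_convolution_matrix(aif, 1.47)
  set.seed(42)
  for (i in 1:5) {
    x <- abs(rnorm(12, 0.04, 0.02))
    y <- as.numeric(A %*% x)
    est <- deconvolve_voxel(y, A, truncation_frac = 1e-9)
    expect_lt(max(abs(est$residue - x)) / max(x), 1e-8)
  }
})

test_that("zero tissue curve gives a zero residue flagged invalid", {
  A <- build_convolution_matrix(c(1, 2, 1, 0.5), 1.47)
  est <- deconvolve_voxel(rep(0, 4), A)
  expect_equal(est$residue, rep(0, 4))
  aif <- structure(list(integral = 10, values = c(1, 2, 1, 0.5)),
                   class = "aif_curve")
  p <- params_from_residue(est, rep(0, 4), aif, times_s = (1:4) * 1.47)
  expect_false(p$valid)
  expect_true(is.na(p$mtt_s))
})

test_that("noise-free deconvolution recovers the flow-scaled residue", {
  spec <- small_spec(noise_sd = 0, sat_beta = 0, residual_fraction = 0)
  ph <- generate_phantom(spec)
  conc <- signal_to_concentration(ph$series, ph$truth$arrival_frame)
  w <- ph$truth$arrival_frame:spec$n_frames
  A <- build_convolution_matrix(ph$truth$aif_first_pass[w], spec$dt_s)
  row <- ph$truth$region_table[1, ]
  vox <- which(ph$series$masks$regions == row$region_id)[1]
  co <- arrayInd(vox, dim(ph$series$masks$regions))
  ct <- conc$data[co[1], co[2], co[3], w]
  est <- deconvolve_voxel(ct, A, truncation_frac = 1e-6)
  f <- row$pbf / 6000
  truth <- f * (1 - spec$dt_s / row$mtt)^(seq_along(w) - 1)
  keep <- (seq_along(w) - 1) * spec$dt_s <= 3 * row$mtt
  expect_equal(est$residue[keep], truth[keep], tolerance = 0.02)
})

test_that("parameter extraction follows the indicator-dilution definitions", {
  times <- (1:24) * 1.47
  av <- generate_aif(aif_params(), times)$first_pass[6:24]
  tw <- times[6:24]
  aif <- structure(list(values = av, integral = trapz(tw, av)),
                   class = "aif_curve")
  # shape-identical tissue curve: PBV is the scale factor exactly
  A <- build_convolution_matrix(av, 1.47)
  est <- deconvolve_voxel(0.1 * av, A, truncation_frac = 1e-8)
  p <- params_from_residue(est, 0.1 * av, aif, tw)
  expect_equal(p$pbv, 10, tolerance = 1e-9)
  # joint rescaling of AIF and tissue leaves all parameters unchanged
  aif2 <- structure(list(values = 2 * av, integral = 2 * aif$integral),
                    class = "aif_curve")
  est2 <- deconvolve_voxel(0.2 * av, build_convolution_matrix(2 * av, 1.47),
                           truncation_frac = 1e-8)
  p2 <- params_from_residue(est2, 0.2 * av, aif2, tw)
  expect_equal(p2$pbv, p$pbv, tolerance = 1e-9)
  expect_equal(p2$pbf, p$pbf, tolerance = 1e-7)
  expect_equal(p2$mtt_s, p$mtt_s, tolerance = 1e-7)
})

test_that("central-volume MTT agrees with residue area/height on noise-free data", {
  spec <- small_spec(noise_sd = 0, sat_beta = 0, residual_fraction = 0)
  ph <- generate_phantom(spec)
  conc <- signal_to_concentration(ph$series, ph$truth$arrival_frame)
  w <- ph$truth$arrival_frame:spec$n_frames
  A <- build_convolution_matrix(ph$truth$aif_first_pass[w], spec$dt_s)
  for (id in c(1, 2)) {
    row <- ph$truth$region_table[ph$truth$region_table$region_id == id, ]
    vox <- which(ph$series$masks$regions == id)[1]
    co <- arrayInd(vox, dim(ph$series$masks$regions))
    est <- deconvolve_voxel(conc$data[co[1], co[2], co[3], w], A)
    mtt_ah <- spec$dt_s * sum(est$residue) / max(est$residue)
    expect_equal(mtt_ah, row$mtt, tolerance = 0.15)
  }
})

test_that("whole-pipeline recovery holds per region and is deterministic", {
  spec <- small_spec(noise_sd = 2, sat_beta = 0, residual_fraction = 0)
  ph <- generate_phantom(spec)
  maps <- quantify_lung(ph$series)
  err <- region_recovery_errors(ph, maps)
  expect_true(all(abs(err$pbf) < 0.10))
  expect_true(all(abs(err$pbv) < 0.10))
  expect_true(all(abs(err$mtt) < 0.10))
  maps2 <- quantify_lung(ph$series)
  expect_identical(maps$pbf, maps2$pbf)
  # single-voxel mask contract
  one <- array(FALSE, dim(ph$series$masks$lung))
  one[which(ph$series$masks$lung)[1]] <- TRUE
  m1 <- quantify_lung(ph$series, lung_mask = one)
  expect_equal(sum(!is.na(m1$pbf)), 1)
})

test_that("late bolus arrival aborts quantification", {
  spec <- small_spec(noise_sd = 0, injection_delay_s = 16)
  ph <- generate_phantom(spec)
  expect_error(quantify_lung(ph$series), "insufficient first-pass coverage")
})
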