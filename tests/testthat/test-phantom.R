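test_that("AIF has no contrast before injection and an additive residual plateau", {
  times <- (1:24) * 1.47
  p <- aif_params()
  aif0 <- generate_aif(p, times, injection_delay_s = 5, arrival_delay_s = 3,
                       residual_fraction = 0)
  pre <- times < 8
  expect_true(all(aif0$values[pre] == 0))

  css <- p$amplitude / 80
  aif5 <- generate_aif(p, times, residual_fraction = 0.5,
                       steady_state_conc = css)
  expect_equal(unique(aif5$values[pre]), 0.5 * css)
  # first-pass component unchanged by the residual baseline
  expect_equal(aif5$values - aif5$residual, aif0$values)
  # the sampled peak sits within one frame of the analytic maximum
  expect_lte(max(aif5$first_pass), p$amplitude)
  expect_gt(max(aif5$first_pass), 0.95 * p$amplitude)
})

test_that("first enhanced frame matches the protocol timing arithmetic", {
  # injection 5 s + trunk arrival 3 s at 1.47 s/frame: floor(8/1.47) = 5
  # unenhanced frames, so the first enhanced frame is the 6th (1-based)
  times <- (1:24) * 1.47
  aif <- generate_aif(aif_params(), times, 5, 3)
  expect_identical(which(aif$first_pass > 0)[1], 6L)
})

test_that("a bolus peaking after the last frame is refused", {
  times <- (1:10) * 1.47
  expect_error(generate_aif(aif_params(time_to_peak_s = 20), times, 5, 3),
               "after the last frame")
})

test_that("tissue curve is the flow-scaled residue response", {
  dt <- 1.47; pbv <- 20; pbf <- 240
  mtt <- 60 * pbv / pbf
  expect_equal(mtt, 5)
  # delta-like AIF with integral A: tissue curve = f * A * R(t)
  A <- 7
  aif <- c(A / dt, rep(0, 19))
  ct <- tissue_curve_from_truth(aif, pbf, pbv, dt)
  f <- pbf / 6000
  expect_equal(ct[1], f * A)
  expect_equal(ct, f * A * (1 - dt / mtt)^(0:19), tolerance = 1e-10)
  # geometric kernel tracks the exponential residue when dt << MTT
  ct_fine <- tissue_curve_from_truth(c(A / 0.1, rep(0, 199)), pbf, pbv, 0.1)
  expect_equal(ct_fine, f * A * exp(-(0:199) * 0.1 / mtt), tolerance = 0.05)
})

test_that("tissue/arterial integral ratio recovers PBV in the untruncated limit", {
  dt <- 1.47; n <- 200
  times <- (1:n) * dt
  aif <- generate_aif(aif_params(), times)$first_pass
  for (pv in c(10, 20)) {
    ct <- tissue_curve_from_truth(aif, pbf = 12 * pv, pbv = pv, dt)
    expect_equal(sum(ct) / sum(aif), pv / 100, tolerance = 1e-8)
  }
  expect_error(tissue_curve_from_truth(aif, pbf = 240, pbv = 1, dt),
               "below the frame interval")
})

test_that("saturating enhancement model is monotone, concave and bounded", {
  expect_equal(signal_from_concentration(0, 100, 1), 100)
  expect_equal(signal_from_concentration(0.5, 100, 0), 150)
  expect_equal(signal_from_concentration(1e9, 100, 1), 200, tolerance = 1e-6)
  expect_error(signal_from_concentration(-0.1, 100, 1), "non-negative")

  cgrid <- seq(0, 10, by = 0.05)
  s <- signal_from_concentration(cgrid, 100, 0.7)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) <= 1e-9))
  # marginal enhancement of a fixed increment decreases with the baseline
  marg <- signal_from_concentration(cgrid + 0.2, 100, 0.7) - s
  expect_true(all(diff(marg) < 0))
})

test_that("noiseless linear phantom voxels carry exactly the analytic curves", {
  spec <- small_spec(noise_sd = 0, sat_beta = 0, residual_fraction = 0)
  ph <- generate_phantom(spec)
  tr <- ph$truth
  reg <- ph$series$masks$regions
  for (id in c(1, 8)) {
    vox <- which(reg == id)[1]
    co <- arrayInd(vox, dim(reg))
    sig <- ph$series$data[co[1], co[2], co[3], ]
    row <- tr$region_table[tr$region_table$region_id == id, ]
    ct <- tissue_curve_from_truth(tr$aif_first_pass, row$pbf, row$pbv,
                                  spec$dt_s)
    expect_equal(sig, spec$s0 * (1 + ct), tolerance = 1e-12)
  }
  # trunk voxels carry the AIF signal
  tvox <- which(ph$series$masks$trunk)[1]
  co <- arrayInd(tvox, dim(reg))
  expect_equal(ph$series$data[co[1], co[2], co[3], ],
               spec$s0 * (1 + tr$aif), tolerance = 1e-12)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(small_spec(seed = 11))
  b <- generate_phantom(small_spec(seed = 11))
  d <- generate_phantom(small_spec(seed = 12))
  expect_identical(a$series$data, b$series$data)
  expect_false(identical(a$series$data, d$series$data))
})

test_that("dorsal truth exceeds ventral truth under the default gradient", {
  ph <- generate_phantom(small_spec(noise_sd = 0))
  tab <- ph$truth$region_table
  expect_true(all(tab$pbv[tab$depth == "back"] >
                    tab$pbv[tab$depth == "front"]))
  dorsal <- median(ph$truth$maps$pbv[ph$series$masks$regions %in%
                                       tab$region_id[tab$depth == "back"]])
  ventral <- median(ph$truth$maps$pbv[ph$series$masks$regions %in%
                                        tab$region_id[tab$depth == "front"]])
  expect_gt(dorsal, ventral)
})

test_that("generation refuses truth with MTT below the frame interval", {
  bad <- default_region_truth()
  bad$pbf <- bad$pbv * 60  # MTT = 1 s < 1.47 s
  expect_error(small_spec(region_truth = bad), "below the frame interval")
  bad2 <- default_region_truth()[-1, ]
  ph <- expect_error(generate_phantom(small_spec(region_truth = bad2)),
                     "missing regions")
})

test_that("unenhanced frame count spans 5 to 8 over physiological arrival delays", {
  times <- (1:24) * 1.47
  for (delay in seq(2.4, 8.2, by = 0.2)) {
    aif <- generate_aif(aif_params(), times, 5, delay)
    n_unenh <- which(aif$first_pass > 0)[1] - 1
    expect_gte(n_unenh, 5)
    expect_lte(n_unenh, 8)
  }
})
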