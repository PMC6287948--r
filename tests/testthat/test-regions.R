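test_that("lungs are split by connectivity and handed out left/right", {
  dm <- c(20, 10, 10)
  mask <- array(FALSE, dm)
  mask[2:8, 2:9, 2:9] <- TRUE
  mask[12:18, 2:9, 2:9] <- TRUE
  s <- split_lungs(mask)
  expect_equal(sum(s$left), 7 * 8 * 8)
  expect_true(all(arrayInd(which(s$left), dm)[, 1] <= 8))
  expect_true(all(arrayInd(which(s$right), dm)[, 1] >= 12))
  blob <- array(FALSE, dm); blob[5:15, 2:9, 2:9] <- TRUE
  expect_error(split_lungs(blob), "not separable")
})

test_that("phantom masks split into the generator's own left/right lungs", {
  ph <- generate_phantom(small_spec())
  s <- split_lungs(ph$series$masks$lung)
  reg <- ph$series$masks$regions
  expect_true(all(reg[s$left] %in% 1:6))
  expect_true(all(reg[s$right] %in% 7:12))
})

test_that("divisible cuboid partitions into six exactly equal regions", {
  mask <- array(FALSE, c(50, 2, 6))
  mask[1:50, 1:2, 1:6] <- TRUE  # 600 voxels, 6 z-planes x 2 y-planes
  p <- partition_lung(mask)
  expect_equal(sort(unique(p$labels[mask])), 1:6)
  expect_true(all(p$table$voxel_count == 100))
})

test_that("near-divisible mask achieves the brute-force optimal slab balance", {
  extra <- array(FALSE, c(10, 10, 7))
  extra[, , 1:6] <- TRUE       # 100 voxels per z-plane
  extra[1, 1, 7] <- TRUE       # 601 voxels, uneven final plane
  p <- partition_lung(extra)
  slab <- tapply(p$table$voxel_count, rep(1:3, each = 2), sum)
  # brute-force enumeration of all plane cuts
  plane <- apply(extra, 3, sum)
  best <- Inf
  for (k1 in 1:5) for (k2 in (k1 + 1):6) {
    s <- c(sum(plane[1:k1]), sum(plane[(k1 + 1):k2]),
           sum(plane[(k2 + 1):7]))
    best <- min(best, max(dist(s)))
  }
  expect_equal(max(dist(as.numeric(slab))), best)
  # deterministic
  p2 <- partition_lung(extra)
  expect_identical(p$labels, p2$labels)
})

test_that("partition invariants hold on randomized masks", {
  set.seed(202)
  for (i in 1:100) {
    dm <- c(sample(6:12, 1), sample(8:14, 1), sample(4:9, 1))
    mask <- array(FALSE, dm)
    mask[2:dm[1], 2:dm[2], 1:dm[3]] <- TRUE
    drop <- sample(which(mask), round(0.15 * sum(mask)))
    mask[drop] <- FALSE
    plane_z <- apply(mask, 3, sum)
    if (sum(plane_z > 0) < 3) next
    p <- tryCatch(partition_lung(mask), error = function(e) NULL)
    if (is.null(p)) next  # slab too thin to halve: allowed failure mode
    lab <- p$labels
    # disjoint cover of the mask with six non-empty regions
    expect_true(all(lab[mask] %in% 1:6))
    expect_true(all(lab[!mask] == 0))
    expect_equal(sum(p$table$voxel_count), sum(mask))
    expect_true(all(p$table$voxel_count > 0))
    # slab imbalance bounded by one plane's in-mask count
    slab <- tapply(p$table$voxel_count, rep(1:3, each = 2), sum)
    expect_lte(max(dist(as.numeric(slab))), max(plane_z))
  }
})

test_that("12-region partition covers both lungs with sensible volumes", {
  ph <- generate_phantom(small_spec())
  part <- partition_regions(ph$series$masks$lung, c(8, 8, 15))
  expect_equal(nrow(part$table), 12)
  expect_equal(sum(part$table$voxel_count), sum(ph$series$masks$lung))
  expect_equal(part$table$volume_ml,
               part$table$voxel_count * 8 * 8 * 15 / 1000)
})

test_that("vessel exclusion removes the high-PBV tail and planted vessels", {
  # percentile contract on a continuous map
  set.seed(7)
  dm <- c(12, 12, 8)
  mask <- array(TRUE, dm)
  maps <- list(pbv = array(runif(prod(dm)), dm), valid_mask = mask)
  out <- exclude_vessels(maps, mask, pbv_percentile = 95, dilate = 0)
  expect_equal(1 - sum(out) / sum(mask), 0.05, tolerance = 0.01)
  expect_error(exclude_vessels(maps, mask, pbv_percentile = 40), "percentile")

  # planted vessel voxels at 5x regional PBV are all removed
  spec <- small_spec(noise_sd = 1, sat_beta = 0, vessel_fraction = 0.005)
  ph <- generate_phantom(spec)
  qm <- quantify_lung(ph$series)
  kept <- exclude_vessels(qm, ph$series$masks$lung)
  expect_equal(sum(kept & ph$series$masks$vessels), 0)

  # on a vessel-free phantom with spatially uniform truth the filtered
  # medians barely move (the removed tail is symmetric noise, so the
  # median is robust to it)
  spec0 <- small_spec(noise_sd = 1, sat_beta = 0,
                      region_truth = default_region_truth(pbv_front = 20,
                                                          pbv_back = 20))
  ph0 <- generate_phantom(spec0)
  qm0 <- quantify_lung(ph0$series)
  kept0 <- exclude_vessels(qm0, ph0$series$masks$lung)
  for (p in c("pbf", "pbv")) {
    m_all <- median(qm0[[p]][ph0$series$masks$lung & qm0$valid_mask])
    m_flt <- median(qm0[[p]][kept0 & qm0$valid_mask])
    expect_equal(m_flt, m_all, tolerance = 0.01)
  }
})

test_that("regional summaries reduce to medians with containment", {
  ph <- generate_phantom(small_spec(noise_sd = 0, sat_beta = 0))
  dmv <- dim(ph$series$masks$lung)
  const <- list(mtt = array(5, dmv), pbf = array(240, dmv),
                pbv = array(20, dmv), valid_mask = ph$series$masks$lung)
  part <- partition_regions(ph$series$masks$lung)
  s <- summarize_regions(const, part)
  expect_true(all(s$mtt == 5))
  expect_true(all(s$pbv == 20))
  # whole-lung median lies between the regional extremes
  qm <- quantify_lung(ph$series)
  s2 <- summarize_regions(qm, part)
  whole <- s2[s2$region_id == "whole", ]
  regs <- s2[s2$region_id != "whole", ]
  for (p in c("mtt", "pbf", "pbv")) {
    expect_gte(whole[[p]], min(regs[[p]]))
    expect_lte(whole[[p]], max(regs[[p]]))
  }
})
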