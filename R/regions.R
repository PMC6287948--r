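## Equal-volume geometric partitioning of the lungs and regional summaries.
##
## Each lung is split into six regions: three vertical slabs (upper, middle,
## lower along z, apical -> basal) of near-equal in-lung voxel count, each
## halved into front (ventral) and back (dorsal) along y.  Cuts are whole
## voxel planes, so regions stay contiguous and the residual imbalance is at
## most one plane's in-lung voxel count.

#' Split a lung mask into left and right lungs
#'
#' Takes the two largest 6-connected components; the one with the smaller
#' centroid x-coordinate is the left lung (x increases left -> right).
#'
#' @param lung_mask 3D logical array with two separable lungs.
#' @return list with logical masks `left` and `right`.
#' @export
split_lungs <- function(lung_mask) {
  lab <- label_components(lung_mask)
  ncomp <- max(lab)
  if (ncomp < 2)
    stop_input("lungs not separable: mask has %d connected component(s)", ncomp)
  sizes <- tabulate(lab[lab > 0], ncomp)
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  cx <- vapply(top2, function(k) mean(arrayInd(which(lab == k),
                                               dim(lung_mask))[, 1]),
               numeric(1))
  left_lab <- top2[which.min(cx)]
  right_lab <- top2[which.max(cx)]
  list(left = lab == left_lab, right = lab == right_lab)
}

## choose the pair of cut planes minimising the maximum pairwise difference
## of the three slab sums; ties broken toward lower plane indices
best_z_cuts <- function(plane, occ) {
  total <- sum(plane)
  cum <- cumsum(plane)
  best <- NULL; best_obj <- Inf
  for (k1 in occ[1:(length(occ) - 2)]) {
    for (k2 in occ[occ > k1 & occ < occ[length(occ)]]) {
      s <- c(cum[k1], cum[k2] - cum[k1], total - cum[k2])
      obj <- max(abs(outer(s, s, `-`)))
      if (obj < best_obj) {  # strict: first (lowest-index) optimum wins
        best_obj <- obj
        best <- c(k1, k2)
      }
    }
  }
  best
}

#' Partition one lung into six equal-volume regions
#'
#' The two z cut planes are chosen to minimise the maximum pairwise
#' difference of the three slab voxel counts (upper/middle/lower); within
#' each slab the y cut plane minimises the front/back count difference.
#' Ties go to the lower plane index; every region is non-empty, and the
#' residual slab imbalance is bounded by one plane's in-lung voxel count.
#'
#' @param mask 3D logical array, one lung.
#' @return list of class `lung_partition` with `labels` (integer array,
#'   1..6 inside the mask, 0 outside) and `table` (label, vertical, depth,
#'   voxel_count).
#' @export
partition_lung <- function(mask) {
  if (!any(mask)) stop_input("lung mask is empty")
  dm <- dim(mask)
  plane_z <- apply(mask, 3, sum)
  occ_z <- which(plane_z > 0)
  if (length(occ_z) < 3)
    stop_input("lung spans only %d z-plane(s); at least 3 required",
               length(occ_z))
  cuts <- best_z_cuts(plane_z, occ_z)
  k1 <- cuts[1]; k2 <- cuts[2]

  labels <- array(0L, dm)
  verticals <- c("upper", "middle", "lower")
  slab_of_z <- function(z) if (z <= k1) 1L else if (z <= k2) 2L else 3L
  tab <- data.frame(label = 1:6,
                    vertical = rep(verticals, each = 2),
                    depth = rep(c("front", "back"), 3),
                    voxel_count = 0L,
                    stringsAsFactors = FALSE)
  for (s in 1:3) {
    zsel <- which(vapply(seq_len(dm[3]), slab_of_z, integer(1)) == s &
                    plane_z > 0)
    slab <- array(FALSE, dm)
    slab[, , zsel] <- mask[, , zsel, drop = FALSE]
    plane_y <- apply(slab, 2, sum)
    occ_y <- which(plane_y > 0)
    if (length(occ_y) < 2)
      stop_input("slab '%s' spans fewer than 2 y-planes; cannot split",
                 verticals[s])
    cum_y <- cumsum(plane_y)
    cand <- occ_y[1:(length(occ_y) - 1)]
    cy <- cand[which.min(abs(2 * cum_y[cand] - sum(plane_y)))]
    front <- slab; front[, (cy + 1):dm[2], ] <- FALSE
    back <- slab & !front
    lf <- 2L * (s - 1L) + 1L
    labels[front] <- lf
    labels[back] <- lf + 1L
    tab$voxel_count[lf] <- sum(front)
    tab$voxel_count[lf + 1L] <- sum(back)
  }
  structure(list(labels = labels, table = tab), class = "lung_partition")
}

#' Partition both lungs into the 12-region scheme
#'
#' @param lung_mask 3D logical array covering both lungs.
#' @param voxel_size_mm voxel spacing, used for region volumes.
#' @return list of class `region_partition` with `labels` (1..12; left lung
#'   1..6, right lung 7..12) and `table` (region_id, side, vertical, depth,
#'   voxel_count, volume_ml).
#' @export
partition_regions <- function(lung_mask, voxel_size_mm = c(1, 1, 1)) {
  lungs <- split_lungs(lung_mask)
  pl <- partition_lung(lungs$left)
  pr <- partition_lung(lungs$right)
  labels <- array(0L, dim(lung_mask))
  labels[lungs$left] <- pl$labels[lungs$left]
  labels[lungs$right] <- pr$labels[lungs$right] + 6L
  tab <- rbind(cbind(region_id = pl$table$label, side = "left",
                     pl$table[, c("vertical", "depth", "voxel_count")]),
               cbind(region_id = pr$table$label + 6L, side = "right",
                     pr$table[, c("vertical", "depth", "voxel_count")]))
  tab$volume_ml <- tab$voxel_count * prod(voxel_size_mm) / 1000
  rownames(tab) <- NULL
  structure(list(labels = labels, table = tab), class = "region_partition")
}

#' Exclude large-vessel voxels by PBV percentile
#'
#' Vessels are blood-filled, so their apparent PBV is far above parenchymal
#' values.  Voxels above the given in-mask PBV percentile, plus an optional
#' one-voxel dilation, are removed from the mask.
#'
#' @param maps a [perfusion_maps] object.
#' @param lung_mask 3D logical array.
#' @param pbv_percentile percentile in (50, 100); default 95.
#' @param dilate number of one-voxel dilation passes applied to the removed
#'   set (default 1).
#' @return reduced logical mask.
#' @export
exclude_vessels <- function(maps, lung_mask, pbv_percentile = 95, dilate = 1) {
  if (pbv_percentile <= 50 || pbv_percentile >= 100)
    stop_input("pbv_percentile must lie in (50, 100)")
  pbv <- maps$pbv[lung_mask]
  thr <- stats::quantile(pbv, pbv_percentile / 100, na.rm = TRUE, names = FALSE)
  removed <- array(FALSE, dim(lung_mask))
  removed[lung_mask] <- !is.na(maps$pbv[lung_mask]) & maps$pbv[lung_mask] > thr
  if (dilate > 0) for (i in seq_len(dilate)) removed <- dilate1(removed)
  out <- lung_mask & !removed
  if (!any(out)) stop_input("vessel exclusion removed every voxel")
  out
}

#' Regional and whole-lung medians of the perfusion parameters
#'
#' Medians are taken over valid voxels only (the maps' `valid_mask`
#' intersected with each region).  A region without valid voxels is kept in
#' the table with NA medians.
#'
#' @param maps a [perfusion_maps] object.
#' @param partition a [region_partition] (or compatible `labels` + `table`).
#' @return data.frame of class `region_summary`: one row per region plus a
#'   final `whole` row, with columns region_id, side, vertical, depth,
#'   n_valid, mtt, pbf, pbv.
#' @export
summarize_regions <- function(maps, partition) {
  labels <- partition$labels
  tab <- partition$table
  valid <- maps$valid_mask & labels > 0
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    sel <- labels == tab$region_id[i] & maps$valid_mask
    data.frame(region_id = as.character(tab$region_id[i]),
               side = tab$side[i], vertical = tab$vertical[i],
               depth = tab$depth[i], n_valid = sum(sel),
               mtt = stats::median(maps$mtt[sel]),
               pbf = stats::median(maps$pbf[sel]),
               pbv = stats::median(maps$pbv[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(region_id = "whole", side = "both",
                               vertical = "all", depth = "all",
                               n_valid = sum(valid),
                               mtt = stats::median(maps$mtt[valid]),
                               pbf = stats::median(maps$pbf[valid]),
                               pbv = stats::median(maps$pbv[valid]),
                               stringsAsFactors = FALSE))
  if (any(out$n_valid[out$region_id != "whole"] == 0))
    message("regions without valid voxels: ",
            paste(out$region_id[out$n_valid == 0], collapse = ", "))
  class(out) <- c("region_summary", "data.frame")
  out
}
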