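## Automatic arterial-input-function detection and extraction.
##
## In a lung first-pass acquisition the pulmonary trunk is the earliest,
## brightest large structure, so candidate voxels are scored by
## (peak enhancement) x (earliness rank of the peak) and the largest
## connected component among the top scorers is taken as the trunk.

#' Detect AIF voxels
#'
#' Every voxel in the search mask with positive peak enhancement is scored
#' by `peak * earliness`, where earliness decreases linearly from 1 (peak
#' at the arrival frame) to 1/n (peak at the last frame); earlier peaks
#' score higher at equal amplitude.  The top `top_frac` scorers (at least
#' three times `min_voxels`, so a connected component can form on coarse
#' grids) are kept and their largest 6-connected component is returned.
#'
#' @param conc a [concentration_series].
#' @param search_mask 3D logical array (whole thorax if no trunk prior).
#' @param top_frac fraction of scorers kept (default 0.01).
#' @param min_voxels minimum acceptable component size (default 10).
#' @return 3D logical mask of the selected voxels.
#' @export
detect_aif_voxels <- function(conc, search_mask, top_frac = 0.01,
                              min_voxels = 10) {
  if (is.null(search_mask) || !any(search_mask))
    stop_input("search mask is empty")
  dm <- dim(conc$data)
  idx <- which(search_mask)
  curves <- matrix(conc$data, nrow = prod(dm[1:3]))[idx, , drop = FALSE]
  post <- conc$arrival_frame:dm[4]
  peaks <- apply(curves[, post, drop = FALSE], 1, max)
  peak_fr <- post[apply(curves[, post, drop = FALSE], 1, which.max)]
  cand <- peaks > 0
  if (sum(cand) < min_voxels)
    stop_input("AIF detection failed: %d voxel(s) with positive enhancement",
               sum(cand))
  nf <- length(post)
  earliness <- (dm[4] + 1 - peak_fr[cand]) / nf
  score <- peaks[cand] * earliness
  ## keep enough candidates that the trunk can form a connected component
  ## even on coarse grids; expand the quantile if the top scorers are too
  ## scattered to percolate
  ord <- order(score, decreasing = TRUE)
  k <- max(3 * min_voxels, ceiling(top_frac * sum(cand)))
  out <- NULL
  repeat {
    top <- ord[seq_len(min(k, length(ord)))]
    sel <- array(FALSE, dm[1:3])
    sel[idx[cand][top]] <- TRUE
    lab <- label_components(sel)
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    out <- lab == best
    if (sum(out) >= min_voxels) break
    if (k >= length(ord)) {
      stop_input("AIF detection failed: largest component has %d voxel(s)",
                 sum(out))
    }
    k <- min(2 * k, length(ord))
  }
  ## grow the seed component over adjacent candidates of comparable score,
  ## so the whole vessel is captured rather than only its top scorers
  score_arr <- array(-Inf, dm[1:3])
  score_arr[idx[cand]] <- score
  repeat {
    floor_score <- 0.5 * stats::median(score_arr[out])
    frontier <- dilate1(out) & !out & score_arr >= floor_score
    if (!any(frontier)) break
    out <- out | frontier
  }
  out
}

#' Extract the arterial input function over a voxel set
#'
#' The AIF is the per-frame mean concentration over the voxel set; its
#' integral is the trapezoid over the frames from bolus arrival to the end
#' of the acquisition.
#'
#' @param conc a [concentration_series].
#' @param voxels 3D logical mask (non-empty).
#' @return object of class `aif_curve`: `times_s`, `values`, `integral`,
#'   `source_voxel_count`, `peak_frame`, `arrival_frame`.
#' @export
extract_aif <- function(conc, voxels) {
  if (!any(voxels)) stop_input("AIF voxel set is empty")
  dm <- dim(conc$data)
  idx <- which(voxels)
  curves <- matrix(conc$data, nrow = prod(dm[1:3]))[idx, , drop = FALSE]
  values <- colMeans(curves)
  w <- conc$arrival_frame:dm[4]
  integral <- trapz(conc$frame_times_s[w], values[w])
  if (!is.finite(integral) || integral <= 0)
    stop_input("AIF integral is not positive")
  structure(list(times_s = conc$frame_times_s, values = values,
                 integral = integral, source_voxel_count = length(idx),
                 peak_frame = which.max(values),
                 arrival_frame = conc$arrival_frame),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf(
    "<aif_curve> %d frames, %d source voxels, peak frame %d, integral %.4g\n",
    length(x$values), x$source_voxel_count, x$peak_frame, x$integral))
  invisible(x)
}
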