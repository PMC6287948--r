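#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral
#'
#' @param x ordinate values (strictly increasing).
#' @param y values sampled at `x`.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

## 6-connected neighbour offsets in 3D
.neigh6 <- rbind(
  c(-1L, 0L, 0L), c(1L, 0L, 0L),
  c(0L, -1L, 0L), c(0L, 1L, 0L),
  c(0L, 0L, -1L), c(0L, 0L, 1L)
)

#' Label 6-connected components of a 3D logical mask
#'
#' Flood fill over face neighbours; labels are assigned in raster order so
#' the result is independent of any prior voxel ordering.
#'
#' @param mask 3D logical array.
#' @return integer array of the same shape; 0 outside, components 1, 2, ...
#' @keywords internal
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  coords <- arrayInd(idx, dm)
  rownames(coords) <- NULL
  lin <- function(co) (co[, 3] - 1L) * dm[1] * dm[2] + (co[, 2] - 1L) * dm[1] + co[, 1]
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      co <- arrayInd(queue, dm)
      nb <- do.call(rbind, lapply(seq_len(nrow(.neigh6)), function(k) {
        sweep(co, 2, .neigh6[k, ], `+`)
      }))
      keep <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[keep, , drop = FALSE]
      nl <- lin(nb)
      nl <- unique(nl[mask[nl] & lab[nl] == 0L])
      lab[nl] <- cur
      queue <- nl
    }
  }
  lab
}

#' Dilate a 3D logical mask by one voxel (6-connectivity)
#' @keywords internal
dilate1 <- function(mask) {
  dm <- dim(mask)
  out <- mask
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  co <- arrayInd(idx, dm)
  for (k in seq_len(nrow(.neigh6))) {
    nb <- sweep(co, 2, .neigh6[k, ], `+`)
    keep <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[keep, , drop = FALSE]
    out[nb] <- TRUE
  }
  out
}

## frame timestamps: frame i covers [(i-1)*dt, i*dt) and is stamped at its
## end, so a bolus arriving at time t first appears in frame floor(t/dt)+1
frame_time_grid <- function(n_frames, dt_s) seq_len(n_frames) * dt_s
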