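## Synthetic 4D DCE-MRI lung phantoms with known perfusion ground truth.
##
## Axis convention (fixed throughout the package):
##   x = left-right, y = ventral -> dorsal (increasing), z = apical -> basal.
## All times are seconds, concentrations are relative enhancement units in
## which the first-pass arterial peak is O(1).

#' Gamma-variate bolus parameters
#'
#' Shape of the first-pass arterial bolus,
#' `C(t) = a * ((t-t0)/tp)^alpha * exp(alpha * (1 - (t-t0)/tp))` for `t > t0`,
#' normalised so the peak value is `amplitude` at `t0 + time_to_peak_s`.
#' An optional recirculation bump reuses the same shape, delayed and
#' broadened.
#'
#' @param amplitude peak concentration of the first pass (relative units).
#' @param shape gamma-variate shape exponent (dimensionless, > 0).
#' @param time_to_peak_s time from bolus arrival to peak, seconds.
#' @param recirc_amplitude peak of the recirculation bump (0 disables it).
#' @param recirc_delay_s delay of the recirculation bump after first-pass
#'   arrival, seconds.
#' @param recirc_broadening multiplicative broadening of the recirculation
#'   time-to-peak.
#' @return an object of class `aif_params`.
#' @export
aif_params <- function(amplitude = 3, shape = 3, time_to_peak_s = 4,
                       recirc_amplitude = 0, recirc_delay_s = 12,
                       recirc_broadening = 2) {
  if (amplitude <= 0 || shape <= 0 || time_to_peak_s <= 0)
    stop_input("gamma-variate parameters must be strictly positive")
  if (recirc_amplitude < 0)
    stop_input("recirc_amplitude must be >= 0")
  structure(list(amplitude = amplitude, shape = shape,
                 time_to_peak_s = time_to_peak_s,
                 recirc_amplitude = recirc_amplitude,
                 recirc_delay_s = recirc_delay_s,
                 recirc_broadening = recirc_broadening),
            class = "aif_params")
}

gamma_variate <- function(t, onset_s, amplitude, shape, time_to_peak_s) {
  x <- pmax(t - onset_s, 0) / time_to_peak_s
  amplitude * x^shape * exp(shape * (1 - x))
}

#' Default regional ground truth
#'
#' Piecewise-constant truth for the 12 lung regions (2 sides x 3 vertical
#' slabs x front/back).  Dorsal (back) regions receive higher PBV and PBF
#' than ventral (front) ones, emulating the gravity-dependent perfusion
#' gradient of the supine lung; MTT is 5 s throughout (MTT = 60*PBV/PBF).
#'
#' @param pbv_front,pbv_back PBV in ml/100ml for ventral and dorsal regions.
#' @param mtt_s mean transit time in seconds (PBF is derived).
#' @return data.frame with columns side, vertical, depth, pbf, pbv.
#' @export
default_region_truth <- function(pbv_front = 15, pbv_back = 20, mtt_s = 5) {
  grid <- expand.grid(side = c("left", "right"),
                      vertical = c("upper", "middle", "lower"),
                      depth = c("front", "back"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$pbv <- ifelse(grid$depth == "back", pbv_back, pbv_front)
  grid$pbf <- 60 * grid$pbv / mtt_s
  grid
}

#' Phantom specification
#'
#' Full description of a synthetic acquisition: geometry, frame timing,
#' bolus, regional ground truth, signal model and noise.  Defaults follow
#' a clinical lung first-pass protocol: 24 volumes at 1.47 s/volume with
#' injection 5 s after scan start.
#'
#' @param grid_shape voxel counts (x, y, z).
#' @param voxel_size_mm voxel spacing per axis, millimetres.
#' @param n_frames number of dynamic frames.
#' @param dt_s frame interval, seconds.
#' @param injection_delay_s seconds from scan start to injection.
#' @param arrival_delay_s transit delay from injection to the pulmonary
#'   trunk, seconds.
#' @param lung_delay_s additional transit delay trunk -> lung tissue,
#'   seconds (applied to the tissue input).
#' @param aif_params an [aif_params()] object.
#' @param region_truth data.frame as returned by [default_region_truth()].
#' @param s0 baseline signal level (arbitrary units).
#' @param sat_beta saturation strength of the signal-enhancement
#'   nonlinearity, per unit concentration (0 = linear).
#' @param residual_fraction fraction of one injection's fully mixed
#'   steady-state concentration still circulating at scan start, in [0, 1].
#' @param steady_state_frac fully mixed steady-state concentration of one
#'   dose as a fraction of the first-pass arterial peak.  The default 1/80
#'   reflects the one-to-two orders of magnitude dilution between a compact
#'   first-pass bolus and its post-distribution equilibrium.
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param vessel_fraction fraction of lung voxels replaced by large-vessel
#'   voxels (5x regional PBV and PBF).
#' @param gradient_mode if TRUE, overlay a smooth ventral->dorsal gain on
#'   the regional truth (0.85 to 1.15 across the lung depth) instead of
#'   keeping regions internally flat.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16),
                         voxel_size_mm = c(6, 6, 10),
                         n_frames = 24, dt_s = 1.47,
                         injection_delay_s = 5, arrival_delay_s = 3,
                         lung_delay_s = 0,
                         aif_params = lungperf::aif_params(),
                         region_truth = default_region_truth(),
                         s0 = 100, sat_beta = 0.3,
                         residual_fraction = 0,
                         steady_state_frac = 1 / 80,
                         noise_sd = 2,
                         vessel_fraction = 0,
                         gradient_mode = FALSE,
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size_mm = voxel_size_mm,
                         n_frames = as.integer(n_frames), dt_s = dt_s,
                         injection_delay_s = injection_delay_s,
                         arrival_delay_s = arrival_delay_s,
                         lung_delay_s = lung_delay_s,
                         aif_params = aif_params,
                         region_truth = region_truth,
                         s0 = s0, sat_beta = sat_beta,
                         residual_fraction = residual_fraction,
                         steady_state_frac = steady_state_frac,
                         noise_sd = noise_sd,
                         vessel_fraction = vessel_fraction,
                         gradient_mode = gradient_mode,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3 || any(grid_shape < 8))
      stop_input("grid_shape must be 3 axes of at least 8 voxels")
    if (any(voxel_size_mm <= 0) || dt_s <= 0 || n_frames < 4)
      stop_input("voxel size, dt and frame count must be positive")
    if (s0 <= 0 || sat_beta < 0 || noise_sd < 0)
      stop_input("s0 must be > 0; sat_beta and noise_sd must be >= 0")
    if (residual_fraction < 0 || residual_fraction > 1)
      stop_input("residual_fraction must lie in [0, 1]")
    rt <- region_truth
    if (!all(c("side", "vertical", "depth", "pbf", "pbv") %in% names(rt)))
      stop_input("region_truth must have side, vertical, depth, pbf, pbv")
    if (any(rt$pbf <= 0) || any(rt$pbv <= 0))
      stop_input("regional PBF and PBV must be strictly positive")
    mtt <- 60 * rt$pbv / rt$pbf
    if (any(mtt < dt_s))
      stop_input("implied MTT (60*PBV/PBF) below the frame interval %.3g s",
                 dt_s)
    span <- n_frames * dt_s
    peak_t <- injection_delay_s + arrival_delay_s + aif_params$time_to_peak_s
    if (peak_t >= span)
      stop_input("bolus peak (%.1f s) not captured within the %.1f s scan",
                 peak_t, span)
  })
  invisible(spec)
}

#' Arterial input concentration curve
#'
#' First-pass gamma-variate (plus optional recirculation bump) on top of a
#' constant residual baseline from a prior injection.  Elimination over the
#' <= 40 s acquisition is negligible, so the residual term is constant.
#'
#' @param params an [aif_params()] object.
#' @param frame_times_s sampling times, seconds (strictly increasing).
#' @param injection_delay_s seconds from scan start to injection.
#' @param arrival_delay_s transit delay injection -> sampled vessel.
#' @param residual_fraction fraction of `steady_state_conc` still present.
#' @param steady_state_conc fully mixed concentration of one dose.
#' @return list with `values` (total concentration), `first_pass`,
#'   `residual` (scalar baseline) and `onset_s`.
#' @export
generate_aif <- function(params, frame_times_s, injection_delay_s = 5,
                         arrival_delay_s = 3, residual_fraction = 0,
                         steady_state_conc = params$amplitude / 80) {
  stopifnot(inherits(params, "aif_params"))
  if (any(diff(frame_times_s) <= 0))
    stop_input("frame_times_s must be strictly increasing")
  onset <- injection_delay_s + arrival_delay_s
  peak_t <- onset + params$time_to_peak_s
  if (peak_t > max(frame_times_s))
    stop_input("bolus peak at %.1f s is after the last frame (%.1f s)",
               peak_t, max(frame_times_s))
  fp <- gamma_variate(frame_times_s, onset, params$amplitude,
                      params$shape, params$time_to_peak_s)
  if (params$recirc_amplitude > 0) {
    fp <- fp + gamma_variate(frame_times_s, onset + params$recirc_delay_s,
                             params$recirc_amplitude, params$shape,
                             params$time_to_peak_s * params$recirc_broadening)
  }
  residual <- residual_fraction * steady_state_conc
  list(values = fp + residual, first_pass = fp, residual = residual,
       onset_s = onset)
}

#' Tissue concentration from ground-truth perfusion
#'
#' Indicator-dilution forward model: the incremental tissue concentration is
#' the discrete convolution of the first-pass arterial input with the
#' flow-scaled residue `f * R`, where `f = pbf/6000` per second and `R` is
#' the area-exact geometric kernel `R[k] = (1 - dt/MTT)^k`.  This kernel has
#' height exactly 1 and rectangle-rule area exactly MTT, so peak-based PBF
#' and ratio-based PBV are simultaneously exact on noiseless data; it
#' requires MTT >= dt (enforced).  A constant residual blood concentration
#' contributes `residual_conc * pbv/100` to the tissue baseline.
#'
#' @param aif_first_pass first-pass arterial concentration per frame
#'   (residual baseline excluded).
#' @param pbf pulmonary blood flow, ml/min/100ml.
#' @param pbv pulmonary blood volume, ml/100ml.
#' @param dt_s frame interval, seconds.
#' @param residual_conc residual blood concentration (same units as the AIF).
#' @return tissue concentration per frame (baseline included).
#' @export
tissue_curve_from_truth <- function(aif_first_pass, pbf, pbv, dt_s,
                                    residual_conc = 0) {
  mtt <- 60 * pbv / pbf
  if (mtt < dt_s)
    stop_input("implied MTT %.3g s is below the frame interval %.3g s",
               mtt, dt_s)
  n <- length(aif_first_pass)
  f <- pbf / 6000  # 1/s
  R <- (1 - dt_s / mtt)^(0:(n - 1))
  ct <- f * dt_s * stats::convolve(aif_first_pass, rev(R), type = "open")[1:n]
  ct[ct < 0] <- 0  # FFT round-off; the model is non-negative
  ct + residual_conc * pbv / 100
}

#' Signal from concentration (saturating enhancement model)
#'
#' `S = s0 * (1 + c / (1 + sat_beta * c))`: monotone increasing, concave,
#' linear (`S = s0 * (1 + c)`) when `sat_beta = 0`, saturating towards
#' `s0 * (1 + 1/sat_beta)`.  The marginal enhancement of a concentration
#' increment decreases with the baseline concentration when `sat_beta > 0`,
#' which is what dampens high (arterial) signals more than dilute (tissue)
#' signals.
#'
#' @param c concentration (>= 0), any shape.
#' @param s0 baseline signal (> 0).
#' @param sat_beta saturation strength (>= 0).
#' @return signal, same shape as `c`.
#' @export
signal_from_concentration <- function(c, s0, sat_beta = 0) {
  if (any(c < 0)) stop_input("concentration must be non-negative")
  if (s0 <= 0 || sat_beta < 0) stop_input("s0 > 0 and sat_beta >= 0 required")
  s0 * (1 + c / (1 + sat_beta * c))
}

#' Invert the saturating enhancement map
#'
#' Inverse of [signal_from_concentration()] in enhancement space:
#' given relative enhancement `e = (S - s0)/s0`, returns
#' `c = e / (1 - sat_beta * e)`.  Enhancements at or above the saturation
#' asymptote `1/sat_beta` are clamped just below it.
#'
#' @param e relative enhancement.
#' @param sat_beta saturation strength (>= 0).
#' @keywords internal
concentration_from_enhancement <- function(e, sat_beta) {
  if (sat_beta == 0) return(e)
  e <- pmin(e, 0.999 / sat_beta)
  e / (1 - sat_beta * e)
}

## ---- phantom geometry ------------------------------------------------------

phantom_masks <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  lung <- array(FALSE, grid_shape)
  trunk <- array(FALSE, grid_shape)
  ## two lung boxes separated by a mediastinal gap
  xw <- max(3L, round(nx * 0.34))
  xl <- 2L:(1L + xw)
  xr <- (nx - xw):(nx - 1L)
  yy <- max(2L, round(ny * 0.12)):min(ny - 1L, round(ny * 0.92))
  zz <- max(2L, round(nz * 0.1)):min(nz - 1L, round(nz * 0.95))
  lung[xl, yy, zz] <- TRUE
  lung[xr, yy, zz] <- TRUE
  ## pulmonary trunk: small ventral-central box in the mediastinum
  xt <- (max(xl) + 1L):(min(xr) - 1L)
  yt <- min(yy):(min(yy) + max(2L, round(ny * 0.18)))
  zt <- min(zz):(min(zz) + max(2L, round(nz * 0.35)))
  trunk[xt, yt, zt] <- TRUE
  list(lung = lung, trunk = trunk)
}

#' Generate a seeded 4D perfusion phantom
#'
#' Composes the arterial input, per-region tissue kinetics, the saturating
#' signal model and additive Gaussian noise (clipped at zero) into a
#' [dynamic_series] plus its ground truth.  Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `lung_phantom` with elements `series`
#'   (class `dynamic_series`) and `truth` (regional table, truth maps,
#'   true AIF, arrival frame).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  n <- spec$n_frames
  times <- frame_time_grid(n, spec$dt_s)
  masks <- phantom_masks(dm)
  lungs <- split_lungs(masks$lung)
  regions <- array(0L, dm)
  part_l <- partition_lung(lungs$left)
  part_r <- partition_lung(lungs$right)
  regions[lungs$left] <- part_l$labels[lungs$left]
  regions[lungs$right] <- part_r$labels[lungs$right] + 6L
  region_table <- rbind(cbind(side = "left", part_l$table),
                        cbind(side = "right", part_r$table))
  region_table$region_id <- c(part_l$table$label, part_r$table$label + 6L)

  ## attach ground truth to each region
  rt <- spec$region_truth
  key <- paste(rt$side, rt$vertical, rt$depth)
  want <- paste(region_table$side, region_table$vertical, region_table$depth)
  hit <- match(want, key)
  if (anyNA(hit))
    stop_input("region_truth is missing regions: %s",
               paste(want[is.na(hit)], collapse = ", "))
  region_table$pbf <- rt$pbf[hit]
  region_table$pbv <- rt$pbv[hit]
  region_table$mtt <- 60 * region_table$pbv / region_table$pbf

  steady_state <- spec$aif_params$amplitude * spec$steady_state_frac
  aif <- generate_aif(spec$aif_params, times, spec$injection_delay_s,
                      spec$arrival_delay_s, spec$residual_fraction,
                      steady_state)
  tissue_input <- if (spec$lung_delay_s > 0) {
    generate_aif(spec$aif_params, times, spec$injection_delay_s,
                 spec$arrival_delay_s + spec$lung_delay_s,
                 spec$residual_fraction, steady_state)$first_pass
  } else aif$first_pass
  arrival_frame <- which(aif$first_pass > 0)[1]

  ## per-voxel truth maps (piecewise constant per region, optionally with a
  ## smooth ventral->dorsal gain)
  pbf_map <- array(NA_real_, dm)
  pbv_map <- array(NA_real_, dm)
  for (i in seq_len(nrow(region_table))) {
    sel <- regions == region_table$region_id[i]
    pbf_map[sel] <- region_table$pbf[i]
    pbv_map[sel] <- region_table$pbv[i]
  }
  if (spec$gradient_mode) {
    ys <- which(apply(masks$lung, 2, any))
    gain <- array(1, dm)
    gvals <- seq(0.85, 1.15, length.out = length(ys))
    for (j in seq_along(ys)) gain[, ys[j], ] <- gvals[j]
    pbf_map <- pbf_map * gain
    pbv_map <- pbv_map * gain
  }

  ## vessel voxels: high-PBV blood-filled voxels inside the lung
  vessels <- array(FALSE, dm)
  if (spec$vessel_fraction > 0) {
    lung_idx <- which(masks$lung)
    nv <- max(1L, round(spec$vessel_fraction * length(lung_idx)))
    pick <- withr::with_seed(spec$seed + 7L,
                             sample(lung_idx, nv))
    vessels[pick] <- TRUE
    pbf_map[pick] <- pbf_map[pick] * 5
    pbv_map[pick] <- pbv_map[pick] * 5
  }
  mtt_map <- 60 * pbv_map / pbf_map

  ## compose the clean signal: group voxels by unique (pbf, pbv)
  data <- array(spec$s0, c(dm, n))  # background: unenhanced baseline signal
  trunk_sig <- signal_from_concentration(aif$values, spec$s0, spec$sat_beta)
  trunk_idx <- which(masks$trunk)
  for (fr in seq_len(n)) {
    vol <- data[, , , fr]
    vol[trunk_idx] <- trunk_sig[fr]
    data[, , , fr] <- vol
  }
  lung_idx <- which(masks$lung)
  pairs <- paste(pbf_map[lung_idx], pbv_map[lung_idx])
  for (grp in split(lung_idx, pairs)) {
    pbf <- pbf_map[grp[1]]; pbv <- pbv_map[grp[1]]
    ct <- tissue_curve_from_truth(tissue_input, pbf, pbv, spec$dt_s,
                                  residual_conc = aif$residual)
    sig <- signal_from_concentration(ct, spec$s0, spec$sat_beta)
    for (fr in seq_len(n)) {
      vol <- data[, , , fr]
      vol[grp] <- sig[fr]
      data[, , , fr] <- vol
    }
  }

  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
                              array(stats::rnorm(prod(dm) * n, 0, spec$noise_sd),
                                    c(dm, n)))
    data <- pmax(data + noise, 0)
  }

  series <- dynamic_series(data, dt_s = spec$dt_s,
                           voxel_size_mm = spec$voxel_size_mm,
                           masks = list(lung = masks$lung,
                                        trunk = masks$trunk,
                                        regions = regions,
                                        vessels = vessels))
  truth <- structure(list(region_table = region_table,
                          maps = list(mtt = mtt_map, pbf = pbf_map,
                                      pbv = pbv_map),
                          aif = aif$values, aif_first_pass = aif$first_pass,
                          residual_conc = aif$residual,
                          steady_state_conc = steady_state,
                          arrival_frame = arrival_frame,
                          times_s = times),
                     class = "ground_truth")
  structure(list(series = series, truth = truth, spec = spec),
            class = "lung_phantom")
}

#' Dynamic series container
#'
#' A 4D signal volume with uniform frame timing and optional masks.
#'
#' @param data 4D array (x, y, z, t), non-negative.
#' @param dt_s frame interval, seconds.
#' @param voxel_size_mm voxel spacing per axis.
#' @param masks optional named list (lung, trunk, regions, vessels).
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, dt_s, voxel_size_mm = c(1, 1, 1),
                           masks = list()) {
  if (length(dim(data)) != 4)
    stop_input("data must be a 4D (x, y, z, t) array")
  if (any(data < 0)) stop_input("signal must be non-negative")
  if (dt_s <= 0) stop_input("dt_s must be positive")
  structure(list(data = data, dt_s = dt_s,
                 voxel_size_mm = voxel_size_mm,
                 frame_times_s = frame_time_grid(dim(data)[4], dt_s),
                 masks = masks),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d frames @ %.3g s\n",
              dm[1], dm[2], dm[3], dm[4], x$dt_s))
  if (length(x$masks))
    cat("  masks:", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lung_phantom <- function(x, ...) {
  print(x$series)
  cat(sprintf("  truth: %d regions, arrival frame %d, residual %.4g\n",
              nrow(x$truth$region_table), x$truth$arrival_frame,
              x$truth$residual_conc))
  invisible(x)
}
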