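## Signal -> concentration conversion, bolus-arrival detection and
## contrast-agent elimination kinetics.

#' Detect the bolus arrival frame from the pulmonary-trunk signal
#'
#' The trunk-mean signal curve is scanned with an expanding baseline: the
#' arrival is the first frame whose value exceeds
#' `mean(baseline) + k * sd(baseline)` sustained for `persistence`
#' consecutive frames, where the baseline is all frames before that point.
#' Because the baseline SD is estimated from very few frames, the threshold
#' additionally never drops below `peak_frac` of the curve's total
#' enhancement (peak minus baseline); this peak-referenced floor prevents
#' heavy-tailed single-frame noise excursions from triggering one frame
#' early.  At least three baseline frames are required.
#'
#' @param series a [dynamic_series].
#' @param trunk_mask 3D logical array (defaults to `series$masks$trunk`).
#' @param k threshold in baseline SDs (default 3).
#' @param persistence consecutive supra-threshold frames required (default 2).
#' @param peak_frac floor of the detection threshold as a fraction of the
#'   total enhancement (default 0.05).
#' @return integer frame index (1-based) of the first enhanced frame; the
#'   number of unenhanced frames is this index minus one.
#' @export
detect_bolus_arrival <- function(series, trunk_mask = NULL, k = 3,
                                 persistence = 2, peak_frac = 0.05) {
  trunk_mask <- trunk_mask %||% series$masks$trunk
  if (is.null(trunk_mask) || !any(trunk_mask))
    stop_input("trunk mask is empty")
  n <- dim(series$data)[4]
  if (n < 4) stop_input("need at least 4 frames")
  m <- vapply(seq_len(n), function(fr) {
    vol <- series$data[, , , fr]
    mean(vol[trunk_mask])
  }, numeric(1))
  ## a jump inside the first three frames means the baseline itself is
  ## contaminated
  bl3 <- m[1:3]
  if (diff(range(bl3)) > 0.5 * (max(m) - min(bl3)) && diff(range(m)) > 0)
    stop_input("insufficient baseline: enhancement within the first 3 frames")
  for (fr in 4:(n - persistence + 1)) {
    bl <- m[1:(fr - 1)]
    thr <- mean(bl) + max(k * stats::sd(bl),
                          peak_frac * (max(m) - mean(bl)))
    if (all(m[fr:(fr + persistence - 1)] > thr)) return(fr)
  }
  stop_input("no bolus detected")
}

#' Convert a dynamic signal series to relative concentration
#'
#' The per-voxel baseline `S0` is the mean over the pre-arrival frames.
#' Mode `"linear"` (the default, mirroring conventional evaluation
#' software) returns relative enhancement `c = (S - S0)/S0`; this is the
#' conversion whose interaction with signal saturation produces the
#' residual-contrast bias studied by this package.  Mode `"corrected"`
#' inverts the saturating enhancement map for a known `sat_beta` and then
#' subtracts the per-voxel pre-arrival concentration, so a constant
#' residual baseline is removed in concentration space.  If a true
#' contrast-free baseline `s0_ref` is available (e.g. from the first
#' injection of the day), it is used as the reference; otherwise the
#' measured (possibly residual-inflated) baseline is used.
#'
#' Noise can make concentrations negative; values are deliberately not
#' clipped.
#'
#' @param series a [dynamic_series].
#' @param arrival_frame 1-based first enhanced frame (>= 4).
#' @param mode `"linear"` or `"corrected"`.
#' @param sat_beta saturation strength, required for `"corrected"`.
#' @param s0_ref optional contrast-free baseline (scalar or 3D array).
#' @param mask optional 3D logical array restricting the baseline-positivity
#'   check (default: all voxels).
#' @return list of class `concentration_series`: `data` (4D), `baseline_map`,
#'   `arrival_frame`, `dt_s`, `frame_times_s`, `mode`.
#' @export
signal_to_concentration <- function(series, arrival_frame,
                                    mode = c("linear", "corrected"),
                                    sat_beta = NULL, s0_ref = NULL,
                                    mask = NULL) {
  mode <- match.arg(mode)
  dm <- dim(series$data)
  if (arrival_frame < 4)
    stop_input("insufficient baseline: arrival frame %d < 4", arrival_frame)
  pre <- seq_len(arrival_frame - 1)
  baseline <- apply(series$data[, , , pre, drop = FALSE], 1:3, mean)
  check <- if (is.null(mask)) baseline else baseline[mask]
  if (any(check <= 0))
    stop_input("non-positive baseline signal inside the mask")
  conc <- array(0, dm)
  if (mode == "linear") {
    for (fr in seq_len(dm[4]))
      conc[, , , fr] <- (series$data[, , , fr] - baseline) / baseline
  } else {
    if (is.null(sat_beta))
      stop_input("mode 'corrected' requires sat_beta")
    ref <- if (is.null(s0_ref)) baseline else
      if (length(s0_ref) == 1) array(s0_ref, dm[1:3]) else s0_ref
    if (any((if (is.null(mask)) ref else ref[mask]) <= 0))
      stop_input("non-positive reference baseline")
    for (fr in seq_len(dm[4])) {
      e <- (series$data[, , , fr] - ref) / ref
      conc[, , , fr] <- concentration_from_enhancement(e, sat_beta)
    }
    ## remove the pre-arrival concentration (residual estimate) per voxel
    pre_conc <- apply(conc[, , , pre, drop = FALSE], 1:3, mean)
    for (fr in seq_len(dm[4]))
      conc[, , , fr] <- conc[, , , fr] - pre_conc
  }
  structure(list(data = conc, baseline_map = baseline,
                 arrival_frame = as.integer(arrival_frame),
                 dt_s = series$dt_s,
                 frame_times_s = series$frame_times_s, mode = mode),
            class = "concentration_series")
}

#' Remaining fraction of circulating contrast agent
#'
#' First-order elimination: `0.5^(elapsed_h / half_life_h)`.
#'
#' @param half_life_h serum elimination half-life, hours (> 0).
#' @param elapsed_h time since injection, hours (>= 0).
#' @return remaining fraction in (0, 1].
#' @export
residual_fraction <- function(half_life_h, elapsed_h) {
  if (half_life_h <= 0) stop_input("half_life_h must be positive")
  if (any(elapsed_h < 0)) stop_input("elapsed_h must be non-negative")
  0.5^(elapsed_h / half_life_h)
}
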