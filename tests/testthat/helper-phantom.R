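# Small phantoms keep the unit tests fast; acceptance tests use the
# full-size default grid.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(16, 16, 8), voxel_size_mm = c(8, 8, 15), ...)
}

# regional relative recovery errors of a quantified phantom, using the
# generator's own region labels
region_recovery_errors <- function(phantom, maps) {
  part <- list(labels = phantom$series$masks$regions,
               table = phantom$truth$region_table[, c("region_id", "side",
                                                      "vertical", "depth")])
  s <- summarize_regions(maps, part)
  s <- s[s$region_id != "whole", ]
  tr <- phantom$truth$region_table
  i <- match(s$region_id, as.character(tr$region_id))
  data.frame(region_id = s$region_id,
             mtt = s$mtt / tr$mtt[i] - 1,
             pbf = s$pbf / tr$pbf[i] - 1,
             pbv = s$pbv / tr$pbv[i] - 1)
}

# concentration_series built directly from an array, for synthetic
# detection fixtures
conc_from_array <- function(data, dt_s = 1.47, arrival_frame = 4) {
  structure(list(data = data,
                 baseline_map = array(1, dim(data)[1:3]),
                 arrival_frame = as.integer(arrival_frame), dt_s = dt_s,
                 frame_times_s = seq_len(dim(data)[4]) * dt_s,
                 mode = "linear"),
            class = "concentration_series")
}

# whole-lung median estimates for one residual level / conversion mode
whole_lung_estimates <- function(spec, mode = "linear") {
  ph <- generate_phantom(spec)
  cfg <- if (mode == "linear") quant_config() else
    quant_config("corrected", sat_beta = spec$sat_beta, s0_ref = spec$s0)
  maps <- quantify_lung(ph$series, config = cfg)
  v <- maps$valid_mask
  list(pbv = median(maps$pbv[v]), pbf = median(maps$pbf[v]),
       mtt = median(maps$mtt[v]), aif = maps$aif$integral, maps = maps,
       phantom = ph)
}
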