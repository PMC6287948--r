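## NIfTI-1 and table I/O plus provenance manifests.  Frame timing is carried
## through explicit configuration rather than the NIfTI time header, which is
## unreliable across tools.

#' Read a 4D dynamic series from NIfTI
#'
#' @param path NIfTI-1 file with 4 dimensions.
#' @param dt_s frame interval in seconds (required; the time header is not
#'   trusted).
#' @return a [dynamic_series].
#' @export
read_series <- function(path, dt_s) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4)
    stop_input("'%s' has %d dimensions; a 4D (x, y, z, t) series is required",
               path, length(dim(a)))
  if (missing(dt_s) || is.null(dt_s) || !is.finite(dt_s) || dt_s <= 0)
    stop_input("a positive frame interval dt_s must be supplied")
  pix <- RNifti::pixdim(img)
  dynamic_series(a, dt_s = dt_s, voxel_size_mm = pix[1:3])
}

#' Write a dynamic series to NIfTI
#'
#' @param series a [dynamic_series].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$dt_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file whose values are all 0 or 1.
#' @return 3D logical array.
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3)
    stop_input("'%s' is not a 3D volume", path)
  if (!all(a %in% c(0, 1)))
    stop_input("'%s' contains labels outside {0, 1}", path)
  array(a == 1, dim(a))
}

#' Write a 3D volume (mask or parameter map) to NIfTI
#'
#' Logical/integer volumes are written as uint8, numeric maps as float32.
#'
#' @param vol 3D array.
#' @param path output path.
#' @param voxel_size_mm voxel spacing.
#' @export
write_volume <- function(vol, path, voxel_size_mm = c(1, 1, 1)) {
  dt <- if (is.logical(vol) || is.integer(vol)) "uint8" else "float"
  storage.mode(vol) <- if (dt == "uint8") "integer" else "double"
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write pipeline outputs with a checksummed manifest
#'
#' Writes NIfTI parameter maps, a regional summary CSV, arbitrary extra
#' tables (CSV), a provenance JSON (configuration, seed, package version)
#' and a manifest listing every written file with its MD5 checksum.
#' Summaries with missing regions keep their rows with NA values rather
#' than dropping them.
#'
#' @param out_dir output directory (created if needed).
#' @param maps optional [perfusion_maps].
#' @param summary optional [summarize_regions()] data.frame.
#' @param tables named list of additional data.frames.
#' @param provenance list stored as provenance JSON (seed, config, ...).
#' @param voxel_size_mm spacing for the NIfTI maps.
#' @return path of the manifest JSON, invisibly.
#' @export
write_outputs <- function(out_dir, maps = NULL, summary = NULL,
                          tables = list(), provenance = list(),
                          voxel_size_mm = c(1, 1, 1)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(maps)) {
    for (p in c("mtt", "pbf", "pbv")) {
      f <- file.path(out_dir, paste0(p, ".nii.gz"))
      write_volume(maps[[p]], f, voxel_size_mm)
      written <- c(written, f)
    }
    f <- file.path(out_dir, "valid_mask.nii.gz")
    write_volume(maps$valid_mask, f, voxel_size_mm)
    written <- c(written, f)
  }
  if (!is.null(summary)) {
    f <- file.path(out_dir, "region_summary.csv")
    utils::write.csv(summary, f, row.names = FALSE, na = "NA")
    written <- c(written, f)
  }
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, na = "NA")
    written <- c(written, f)
  }
  provenance$package_version <-
    as.character(utils::packageVersion("lungperf"))
  f <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(provenance, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  written <- c(written, f)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Serialise a phantom spec to YAML
#'
#' The regional truth table is stored as a list of rows; [read_phantom_spec()]
#' restores a validated [phantom_spec()].
#'
#' @param spec a [phantom_spec()].
#' @param path output YAML path.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$aif_params <- unclass(x$aif_params)
  x$region_truth <- lapply(seq_len(nrow(spec$region_truth)),
                           function(i) as.list(spec$region_truth[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  rt <- do.call(rbind, lapply(x$region_truth, as.data.frame))
  ap <- do.call(aif_params, x$aif_params)
  x$region_truth <- NULL
  x$aif_params <- NULL
  do.call(phantom_spec, c(x, list(region_truth = rt, aif_params = ap)))
}
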