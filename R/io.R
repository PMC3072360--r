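#' Read a silhouette movie from disk
#'
#' Accepts a multi-page TIFF file or a directory of PNG frames (lexicographic
#' filename order defines time). Each page/file is passed through
#' [extract_mask()], so grayscale stacks are thresholded and binary stacks
#' (0/1 or 0/255) pass through cleanup.
#'
#' @param path TIFF file or directory of PNGs.
#' @param dt sampling interval in seconds.
#' @param threshold_policy forwarded to [extract_mask()].
#' @return list of [binary_mask()] objects.
#' @export
read_mask_stack <- function(path, dt = 2, threshold_policy = "auto") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) md_error("morphodyn_io", "no PNG files in directory")
    imgs <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3) im <- im[, , 1]
      im
    })
  } else {
    if (!file.exists(path)) md_error("morphodyn_io", paste("no such file:", path))
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    imgs <- lapply(imgs, function(im) if (length(dim(im)) == 3) im[, , 1] else im)
  }
  lapply(seq_along(imgs), function(i)
    extract_mask(imgs[[i]], threshold_policy = threshold_policy,
                 frame_index = i, timestamp = (i - 1) * dt))
}

#' Write per-frame silhouette metrics as CSV
#'
#' @param series an [r_series()] carrying a `"metrics"` attribute (from
#'   [roundness_series()] or [simulate_roundness_series()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_metrics <- function(series, path) {
  met <- attr(series, "metrics")
  if (is.null(met)) md_error("morphodyn_io", "series has no per-frame metrics")
  utils::write.csv(met, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
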