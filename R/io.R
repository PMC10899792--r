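#' Write a synthetic fixture to disk
#'
#' Saves an image stack as a channel-interleaved multi-page 16-bit TIFF
#' (frame 1 DNA, frame 1 RNAP, frame 2 DNA, ...), acquisition metadata as a
#' JSON sidecar, and the ground-truth ledgers as CSV.  A round-trip through
#' [read_fixture()] reproduces the pixel arrays exactly.
#'
#' @param stack an `image_stack`.
#' @param truth the matching `ground_truth` (or `NULL` to skip the ledgers).
#' @param path output directory (created, recursively, if missing).
#' @param overwrite logical; refuse to overwrite an existing fixture unless
#'   `TRUE`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(stack, truth, path, overwrite = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  tif <- file.path(path, "stack.tif")
  if (file.exists(tif) && !overwrite)
    stop("fixture already exists at ", path, "; use overwrite = TRUE")
  chans <- names(stack$channels)
  pages <- vector("list", stack$n_frames * length(chans))
  k <- 1L
  for (f in seq_len(stack$n_frames)) {
    for (ch in chans) {
      pages[[k]] <- stack$channels[[ch]][, , f] / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  meta <- list(
    pixel_size_nm = stack$pixel_size_nm,
    frame_interval_s = stack$frame_interval_s,
    exposure_s = stack$exposure_s, psf_fwhm_nm = stack$psf_fwhm_nm,
    n_frames = stack$n_frames, width_px = stack$width_px,
    height_px = stack$height_px, total_bp = stack$total_bp,
    tether_px = stack$tether_px, channels = chans, noise = stack$noise
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    utils::write.csv(truth$objects, file.path(path, "truth_objects.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$frames, file.path(path, "truth_frames.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return a list with the reconstructed `image_stack` and, when present, the
#'   truth ledgers (`objects`, `frames` data frames).
#' @export
read_fixture <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(path, "stack.tif"), all = TRUE,
                          as.is = TRUE)
  chans <- meta$channels
  nch <- length(chans)
  arrs <- lapply(seq_len(nch), function(ci) {
    a <- array(0, dim = c(meta$height_px, meta$width_px, meta$n_frames))
    for (f in seq_len(meta$n_frames)) a[, , f] <- pages[[(f - 1) * nch + ci]]
    a
  })
  names(arrs) <- chans
  stack <- list(channels = arrs, pixel_size_nm = meta$pixel_size_nm,
                frame_interval_s = meta$frame_interval_s,
                exposure_s = meta$exposure_s, psf_fwhm_nm = meta$psf_fwhm_nm,
                n_frames = meta$n_frames, width_px = meta$width_px,
                height_px = meta$height_px, total_bp = meta$total_bp,
                tether_px = meta$tether_px, n_saturated = 0L,
                noise = isTRUE(meta$noise), preprocessed = FALSE)
  class(stack) <- "image_stack"
  out <- list(stack = stack)
  f_ob <- file.path(path, "truth_objects.csv")
  if (file.exists(f_ob)) {
    out$objects <- utils::read.csv(f_ob)
    out$frames <- utils::read.csv(file.path(path, "truth_frames.csv"))
  }
  out
}
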