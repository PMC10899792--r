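#' Run the full detection pipeline on one molecule
#'
#' Preprocessing (median filter + white top-hat), kymograph construction for
#' both channels, DNA-end localization by peak peeling, punctum detection,
#' track linking, and conversion of positions and excess intensities to
#' genomic coordinates and base-pair sizes.  The RNAP channel is reduced to
#' at most one punctum per frame (highest excess wins).
#'
#' @param stack an `image_stack` (raw; preprocessing is applied here).
#' @param total_bp construct length in bp (defaults to stack metadata).
#' @param params a [detect_params()].
#' @return an object of class `molecule_analysis`: `$geometry`, `$tracks`
#'   (both channels, with `position_bp`, `size_bp`, `below_floor`),
#'   `$kymographs`, `$params`.
#' @export
analyze_stack <- function(stack, total_bp = stack$total_bp,
                          params = detect_params()) {
  stopifnot(inherits(stack, "image_stack"))
  fwhm_px <- if (is.null(params$psf_fwhm_px))
    stack$psf_fwhm_nm / stack$pixel_size_nm else params$psf_fwhm_px
  pp <- preprocess(stack, params$median_window_px, params$tophat_width_px)
  ky_dna <- build_kymograph(pp, "dna", params$band_half_px)
  has_rnap <- !is.null(pp$channels$rnap) && any(pp$channels$rnap > 0)
  end_frames <- params$end_frames
  geom <- find_dna_ends(ky_dna, total_bp, frames = end_frames,
                        psf_fwhm_px = fwhm_px)
  dt <- stack$frame_interval_s
  gate <- if (is.null(params$max_link_px))
    3 * sqrt(2 * params$assumed_D_um2_s * dt) * 1000 / stack$pixel_size_nm
  else params$max_link_px
  gate <- max(gate, 2)

  track_one <- function(kymo, k, unique_per_frame = FALSE) {
    det <- detect_puncta(kymo, geom, prominence_k = k,
                         psf_fwhm_px = fwhm_px,
                         edge_margin_px = params$edge_margin_px)
    if (unique_per_frame && nrow(det) > 0) {
      det <- det[order(det$frame, -det$excess), , drop = FALSE]
      det <- det[!duplicated(det$frame), , drop = FALSE]
    }
    tr <- link_tracks(det, max_link_px = gate,
                      min_lifetime_frames = params$min_lifetime_frames,
                      gap_frames = params$gap_frames)
    if (nrow(tr) > 0) {
      tr$time_s <- tr$frame * dt
      tr$position_bp <- map_px_to_bp(tr$position_px, geom)
      tr$size_bp <- size_from_intensity(tr$excess, tr$row_total, total_bp)
      tr$below_floor <- tr$size_bp < params$floor_bp
    } else {
      tr$time_s <- numeric(0); tr$position_bp <- numeric(0)
      tr$size_bp <- numeric(0); tr$below_floor <- logical(0)
    }
    tr
  }
  tr_dna <- track_one(ky_dna, params$prominence_k)
  tr_dna$channel <- rep("dna", nrow(tr_dna))
  tracks <- tr_dna
  ky_rnap <- NULL
  if (has_rnap) {
    ky_rnap <- build_kymograph(pp, "rnap", params$band_half_px)
    tr_rnap <- track_one(ky_rnap, params$prominence_k_rnap,
                         unique_per_frame = TRUE)
    tr_rnap$channel <- rep("rnap", nrow(tr_rnap))
    tr_rnap$below_floor <- rep(FALSE, nrow(tr_rnap))  # no size floor for RNAP
    tracks <- rbind(tracks, tr_rnap)
  }
  rownames(tracks) <- NULL
  out <- list(geometry = geom, tracks = tracks,
              kymographs = list(dna = ky_dna, rnap = ky_rnap),
              params = params, frame_interval_s = dt,
              n_frames = stack$n_frames)
  class(out) <- "molecule_analysis"
  out
}

#' @export
print.molecule_analysis <- function(x, ...) {
  cat("<molecule_analysis> ", x$n_frames, " frames, ",
      length(unique(x$tracks$track_id[x$tracks$channel == "dna"])),
      " DNA-channel tracks\n", sep = "")
  invisible(x)
}

#' Combine per-molecule analyses into one tidy track table
#'
#' @param analyses named or unnamed list of `molecule_analysis` objects.
#' @return a list with `tracks` (one data frame, `molecule` column added,
#'   track ids made unique per molecule), `geometries`, `n_frames` and
#'   `frame_interval_s` per molecule.
#' @export
combine_analyses <- function(analyses) {
  nm <- names(analyses)
  if (is.null(nm)) nm <- as.character(seq_along(analyses))
  tracks <- do.call(rbind, lapply(seq_along(analyses), function(i) {
    tr <- analyses[[i]]$tracks
    if (nrow(tr) > 0) tr$molecule <- nm[i] else tr$molecule <- character(0)
    tr
  }))
  rownames(tracks) <- NULL
  list(tracks = tracks,
       geometries = stats::setNames(lapply(analyses, `[[`, "geometry"), nm),
       n_frames = stats::setNames(vapply(analyses, `[[`, 0L, "n_frames"), nm),
       frame_interval_s = stats::setNames(
         vapply(analyses, `[[`, 0, "frame_interval_s"), nm))
}

#' Reported plectonemes (above the detection floor)
#'
#' Filters a track table to DNA-channel tracks whose mean size reaches the
#' detection floor; these are the plectonemes the assay can report.
#'
#' @param tracks track data frame (from one or several analyses).
#' @param floor_bp detection floor, bp (default 1500).
#' @return the filtered track table.
#' @export
reported_plectonemes <- function(tracks, floor_bp = 1500) {
  tr <- tracks[tracks$channel == "dna", , drop = FALSE]
  if (nrow(tr) == 0) return(tr)
  key <- if ("molecule" %in% names(tr))
    paste(tr$molecule, tr$track_id) else as.character(tr$track_id)
  mean_size <- tapply(tr$size_bp, key, mean)
  ok <- names(mean_size)[mean_size >= floor_bp]
  out <- tr[key %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
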