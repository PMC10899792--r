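#' Localize the DNA ends by peak peeling
#'
#' Averages a set of quiescent frames into an intensity profile, then
#' iteratively places a Gaussian of the PSF width at the current profile
#' maximum, subtracts it (flooring at zero), and records the center, until
#' less than `stop_fraction` of the original integrated area remains.  The
#' outermost recorded centers are the DNA ends; the base-pair scale follows
#' from the known construct length.  The subtracted amplitude is
#' `amp_fraction` times the current maximum: partial subtraction (default
#' 0.5) places peaks more densely and roughly halves the inward bias of the
#' outermost centers at the plateau edges, while still contracting
#' geometrically.
#'
#' @param kymo a DNA-channel `kymograph`.
#' @param total_bp construct length in bp (defaults to the stack metadata).
#' @param frames indices of quiescent frames to average (default the first
#'   `n_avg_frames`).
#' @param n_avg_frames number of leading frames averaged when `frames` is
#'   not given.
#' @param psf_fwhm_px PSF full width at half maximum in pixels.
#' @param stop_fraction stop when the residual integrated area falls below
#'   this fraction of the original (default 0.10).
#' @param amp_fraction fraction of the current maximum subtracted per
#'   iteration (default 0.5).
#' @param min_integral noise floor: error if the profile integral is below
#'   this value.
#' @param max_iter safety cap on peeling iterations.
#' @param orientation_flipped logical, set when the 3' end is on the left.
#' @return an object of class `molecule_geometry` with sub-pixel end
#'   coordinates `end_left_px`, `end_right_px`, the scale `bp_per_px`, and
#'   the peeled peak centers.
#' @export
find_dna_ends <- function(kymo, total_bp = kymo$total_bp, frames = NULL,
                          n_avg_frames = 10, psf_fwhm_px = 2.75,
                          stop_fraction = 0.10, amp_fraction = 0.5,
                          min_integral = 0, max_iter = 1000,
                          orientation_flipped = FALSE) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(frames)) frames <- seq_len(min(n_avg_frames, nrow(kymo$mat)))
  sub <- kymo$mat[frames, , drop = FALSE]
  profile <- colMeans(sub)
  # amplitude floor: 3x the standard error of the temporally averaged
  # profile, so residual noise bumps outside the molecule never receive a
  # peeled peak; identically zero for noiseless input
  amp_floor <- if (length(frames) > 1)
    3 * stats::median(apply(sub, 2, stats::sd)) / sqrt(length(frames))
  else 0
  geom <- peel_profile(profile, total_bp, psf_fwhm_px, stop_fraction,
                       amp_fraction, min_integral, max_iter, amp_floor)
  geom$orientation_flipped <- isTRUE(orientation_flipped)
  geom$pixel_size_nm <- kymo$pixel_size_nm
  geom
}

#' Peak-peel a 1-D intensity profile
#'
#' Workhorse behind [find_dna_ends()], usable directly on any profile.
#'
#' @param profile numeric intensity profile (0-based pixel axis).
#' @param amp_floor stop peeling once the residual maximum falls below this
#'   amplitude (0 disables; [find_dna_ends()] derives it from the temporal
#'   noise of the averaged frames).
#' @inheritParams find_dna_ends
#' @return a `molecule_geometry`.
#' @export
peel_profile <- function(profile, total_bp, psf_fwhm_px = 2.75,
                         stop_fraction = 0.10, amp_fraction = 0.5,
                         min_integral = 0, max_iter = 1000,
                         amp_floor = 0) {
  a0 <- sum(profile)
  if (!is.finite(a0) || a0 <= max(0, min_integral))
    stop("profile too dim: integrated intensity ", signif(a0, 3),
         " is at or below the noise floor")
  if (stop_fraction >= 1)
    stop("stop_fraction >= 1 peels no peaks; no geometry can be derived")
  sigma <- psf_fwhm_px / (2 * sqrt(2 * log(2)))
  x <- seq_along(profile) - 1
  res <- profile
  centers <- numeric(0)
  it <- 0L
  while (sum(res) > stop_fraction * a0 && max(res) > amp_floor &&
         it < max_iter) {
    it <- it + 1L
    i <- which.max(res)
    # sub-pixel refinement by quadratic interpolation around the maximum
    c_px <- x[i]
    if (i > 1 && i < length(res)) {
      y1 <- res[i - 1]; y2 <- res[i]; y3 <- res[i + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) c_px <- x[i] + 0.5 * (y1 - y3) / den
    }
    centers <- c(centers, c_px)
    res <- pmax(0, res - amp_fraction * res[i] *
                  exp(-(x - c_px)^2 / (2 * sigma^2)))
  }
  if (length(centers) < 2)
    stop("peak peeling found fewer than 2 peaks; cannot locate both DNA ends")
  ends <- range(centers)
  out <- list(end_left_px = ends[1], end_right_px = ends[2],
              total_bp = total_bp,
              bp_per_px = total_bp / diff(ends),
              peeled_centers_px = centers, n_peeled = length(centers),
              orientation_flipped = FALSE, pixel_size_nm = NA_real_)
  class(out) <- "molecule_geometry"
  out
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("<molecule_geometry> ends ", round(x$end_left_px, 2), " .. ",
      round(x$end_right_px, 2), " px, ", x$total_bp, " bp (",
      round(x$bp_per_px, 1), " bp/px)\n", sep = "")
  invisible(x)
}

#' Convert pixel positions to genomic positions
#'
#' Linear map from the kymograph axis to genomic coordinates, clamped to
#' `[0, total_bp]`; mirrored when the geometry is orientation-flipped (3' end
#' on the left).
#'
#' @param position_px pixel positions (0-based, sub-pixel allowed).
#' @param geometry a `molecule_geometry`.
#' @return genomic positions in bp.
#' @export
map_px_to_bp <- function(position_px, geometry) {
  bp <- (position_px - geometry$end_left_px) * geometry$bp_per_px
  bp <- pmin(pmax(bp, 0), geometry$total_bp)
  if (isTRUE(geometry$orientation_flipped)) bp <- geometry$total_bp - bp
  bp
}

#' Convert genomic positions to pixel positions
#'
#' Inverse of [map_px_to_bp()].
#'
#' @inheritParams map_px_to_bp
#' @param position_bp genomic positions in bp.
#' @return pixel positions.
#' @export
map_bp_to_px <- function(position_bp, geometry) {
  if (isTRUE(geometry$orientation_flipped))
    position_bp <- geometry$total_bp - position_bp
  geometry$end_left_px + position_bp / geometry$bp_per_px
}
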