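#' Render a ground truth into a two-channel image stack
#'
#' The DNA channel is built per frame as a uniform backbone line carrying the
#' non-plectonemic base pairs between the tether points, plus each
#' plectoneme's base pairs added as a point mass at its position; the profile
#' is convolved with the Gaussian PSF, spread transversely, Poisson-sampled
#' and read noise is added.  The RNAP channel contains a single PSF punctum
#' at the RNAP position.  The expected (noise-free) integrated DNA-channel
#' signal is proportional to `total_bp` and invariant to the plectoneme
#' arrangement.
#'
#' @param truth a `ground_truth` from [simulate_plectonemes()] or
#'   [simulate_transcription()].
#' @param rs a [render_spec()].
#' @param noise logical; `FALSE` renders noiseless expected intensities.
#' @param seed RNG seed for the noise draw.
#' @return an object of class `image_stack`: per-channel arrays of dimension
#'   (height, width, frames) plus acquisition metadata.  Saturated frames
#'   (counts above the camera bit depth) trigger a warning and are clipped,
#'   with the count of clipped pixels stored in `$n_saturated`.
#' @export
render_stack <- function(truth, rs = render_spec(), noise = TRUE, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(rs, "render_spec"))
  mol <- truth$mol
  fwhm_px <- rs$psf_fwhm_nm / mol$pixel_size_nm
  if (fwhm_px < 2)
    stop("PSF undersampled: need >= 2 px per FWHM, got ",
         round(fwhm_px, 2), " px")
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  W <- mol$width_px
  H <- rs$height_px
  n_frames <- nrow(truth$frames)
  xl <- mol$tether_px[1]; xr <- mol$tether_px[2]

  # per-pixel coverage of the backbone segment [xl, xr] (pixel i covers
  # [i - 0.5, i + 0.5) in 0-based pixel coordinates)
  px <- seq_len(W) - 1
  coverage <- pmax(0, pmin(px + 0.5, xr) - pmax(px - 0.5, xl))

  ob <- truth$objects
  plect <- ob[ob$kind == "plectoneme", , drop = FALSE]
  rnap <- ob[ob$kind == "rnap", , drop = FALSE]

  prof_dna <- matrix(0, n_frames, W)
  tot_size <- rep(0, n_frames)
  if (nrow(plect) > 0) {
    agg <- tapply(plect$size_bp, plect$frame, sum)
    tot_size[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  backbone_bp <- mol$total_bp - tot_size
  prof_dna <- outer(backbone_bp / (xr - xl), coverage) * rs$photons_per_bp

  put_mass <- function(prof, frame_idx, pos_bp, photons) {
    # deposit point masses with linear sub-pixel interpolation
    x <- xl + pos_bp / mol$bp_per_px
    i0 <- floor(x); w1 <- x - i0
    i0 <- pmax(0, pmin(W - 2, i0))
    idx1 <- cbind(frame_idx, i0 + 1)
    idx2 <- cbind(frame_idx, i0 + 2)
    add1 <- photons * (1 - w1); add2 <- photons * w1
    for (k in seq_along(frame_idx)) {
      prof[idx1[k, 1], idx1[k, 2]] <- prof[idx1[k, 1], idx1[k, 2]] + add1[k]
      prof[idx2[k, 1], idx2[k, 2]] <- prof[idx2[k, 1], idx2[k, 2]] + add2[k]
    }
    prof
  }
  if (nrow(plect) > 0)
    prof_dna <- put_mass(prof_dna, plect$frame + 1L, plect$position_bp,
                         plect$size_bp * rs$photons_per_bp)
  prof_rnap <- matrix(0, n_frames, W)
  if (nrow(rnap) > 0)
    prof_rnap <- put_mass(prof_rnap, rnap$frame + 1L, rnap$position_bp,
                          rep(rs$rnap_photons, nrow(rnap)))

  # PSF convolution along x as multiplication by a column-stochastic kernel
  off <- outer(seq_len(W), seq_len(W), "-")
  K <- exp(-off^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  prof_dna <- prof_dna %*% K
  prof_rnap <- prof_rnap %*% K

  # transverse Gaussian profile, normalized to conserve photons
  yy <- seq_len(H) - (H + 1) / 2
  wy <- exp(-yy^2 / (2 * sigma^2)); wy <- wy / sum(wy)

  expand <- function(prof)
    array(outer(wy, t(prof)), dim = c(H, W, n_frames))

  lam_dna <- expand(prof_dna)
  lam_rnap <- expand(prof_rnap)
  n_sat <- 0L
  if (noise) {
    with_seed(seed, {
      shoot <- function(lam) {
        v <- stats::rpois(length(lam), lam) +
          stats::rnorm(length(lam), 0, rs$read_noise_sd)
        array(pmax(0, round(v)), dim = dim(lam))
      }
      lam_dna <- shoot(lam_dna)
      lam_rnap <- shoot(lam_rnap)
    })
    cap <- 2^rs$bit_depth - 1
    n_sat <- sum(lam_dna > cap) + sum(lam_rnap > cap)
    if (n_sat > 0) {
      warning(n_sat, " pixel(s) saturated at ", cap, " counts and clipped")
      lam_dna[lam_dna > cap] <- cap
      lam_rnap[lam_rnap > cap] <- cap
    }
  }
  out <- list(
    channels = list(dna = lam_dna, rnap = lam_rnap),
    pixel_size_nm = mol$pixel_size_nm,
    frame_interval_s = truth$frame_interval_s,
    exposure_s = rs$exposure_s, psf_fwhm_nm = rs$psf_fwhm_nm,
    n_frames = n_frames, width_px = W, height_px = H,
    total_bp = mol$total_bp, tether_px = mol$tether_px,
    n_saturated = n_sat, noise = noise, preprocessed = FALSE
  )
  class(out) <- "image_stack"
  out
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", x$n_frames, " frames x ", x$height_px, " x ",
      x$width_px, " px, channels: ", paste(names(x$channels), collapse = ", "),
      if (x$preprocessed) " (preprocessed)", "\n", sep = "")
  invisible(x)
}
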