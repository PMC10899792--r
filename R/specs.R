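#' Molecule specification
#'
#' Geometry of a doubly-tethered, torsionally constrained DNA construct as it
#' appears along the kymograph axis.  The tether separation may not exceed the
#' B-DNA contour length (0.34 nm/bp); by default the molecule is laid out at a
#' fractional extension typical of the low tension (~0.05 pN) of the assay.
#'
#' @param total_bp construct length in base pairs (e.g. 21000, 31000, 38000).
#' @param promoter_bp genomic position of the transcription start site, bp.
#' @param handle_bp surface-attachment handle length at each end, bp.
#' @param pixel_size_nm physical pixel pitch of the camera (default 109).
#' @param extension fractional end-to-end extension used to place the tethers
#'   when `tether_px` is not given.
#' @param tether_px optional length-2 vector of pixel coordinates of the two
#'   DNA ends along the kymograph axis (0-based, sub-pixel allowed).
#' @param margin_px empty margin left of the first tether when tethers are
#'   auto-placed.
#' @param orientation_flipped logical; `TRUE` when the 3' end is on the left,
#'   in which case genomic coordinates are mirrored during mapping.
#' @return an object of class `molecule_spec`.
#' @export
molecule_spec <- function(total_bp, promoter_bp = 8000, handle_bp = 600,
                          pixel_size_nm = 109, extension = 0.7,
                          tether_px = NULL, margin_px = 15,
                          orientation_flipped = FALSE) {
  stopifnot(is.numeric(total_bp), length(total_bp) == 1, total_bp > 0)
  if (!(promoter_bp > 0 && promoter_bp < total_bp))
    stop("promoter_bp must lie strictly inside (0, total_bp)")
  if (2 * handle_bp >= total_bp)
    stop("handle_bp too large: 2 * handle_bp must be < total_bp")
  contour_nm <- total_bp * NM_PER_BP
  if (is.null(tether_px)) {
    if (!(extension > 0 && extension <= 1))
      stop("extension must be in (0, 1]")
    sep_px <- extension * contour_nm / pixel_size_nm
    tether_px <- c(margin_px, margin_px + sep_px)
  }
  if (length(tether_px) != 2 || diff(tether_px) <= 0)
    stop("tether_px must be two increasing pixel coordinates")
  sep_nm <- diff(tether_px) * pixel_size_nm
  if (sep_nm > contour_nm + 1e-6)
    stop("tether separation (", round(sep_nm), " nm) exceeds the contour ",
         "length of ", total_bp, " bp (", round(contour_nm), " nm)")
  out <- list(
    total_bp = total_bp, promoter_bp = promoter_bp, handle_bp = handle_bp,
    pixel_size_nm = pixel_size_nm, tether_px = as.numeric(tether_px),
    orientation_flipped = isTRUE(orientation_flipped),
    nm_per_bp = sep_nm / total_bp,
    bp_per_px = total_bp / diff(tether_px),
    width_px = as.integer(ceiling(tether_px[2] + margin_px))
  )
  class(out) <- "molecule_spec"
  out
}

#' Plectoneme dynamics specification
#'
#' Stochastic dynamics of diffusing plectonemes on a supercoiled molecule:
#' reflected Brownian motion between end-exclusion boundaries, Poisson
#' nucleation from (and termination into) a conserved pool of supercoiled
#' base pairs, and stochastic size exchange between co-existing plectonemes.
#'
#' @param diffusion_um2_s plectoneme diffusion coefficient, um^2/s
#'   (default 0.5, the value measured for plectonemes in this assay).
#' @param nucleation_rate nucleation events per second per molecule.
#' @param termination_rate termination events per second per plectoneme.
#' @param total_supercoiled_bp base pairs stored in supercoils at t = 0.
#' @param exchange_rate scale (bp/sqrt(s)) of stochastic size transfer
#'   between co-existing plectonemes.
#' @param pinned_site_bp optional genomic position at which all supercoils
#'   merge into a single immobile plectoneme (open-complex pinning).
#' @param end_exclusion_bp zone near each tether point where plectonemes may
#'   not sit (default 1200 bp, the span over which plectoneme density
#'   vanishes near the surface handles).
#' @param n_init number of plectonemes holding the initial budget.
#' @return an object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(diffusion_um2_s = 0.5, nucleation_rate = 0.03,
                          termination_rate = 0.01, total_supercoiled_bp = 6000,
                          exchange_rate = 150, pinned_site_bp = NULL,
                          end_exclusion_bp = 1200, n_init = 2) {
  if (diffusion_um2_s < 0) stop("diffusion_um2_s must be >= 0")
  if (total_supercoiled_bp < 0) stop("total_supercoiled_bp must be >= 0")
  if (nucleation_rate < 0 || termination_rate < 0)
    stop("nucleation_rate and termination_rate must be >= 0")
  if (end_exclusion_bp < 0) stop("end_exclusion_bp must be >= 0")
  out <- list(
    diffusion_um2_s = diffusion_um2_s, nucleation_rate = nucleation_rate,
    termination_rate = termination_rate,
    total_supercoiled_bp = total_supercoiled_bp,
    exchange_rate = exchange_rate, pinned_site_bp = pinned_site_bp,
    end_exclusion_bp = end_exclusion_bp, n_init = max(1L, as.integer(n_init))
  )
  class(out) <- "dynamics_spec"
  out
}

#' Transcription specification
#'
#' A promoter-stalled RNA polymerase that restarts on NTP addition, advances
#' at a constant elongation rate, and injects supercoiled base pairs that
#' partition between the upstream and downstream domains.  Injection is
#' quantized per helical turn; each quantum is assigned upstream with
#' probability `upstream_fraction`, so the realized partition carries binomial
#' fluctuations around the nominal split.
#'
#' @param stall_offset_nt stall position downstream of the TSS in nt
#'   (default 29, i.e. the A29 stall).
#' @param elongation_rate_bp_s RNAP translocation speed after restart, bp/s.
#' @param start_time_s moment of NTP addition, s (use `Inf` for a permanently
#'   stalled open complex).
#' @param injection_rate_bp_s rate at which supercoiled (plectonemic) base
#'   pairs accumulate during elongation, bp/s.
#' @param upstream_fraction fraction of injected supercoil assigned upstream.
#' @param rnase_time_s optional treatment-epoch marker time, s.
#' @param rnap_exclusion_bp half-width of the zone around the RNAP that
#'   plectonemes may not enter (twist-diffusion barrier).
#' @param pin_before_start logical; merge any pre-existing supercoils into a
#'   single plectoneme pinned at the stall site before NTP addition.
#' @return an object of class `transcription_spec`.
#' @export
transcription_spec <- function(stall_offset_nt = 29, elongation_rate_bp_s = 50,
                               start_time_s = 60, injection_rate_bp_s = 18.2,
                               upstream_fraction = 0.5, rnase_time_s = NULL,
                               rnap_exclusion_bp = 1500,
                               pin_before_start = TRUE) {
  if (upstream_fraction < 0 || upstream_fraction > 1)
    stop("upstream_fraction must be in [0, 1]")
  if (elongation_rate_bp_s < 0) stop("elongation_rate_bp_s must be >= 0")
  if (injection_rate_bp_s < 0) stop("injection_rate_bp_s must be >= 0")
  out <- list(
    stall_offset_nt = stall_offset_nt,
    elongation_rate_bp_s = elongation_rate_bp_s,
    start_time_s = start_time_s, injection_rate_bp_s = injection_rate_bp_s,
    upstream_fraction = upstream_fraction, rnase_time_s = rnase_time_s,
    rnap_exclusion_bp = rnap_exclusion_bp,
    pin_before_start = isTRUE(pin_before_start)
  )
  class(out) <- "transcription_spec"
  out
}

#' Rendering specification
#'
#' Optical and camera parameters used to turn a ground-truth ledger into a
#' two-channel image stack: Gaussian point-spread function, intercalator
#' photon budget proportional to local DNA content, Poisson shot noise and
#' Gaussian read noise.  The default photon budget is an in-repo calibration
#' chosen so that, with the default detection settings, the smallest reliably
#' detected plectoneme is about 1500 bp.
#'
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum, nm.
#' @param photons_per_bp expected intercalator photons per base pair per
#'   exposure (calibrated default, see Details).
#' @param read_noise_sd camera read noise standard deviation, counts.
#' @param exposure_s exposure time per channel (default 0.1 s).
#' @param frame_interval_s acquisition period, s.
#' @param rnap_photons photon budget of the RNAP label punctum per exposure.
#' @param height_px transverse height of the rendered crop, px (odd).
#' @param bit_depth camera bit depth; counts above `2^bit_depth - 1` are
#'   reported as saturation.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(psf_fwhm_nm = 300, photons_per_bp = 0.12,
                        read_noise_sd = 1, exposure_s = 0.1,
                        frame_interval_s = 2, rnap_photons = 200,
                        height_px = 11, bit_depth = 16) {
  if (photons_per_bp < 0 || rnap_photons < 0)
    stop("photon budgets must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (height_px < 3 || height_px %% 2 == 0)
    stop("height_px must be an odd integer >= 3")
  out <- list(
    psf_fwhm_nm = psf_fwhm_nm, photons_per_bp = photons_per_bp,
    read_noise_sd = read_noise_sd, exposure_s = exposure_s,
    frame_interval_s = frame_interval_s, rnap_photons = rnap_photons,
    height_px = as.integer(height_px), bit_depth = as.integer(bit_depth)
  )
  class(out) <- "render_spec"
  out
}
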