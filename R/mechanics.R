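#' Parameters of the torque-balance supercoil-induction model
#'
#' A deliberately simple, self-contained model of supercoil induction by a
#' translocating RNAP.  To track the helical groove the RNAP must co-rotate
#' at `2 pi v / h`; the torque this costs equals the rotational drag of the
#' RNAP sphere plus (optionally) its nascent RNA blob.  Whenever the DNA's
#' accumulated torsional torque is below that frictional cost, the
#' polymerase cannot rotate and the turn is injected into the DNA instead.
#' Buckling is scored once the supercoiling density reaches
#' `sigma_threshold` and the DNA torque exceeds the buckling torque
#' `sqrt(2 kBT Lp F)`.
#'
#' @param viscosity_Pa_s buffer viscosity, Pa s (water: 1e-3; bacterial
#'   cytoplasm: 17.5).
#' @param rnap_radius_nm RNAP sphere radius, nm.
#' @param rna_monomer_nm Flory prefactor of the RNA blob radius
#'   `Rg = b N^nu`, nm.
#' @param flory_exponent Flory exponent nu (good solvent: 3/5).
#' @param lever_arm_nm offset of the RNA blob center from the DNA axis, nm.
#' @param elongation_rate_bp_s RNAP speed, bp/s.
#' @param helical_pitch_bp helical repeat of B-DNA, bp per turn.
#' @param tension_pN DNA tension, pN (assay: ~0.05).
#' @param bend_persistence_nm bending persistence length, nm.
#' @param twist_persistence_nm twist persistence length, nm.
#' @param kBT_pNnm thermal energy, pN nm.
#' @param domain_length_bp torsionally constrained span on each side, bp.
#' @param sigma_threshold supercoiling density at which buckling is scored.
#' @return a list of class `mechanics_params`.
#' @export
mechanics_params <- function(viscosity_Pa_s = 1e-3, rnap_radius_nm = 7,
                             rna_monomer_nm = 0.5, flory_exponent = 3 / 5,
                             lever_arm_nm = 5, elongation_rate_bp_s = 50,
                             helical_pitch_bp = 10.5, tension_pN = 0.05,
                             bend_persistence_nm = 50,
                             twist_persistence_nm = 100, kBT_pNnm = 4.114,
                             domain_length_bp = 15000,
                             sigma_threshold = 0.001) {
  p <- as.list(environment())
  if (any(unlist(p[c("viscosity_Pa_s", "rnap_radius_nm", "rna_monomer_nm",
                     "lever_arm_nm", "helical_pitch_bp",
                     "bend_persistence_nm", "twist_persistence_nm",
                     "kBT_pNnm", "domain_length_bp", "sigma_threshold")])
          <= 0))
    stop("all physical parameters must be > 0")
  if (p$tension_pN < 0) stop("tension_pN must be >= 0")
  if (p$elongation_rate_bp_s < 0) stop("elongation_rate_bp_s must be >= 0")
  if (!(p$flory_exponent > 0.5 && p$flory_exponent <= 0.6))
    stop("flory_exponent must lie in (0.5, 0.6]")
  class(p) <- "mechanics_params"
  p
}

# 1 Pa s = 1e-6 pN s / nm^2
PA_S_TO_PN_S_NM2 <- 1e-6

#' Rotational drag of RNAP plus nascent transcript
#'
#' `gamma = gamma_RNAP + gamma_RNA` in pN nm s per (rad/s):
#' `gamma_RNAP = 8 pi mu R^3` (a sphere spinning about the DNA axis) and
#' `gamma_RNA = 6 pi mu Rg (Rg + lever)^2` (a non-draining blob of radius
#' `Rg = b N^nu` translating on a circle about the axis).  A zero-length
#' transcript gives exactly the bare-RNAP drag.
#'
#' @param params a [mechanics_params()].
#' @param transcript_nt transcript length, nt (>= 0).
#' @return drag coefficient with attribute `unit = "pN nm s"`.
#' @export
rotational_drag <- function(params, transcript_nt) {
  stopifnot(inherits(params, "mechanics_params"), all(transcript_nt >= 0))
  mu <- params$viscosity_Pa_s * PA_S_TO_PN_S_NM2
  g_rnap <- 8 * pi * mu * params$rnap_radius_nm^3
  rg <- params$rna_monomer_nm * transcript_nt^params$flory_exponent
  rg[transcript_nt == 0] <- 0
  g_rna <- 6 * pi * mu * rg * (rg + params$lever_arm_nm)^2
  structure(g_rnap + g_rna, unit = "pN nm s")
}

#' Critical buckling torque of stretched DNA
#'
#' `tau_b = sqrt(2 kBT Lp F)`: the torsional torque above which twisted DNA
#' under tension `F` becomes unstable to writhe (plectoneme) formation.  At
#' the assay tension of ~0.05 pN this is below 5 pN nm, so injected twist
#' converts readily into plectonemes.
#'
#' @param params a [mechanics_params()].
#' @return torque with attribute `unit = "pN nm"`.
#' @export
buckling_torque <- function(params) {
  stopifnot(inherits(params, "mechanics_params"))
  structure(sqrt(2 * params$kBT_pNnm * params$bend_persistence_nm *
                   params$tension_pN),
            unit = "pN nm")
}

#' Simulate supercoil induction during transcription
#'
#' Per transcribed base pair, the polymerase must co-rotate by `2 pi / h` to
#' track the groove; the frictional torque this requires is
#' `tau_fric = gamma(transcript) * 2 pi v / h`.  While the DNA torsional
#' torque `tau_DNA = 2 pi C kBT dLk / L` is below `tau_fric`, the turn is
#' injected into the DNA (`dLk` grows by `1/h` per bp); otherwise the RNAP
#' spins and no twist accumulates.  Buckling is scored when the supercoiling
#' density `sigma = dLk / (L / h)` reaches `sigma_threshold` *and* `tau_DNA`
#' exceeds the buckling torque.
#'
#' @param params a [mechanics_params()].
#' @param max_bp transcript length cap, bp.
#' @param with_transcript include the RNA-blob drag.
#' @param trace_every record the torque trace every this many bp.
#' @return list of class `mechanics_result`: `buckled`,
#'   `buckling_distance_bp` (capped at `max_bp` when not buckled),
#'   `regime` (`"supercoiling"` or `"tracking"`), `torque_trace` (bp,
#'   tau_DNA, tau_fric; unit attributes in pN nm), `sigma_final`.
#' @export
simulate_induction <- function(params, max_bp = 30000,
                               with_transcript = TRUE, trace_every = 100) {
  stopifnot(inherits(params, "mechanics_params"), max_bp >= 1)
  h <- params$helical_pitch_bp
  L_nm <- params$domain_length_bp * NM_PER_BP
  stiff <- 2 * pi * params$twist_persistence_nm * params$kBT_pNnm / L_nm
  omega <- 2 * pi * params$elongation_rate_bp_s / h
  tau_b <- as.numeric(buckling_torque(params))
  lk_relaxed <- params$domain_length_bp / h

  n <- seq_len(max_bp)
  gam <- as.numeric(rotational_drag(params, if (with_transcript) n else
    rep(0, length(n))))
  tau_fric <- gam * omega
  # ceiling on dLk set by friction: tau_DNA <= tau_fric
  lk_ceiling <- tau_fric / stiff
  # injection-limited accumulation: at most 1/h turn per transcribed bp,
  # never exceeding the (monotone) friction ceiling
  dlk <- pmin(n / h, cummax(lk_ceiling))
  dlk <- cummax(dlk)          # torque never relaxes in this model
  tau_dna <- stiff * dlk
  sigma <- dlk / lk_relaxed
  hit <- which(sigma >= params$sigma_threshold & tau_dna >= tau_b)
  buckled <- length(hit) > 0
  dist <- if (buckled) n[hit[1]] else max_bp
  keep <- unique(c(seq(1, max_bp, by = max(1, trace_every)), dist))
  keep <- sort(keep[keep <= max_bp])
  out <- list(
    buckled = buckled, buckling_distance_bp = dist,
    regime = if (buckled) "supercoiling" else "tracking",
    torque_trace = data.frame(
      transcript_bp = n[keep],
      tau_dna = structure(tau_dna[keep], unit = "pN nm"),
      tau_fric = structure(tau_fric[keep], unit = "pN nm")),
    sigma_final = sigma[max_bp],
    tau_units = "pN nm")
  class(out) <- "mechanics_result"
  out
}

#' @export
print.mechanics_result <- function(x, ...) {
  cat("<mechanics_result> ", x$regime,
      if (x$buckled) paste0(": buckling at ", x$buckling_distance_bp, " bp")
      else paste0(": no buckling up to ", x$buckling_distance_bp, " bp"),
      "\n", sep = "")
  invisible(x)
}

#' Buckling distance versus buffer viscosity
#'
#' Runs [simulate_induction()] over a viscosity grid with and/or without the
#' nascent transcript.
#'
#' @param params a [mechanics_params()] (its viscosity is overridden).
#' @param mu_grid viscosities, Pa s (e.g. `10^seq(log10(1.75e-6),
#'   log10(1.75e4), length.out = 40)`).
#' @param transcript logical vector of transcript conditions to run.
#' @param max_bp transcript length cap per run, bp.
#' @return data frame: `mu_Pa_s`, `transcript`, `buckling_distance_bp`,
#'   `buckled`.
#' @export
viscosity_sweep <- function(params, mu_grid,
                            transcript = c(TRUE, FALSE), max_bp = 30000) {
  if (length(mu_grid) == 0) stop("empty viscosity grid")
  rows <- list()
  for (tr in transcript) for (mu in mu_grid) {
    p <- params; p$viscosity_Pa_s <- mu
    r <- simulate_induction(p, max_bp = max_bp, with_transcript = tr,
                            trace_every = max_bp)
    rows[[length(rows) + 1L]] <- data.frame(
      mu_Pa_s = mu, transcript = tr,
      buckling_distance_bp = r$buckling_distance_bp, buckled = r$buckled)
  }
  do.call(rbind, rows)
}
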