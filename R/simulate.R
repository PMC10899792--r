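#' Simulate diffusing plectonemes on a supercoiled molecule
#'
#' Generates a ground-truth ledger of plectoneme positions and sizes.  Each
#' plectoneme performs reflected Brownian motion in genomic coordinates
#' between the end-exclusion boundaries; nucleation draws a uniform position
#' over the allowed span and transfers base pairs from the unwound pool;
#' termination returns them; co-existing plectonemes exchange size
#' stochastically.  When `dyn$pinned_site_bp` is set, all supercoiled base
#' pairs sit in one immobile plectoneme at that site (open-complex pinning).
#'
#' @param mol a [molecule_spec()].
#' @param dyn a [dynamics_spec()].
#' @param duration_s simulated duration, s.
#' @param frame_interval_s spacing of recorded frames, s.
#' @param dt_s integration time step (Euler-Maruyama), s; must not exceed the
#'   frame interval and must keep the RMS diffusive step below 5 pixels.
#' @param seed integer RNG seed.
#' @param rnap_bp optional static genomic position recorded as an RNAP object
#'   in every frame (used by pinned-open-complex fixtures).
#' @return an object of class `ground_truth`: a per-object ledger
#'   (`$objects`: frame, time_s, id, kind, position_bp, size_bp), a per-frame
#'   summary (`$frames`: frame, time_s, total_plectoneme_bp, pool_bp, epoch,
#'   rnap_bp) and the generating specifications.
#' @export
simulate_plectonemes <- function(mol, dyn, duration_s, frame_interval_s = 2,
                                 dt_s = frame_interval_s / 10, seed = 1,
                                 rnap_bp = NULL) {
  stopifnot(inherits(mol, "molecule_spec"), inherits(dyn, "dynamics_spec"))
  check_step(mol, dyn, dt_s, frame_interval_s)
  if (dyn$total_supercoiled_bp >= mol$total_bp)
    stop("total_supercoiled_bp must be smaller than total_bp")
  lo <- dyn$end_exclusion_bp
  hi <- mol$total_bp - dyn$end_exclusion_bp
  if (!is.null(dyn$pinned_site_bp) &&
      (dyn$pinned_site_bp < lo || dyn$pinned_site_bp > hi))
    stop("pinned_site_bp lies inside an end-exclusion zone")

  n_frames <- floor(duration_s / frame_interval_s) + 1L
  rec_every <- max(1L, round(frame_interval_s / dt_s))
  step_bp <- sqrt(2 * dyn$diffusion_um2_s * dt_s) * 1000 / mol$nm_per_bp

  with_seed(seed, {
    if (!is.null(dyn$pinned_site_bp)) {
      pos <- dyn$pinned_site_bp
      size <- dyn$total_supercoiled_bp
      id <- 1L
      pool <- 0
      static <- TRUE
    } else {
      k <- dyn$n_init
      pos <- stats::runif(k, lo, hi)
      size <- rep(dyn$total_supercoiled_bp / k, k)
      id <- seq_len(k)
      pool <- 0
      static <- FALSE
    }
    next_id <- length(id) + 1L
    ledger <- vector("list", n_frames)
    frames <- data.frame(frame = seq_len(n_frames) - 1L,
                         time_s = (seq_len(n_frames) - 1L) * frame_interval_s,
                         total_plectoneme_bp = NA_real_, pool_bp = NA_real_,
                         epoch = "supercoiled", rnap_bp = NA_real_)
    record <- function(f) {
      n <- length(id)
      rows <- data.frame(frame = rep(f, n + !is.null(rnap_bp)),
                         time_s = rep(f * frame_interval_s, n + !is.null(rnap_bp)),
                         id = c(id, if (!is.null(rnap_bp)) 0L),
                         kind = c(rep("plectoneme", n),
                                  if (!is.null(rnap_bp)) "rnap"),
                         position_bp = c(pos, if (!is.null(rnap_bp)) rnap_bp),
                         size_bp = c(size, if (!is.null(rnap_bp)) NA_real_))
      rows
    }
    ledger[[1]] <- record(0L)
    frames$total_plectoneme_bp[1] <- sum(size)
    frames$pool_bp[1] <- pool
    if (!is.null(rnap_bp)) frames$rnap_bp[1] <- rnap_bp

    n_steps <- (n_frames - 1L) * rec_every
    f <- 1L
    if (n_steps > 0) for (s in seq_len(n_steps)) {
      if (!static) {
        if (length(id) > 0) {
          pos <- reflect_into(pos + stats::rnorm(length(pos), 0, step_bp),
                              lo, hi)
        }
        # size exchange between a random pair of co-existing plectonemes
        if (length(id) > 1 && dyn$exchange_rate > 0) {
          pair <- sample.int(length(id), 2)
          d <- stats::rnorm(1, 0, dyn$exchange_rate * sqrt(dt_s))
          d <- max(-size[pair[1]], min(size[pair[2]], d))
          size[pair[1]] <- size[pair[1]] + d
          size[pair[2]] <- size[pair[2]] - d
        }
        # termination: plectoneme returns its base pairs to the pool
        if (length(id) > 1 && dyn$termination_rate > 0) {
          die <- stats::runif(length(id)) < dyn$termination_rate * dt_s
          if (all(die)) die[1] <- FALSE    # keep at least one plectoneme
          if (any(die)) {
            pool <- pool + sum(size[die])
            pos <- pos[!die]; size <- size[!die]; id <- id[!die]
          }
        }
        # nucleation from the pool at a uniform position
        if (dyn$nucleation_rate > 0 && pool > 300 &&
            stats::runif(1) < dyn$nucleation_rate * dt_s) {
          take <- min(pool, max(300, pool * stats::runif(1, 0.3, 0.9)))
          pool <- pool - take
          pos <- c(pos, stats::runif(1, lo, hi))
          size <- c(size, take)
          id <- c(id, next_id)
          next_id <- next_id + 1L
        }
      }
      if (s %% rec_every == 0L) {
        f <- f + 1L
        ledger[[f]] <- record(f - 1L)
        frames$total_plectoneme_bp[f] <- sum(size)
        frames$pool_bp[f] <- pool
        if (!is.null(rnap_bp)) frames$rnap_bp[f] <- rnap_bp
      }
    }
    new_ground_truth(mol, do.call(rbind, ledger), frames, frame_interval_s,
                     duration_s, list(dyn = dyn), seed)
  })
}

#' Simulate transcription-generated twin supercoiled domains
#'
#' Before `tx$start_time_s` the RNAP sits at its stall position (TSS +
#' `stall_offset_nt`) and, optionally, pins all pre-existing supercoils there.
#' After NTP addition the RNAP advances at the elongation rate and injects
#' supercoiled base pairs at `tx$injection_rate_bp_s`, quantized per helical
#' turn and assigned to the upstream domain with probability
#' `tx$upstream_fraction`.  Plectonemes diffuse within their domain and never
#' cross the RNAP position (twist-diffusion barrier).
#'
#' @inheritParams simulate_plectonemes
#' @param tx a [transcription_spec()].
#' @return a `ground_truth` object; see [simulate_plectonemes()].
#' @export
simulate_transcription <- function(mol, dyn, tx, duration_s,
                                   frame_interval_s = 1,
                                   dt_s = frame_interval_s / 10, seed = 1) {
  stopifnot(inherits(mol, "molecule_spec"), inherits(dyn, "dynamics_spec"),
            inherits(tx, "transcription_spec"))
  check_step(mol, dyn, dt_s, frame_interval_s)
  lo <- dyn$end_exclusion_bp
  hi <- mol$total_bp - dyn$end_exclusion_bp
  stall <- mol$promoter_bp + tx$stall_offset_nt
  if (stall <= lo || stall >= hi)
    stop("stall position lies inside an end-exclusion zone")
  rnap_max <- hi - tx$rnap_exclusion_bp - 100
  excl <- tx$rnap_exclusion_bp

  n_frames <- floor(duration_s / frame_interval_s) + 1L
  rec_every <- max(1L, round(frame_interval_s / dt_s))
  step_bp <- sqrt(2 * dyn$diffusion_um2_s * dt_s) * 1000 / mol$nm_per_bp

  with_seed(seed, {
    rnap <- stall
    # side state: position/size/id vectors per domain
    up_pos <- numeric(0); up_size <- numeric(0); up_id <- integer(0)
    dn_pos <- numeric(0); dn_size <- numeric(0); dn_id <- integer(0)
    pin_pos <- NULL; pin_size <- 0
    if (dyn$total_supercoiled_bp > 0) {
      if (tx$pin_before_start) {
        pin_pos <- stall; pin_size <- dyn$total_supercoiled_bp
      } else {
        up_pos <- stats::runif(1, lo, stall - excl)
        up_size <- dyn$total_supercoiled_bp / 2; up_id <- 1L
        dn_pos <- stats::runif(1, stall + excl, hi)
        dn_size <- dyn$total_supercoiled_bp / 2; dn_id <- 2L
      }
    }
    next_id <- 3L
    started <- FALSE
    acc <- 0
    quantum <- BP_PER_TURN

    epoch_of <- function(t) {
      if (t < tx$start_time_s) "pre_ntp"
      else if (!is.null(tx$rnase_time_s) && t >= tx$rnase_time_s)
        "post_treatment"
      else "transcription"
    }
    diffuse_side <- function(p, lo_s, hi_s) {
      if (length(p) == 0 || hi_s <= lo_s) return(p)
      reflect_into(p + stats::rnorm(length(p), 0, step_bp), lo_s, hi_s)
    }
    ledger <- vector("list", n_frames)
    frames <- data.frame(frame = seq_len(n_frames) - 1L,
                         time_s = (seq_len(n_frames) - 1L) * frame_interval_s,
                         total_plectoneme_bp = NA_real_, pool_bp = 0,
                         epoch = NA_character_, rnap_bp = NA_real_,
                         upstream_bp = NA_real_, downstream_bp = NA_real_)
    record <- function(f, t) {
      if (!is.null(pin_pos)) {
        pp <- pin_pos; ps <- pin_size; pid <- 1L
      } else {
        pp <- c(up_pos, dn_pos); ps <- c(up_size, dn_size)
        pid <- c(up_id, dn_id)
      }
      keep <- ps > 1e-9
      pp <- pp[keep]; ps <- ps[keep]; pid <- pid[keep]
      n <- length(pid)
      data.frame(frame = rep(f, n + 1L), time_s = rep(t, n + 1L),
                 id = c(pid, 0L),
                 kind = c(rep("plectoneme", n), "rnap"),
                 position_bp = c(pp, rnap), size_bp = c(ps, NA_real_))
    }
    set_frame <- function(f, t) {
      frames$total_plectoneme_bp[f + 1L] <<- pin_size + sum(up_size) +
        sum(dn_size)
      frames$epoch[f + 1L] <<- epoch_of(t)
      frames$rnap_bp[f + 1L] <<- rnap
      frames$upstream_bp[f + 1L] <<- if (!is.null(pin_pos)) NA_real_ else
        sum(up_size)
      frames$downstream_bp[f + 1L] <<- if (!is.null(pin_pos)) NA_real_ else
        sum(dn_size)
      ledger[[f + 1L]] <<- record(f, t)
    }
    set_frame(0L, 0)

    n_steps <- (n_frames - 1L) * rec_every
    if (n_steps > 0) for (s in seq_len(n_steps)) {
      t <- s * dt_s
      if (!started && t >= tx$start_time_s) {
        started <- TRUE
        # release any pinned plectoneme symmetrically into the two domains
        if (!is.null(pin_pos)) {
          up_pos <- max(lo, stall - excl - 500); up_size <- pin_size / 2
          up_id <- 1L
          dn_pos <- min(hi, stall + excl + 500); dn_size <- pin_size / 2
          dn_id <- 2L
          pin_pos <- NULL; pin_size <- 0
        }
      }
      if (started) {
        if (rnap < rnap_max) {
          rnap <- min(rnap_max, rnap + tx$elongation_rate_bp_s * dt_s)
          acc <- acc + tx$injection_rate_bp_s * dt_s
        }
        while (acc >= quantum) {
          acc <- acc - quantum
          upstream <- stats::runif(1) < tx$upstream_fraction
          if (upstream) {
            if (length(up_id) == 0) {
              up_pos <- stats::runif(1, lo, max(lo + 1, rnap - excl))
              up_size <- quantum; up_id <- next_id; next_id <- next_id + 1L
            } else {
              j <- if (length(up_id) == 1) 1L else sample.int(length(up_id), 1)
              up_size[j] <- up_size[j] + quantum
            }
          } else {
            if (length(dn_id) == 0) {
              dn_pos <- stats::runif(1, min(hi - 1, rnap + excl), hi)
              dn_size <- quantum; dn_id <- next_id; next_id <- next_id + 1L
            } else {
              j <- if (length(dn_id) == 1) 1L else sample.int(length(dn_id), 1)
              dn_size[j] <- dn_size[j] + quantum
            }
          }
        }
        up_pos <- diffuse_side(up_pos, lo, max(lo, rnap - excl))
        dn_pos <- diffuse_side(dn_pos, min(hi, rnap + excl), hi)
        up_pos <- pmin(pmax(up_pos, lo), max(lo, rnap - excl))
        dn_pos <- pmax(pmin(dn_pos, hi), min(hi, rnap + excl))
      }
      if (s %% rec_every == 0L) set_frame(as.integer(s / rec_every), t)
    }
    gt <- new_ground_truth(mol, do.call(rbind, ledger), frames,
                           frame_interval_s, duration_s,
                           list(dyn = dyn, tx = tx), seed)
    gt
  })
}

check_step <- function(mol, dyn, dt_s, frame_interval_s) {
  if (dt_s > frame_interval_s + 1e-12)
    stop("dt_s must not exceed the frame interval")
  rms_px <- sqrt(2 * dyn$diffusion_um2_s * dt_s) * 1000 / mol$pixel_size_nm
  if (rms_px >= 5)
    stop("dt_s too large: RMS diffusive step is ", round(rms_px, 2),
         " px (must be < 5 px)")
  invisible(TRUE)
}

new_ground_truth <- function(mol, objects, frames, frame_interval_s,
                             duration_s, params, seed) {
  rownames(objects) <- NULL
  out <- list(mol = mol, objects = objects, frames = frames,
              frame_interval_s = frame_interval_s, duration_s = duration_s,
              params = params, seed = seed)
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$frames), " frames, ",
      sum(x$objects$kind == "plectoneme"), " plectoneme records, ",
      x$mol$total_bp, " bp construct\n", sep = "")
  invisible(x)
}

#' Apply a nicking event to a ground truth
#'
#' After `nick_time_s` all plectoneme sizes decay exponentially with time
#' constant `tau_s`, emulating torsional relaxation of a nicked molecule.
#'
#' @param truth a `ground_truth`.
#' @param nick_time_s time of the nick, s.
#' @param tau_s relaxation time constant, s.
#' @return the modified `ground_truth`.
#' @export
apply_nick <- function(truth, nick_time_s, tau_s = 5) {
  stopifnot(inherits(truth, "ground_truth"), tau_s > 0)
  ob <- truth$objects
  sel <- ob$kind == "plectoneme" & ob$time_s >= nick_time_s
  ob$size_bp[sel] <- ob$size_bp[sel] *
    exp(-(ob$time_s[sel] - nick_time_s) / tau_s)
  truth$objects <- ob
  fr <- truth$frames
  sel <- fr$time_s >= nick_time_s
  fr$total_plectoneme_bp[sel] <- fr$total_plectoneme_bp[sel] *
    exp(-(fr$time_s[sel] - nick_time_s) / tau_s)
  fr$epoch[sel] <- "post_nick"
  truth$frames <- fr
  truth$params$nick <- list(nick_time_s = nick_time_s, tau_s = tau_s)
  truth
}
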