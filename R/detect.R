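#' Detection parameters
#'
#' Bundle of detection/tracking thresholds used by [analyze_stack()].
#'
#' @param prominence_k punctum prominence threshold in units of the robust
#'   row noise (default 4, calibrated together with the default rendering
#'   photon budget against the ~1500-bp detection floor).
#' @param prominence_k_rnap prominence threshold for the RNAP channel.
#' @param psf_fwhm_px PSF FWHM in pixels (defaults from stack metadata when
#'   `NULL`).
#' @param min_lifetime_frames minimum consecutive-frame lifetime of a
#'   retained track (default 3).
#' @param max_link_px frame-to-frame linking gate in px; `NULL` derives
#'   3 x sqrt(2 D dt) from `assumed_D_um2_s` and the frame interval.
#' @param assumed_D_um2_s diffusion coefficient used to derive the gate.
#' @param floor_bp plectoneme-size detection floor; detections below it are
#'   flagged, and tracks whose mean size is below it are not reported.
#' @param median_window_px,tophat_width_px preprocessing settings.
#' @param band_half_px transverse integration band half-width (`NULL`: full).
#' @param edge_margin_px ignore detections within this margin of the ends.
#' @param end_frames frame indices averaged for end localization.
#' @param gap_frames number of missed frames bridged during linking.
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(prominence_k = 4, prominence_k_rnap = 6,
                          psf_fwhm_px = NULL, min_lifetime_frames = 3,
                          max_link_px = NULL, assumed_D_um2_s = 0.5,
                          floor_bp = 1500, median_window_px = 3,
                          tophat_width_px = 15, band_half_px = NULL,
                          edge_margin_px = 2,
                          end_frames = NULL, gap_frames = 1) {
  out <- as.list(environment())
  class(out) <- "detect_params"
  out
}

#' Detect puncta in every kymograph row
#'
#' Per row, the backbone baseline is the known backbone shape (a flat top
#' between the localized ends convolved with the PSF) scaled by a robust
#' per-row amplitude.  Local maxima of the residual with prominence at
#' least `prominence_k` times the robust row noise (estimated from
#' frame-to-frame differences), separated by at least one PSF FWHM, are
#' kept.  Each detection carries a sub-pixel position (intensity centroid
#' over +/- 1 FWHM) and the excess intensity above a template baseline
#' rescaled to the flanking punctum-free pixels, integrated over
#' +/- 1.5 FWHM.
#'
#' @param kymo a (preprocessed) `kymograph`.
#' @param geometry a `molecule_geometry`.
#' @param prominence_k prominence threshold in robust-noise units.
#' @param psf_fwhm_px PSF FWHM in pixels.
#' @param edge_margin_px margin near the DNA ends excluded from detection.
#' @param min_prominence absolute prominence floor (useful for noiseless
#'   profiles where the noise estimate vanishes).
#' @return data frame with columns `frame` (0-based), `position_px`,
#'   `prominence`, `excess`, `row_total`.  Empty detection lists are valid.
#' @export
detect_puncta <- function(kymo, geometry, prominence_k = 4,
                          psf_fwhm_px = 2.75, edge_margin_px = 2,
                          min_prominence = 0) {
  stopifnot(inherits(kymo, "kymograph"),
            inherits(geometry, "molecule_geometry"))
  mat <- kymo$mat
  W <- ncol(mat)
  lo <- max(1, ceiling(geometry$end_left_px + edge_margin_px) + 1)
  hi <- min(W, floor(geometry$end_right_px - edge_margin_px) + 1)
  span <- lo:hi
  # molecule span expanded by the PSF tails, for the total-intensity sum;
  # pixels beyond it estimate the residual background pedestal per row
  tail_px <- ceiling(1.5 * psf_fwhm_px)
  mol_span <- max(1, floor(geometry$end_left_px) - tail_px + 1):
    min(W, ceiling(geometry$end_right_px) + tail_px + 1)
  outside <- setdiff(seq_len(W), mol_span)
  w_loc <- ceiling(psf_fwhm_px)
  w_int <- ceiling(1.5 * psf_fwhm_px)
  # normalized backbone shape: flat top between the ends, PSF-convolved
  sig <- psf_fwhm_px / (2 * sqrt(2 * log(2)))
  xs <- seq_len(W) - 1
  template <- stats::pnorm((geometry$end_right_px - xs) / sig) -
    stats::pnorm((geometry$end_left_px - xs) / sig)
  out <- vector("list", nrow(mat))
  n_rows <- nrow(mat)
  for (f in seq_len(n_rows)) {
    row <- mat[f, ]
    pedestal <- if (length(outside) >= 5) stats::median(row[outside]) else 0
    row_total <- sum(row[mol_span]) - pedestal * length(mol_span)
    # row baseline: backbone template scaled by the robust (median-ratio)
    # per-row amplitude; unlike a running median this neither flattens
    # peaks near the span edges nor dips under wide puncta
    amp0 <- stats::median(row[span] / template[span])
    base <- amp0 * template
    res <- row - base
    # robust row noise from the frame-to-frame difference (the running-
    # median residual is zero-inflated and would understate the noise)
    if (n_rows > 1) {
      f2 <- if (f > 1) f - 1L else 2L
      noise <- 1.4826 * stats::median(abs(row[span] - mat[f2, span])) /
        sqrt(2)
    } else {
      noise <- stats::mad(res[span])
    }
    thr <- max(prominence_k * noise, min_prominence, 1e-9)
    r <- res[span]
    n <- length(r)
    is_max <- r >= thr &
      r >= c(-Inf, r[-n]) & r > c(r[-1], -Inf)
    cand <- span[is_max]
    if (length(cand) == 0) { out[[f]] <- NULL; next }
    # enforce minimum separation, strongest first
    ord <- cand[order(res[cand], decreasing = TRUE)]
    kept <- numeric(0)
    for (i in ord)
      if (all(abs(i - kept) >= psf_fwhm_px)) kept <- c(kept, i)
    kept <- sort(kept)
    pos <- numeric(length(kept)); exc <- numeric(length(kept))
    prom <- res[kept]
    for (j in seq_along(kept)) {
      i <- kept[j]
      wl <- max(1, i - w_int); wr <- min(W, i + w_int)
      # local backbone baseline: the known backbone template (flat top
      # between the localized ends, convolved with the PSF) scaled to the
      # flanking punctum-free pixels.  Unlike a linear interpolation this
      # stays correct under the roll-off near the tether points, where a
      # mis-estimated baseline would otherwise bias end-proximal sizes.
      fl <- if (wl > 1) setdiff(max(1, wl - 8):(wl - 1), kept) else integer(0)
      fr <- if (wr < W) setdiff((wr + 1):min(W, wr + 8), kept) else integer(0)
      flank <- c(fl, fr)
      flank <- flank[template[flank] > 0.25]
      win <- wl:wr
      base2 <- if (length(flank) >= 3) {
        amp <- stats::median(row[flank] / template[flank])
        amp * template[win]
      } else base[win]
      # unclamped sum: clamping negative residuals would bias small sizes up
      exc[j] <- sum(row[win] - base2)
      # centroid over +/- 1 FWHM
      cl <- max(wl, i - w_loc); cr <- min(wr, i + w_loc)
      ci <- cl:cr
      dc <- pmax(0, row[ci] - base2[ci - wl + 1])
      pos[j] <- if (sum(dc) > 0) sum((ci - 1) * dc) / sum(dc) else i - 1
    }
    out[[f]] <- data.frame(frame = f - 1L, position_px = pos,
                           prominence = prom, excess = exc,
                           row_total = row_total)
  }
  res_df <- do.call(rbind, out)
  if (is.null(res_df))
    res_df <- data.frame(frame = integer(0), position_px = numeric(0),
                         prominence = numeric(0), excess = numeric(0),
                         row_total = numeric(0))
  res_df
}

#' Plectoneme size from excess punctum intensity
#'
#' The base-pair size of a punctum is the construct length times the fraction
#' of the row's total intensity found in the punctum above the local
#' backbone: `size_bp = total_bp * excess / row_total`.  Negative excess
#' yields size 0.
#'
#' @param excess excess (above-baseline) punctum intensity.
#' @param row_total total row intensity.
#' @param total_bp construct length, bp.
#' @return size in base pairs.
#' @export
size_from_intensity <- function(excess, row_total, total_bp) {
  ifelse(row_total > 0, total_bp * pmax(0, excess) / row_total, 0)
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame assignment minimizing total squared displacement under a
#' hard distance gate, with optional bridging of single missed frames
#' (flagged), and removal of tracks shorter than the minimum consecutive
#' lifetime.  Ties are resolved deterministically (lower track id wins).
#'
#' @param detections data frame from [detect_puncta()].
#' @param max_link_px hard gate on frame-to-frame displacement, px.
#' @param min_lifetime_frames minimum number of consecutive frames.
#' @param gap_frames bridge up to this many missed frames (default 1).
#' @return the detections with `track_id` and `gap_closed` columns, filtered
#'   to retained tracks.  The attribute `n_discarded_tracks` counts tracks
#'   dropped by the lifetime rule.
#' @export
link_tracks <- function(detections, max_link_px, min_lifetime_frames = 3,
                        gap_frames = 1) {
  d <- detections[order(detections$frame, detections$position_px), ,
                  drop = FALSE]
  n <- nrow(d)
  d$track_id <- rep(NA_integer_, n)
  d$gap_closed <- rep(FALSE, n)
  if (n > 0) {
    frames <- sort(unique(d$frame))
    # active track registry
    tr_id <- integer(0); tr_frame <- integer(0); tr_pos <- numeric(0)
    next_id <- 1L
    for (f in frames) {
      idx <- which(d$frame == f)
      pos <- d$position_px[idx]
      live <- which(f - tr_frame <= 1 + gap_frames & f > tr_frame)
      assigned <- rep(NA_integer_, length(idx))   # index into live
      if (length(live) > 0) {
        elapsed <- f - tr_frame[live]
        gate <- max_link_px * sqrt(elapsed)
        cost <- abs(outer(pos, tr_pos[live], "-"))
        ok <- sweep(cost, 2, gate, "<=")
        cost[!ok] <- Inf
        assigned <- assign_min_cost(cost^2)
      }
      for (j in seq_along(idx)) {
        a <- assigned[j]
        if (!is.na(a)) {
          k <- live[a]
          d$track_id[idx[j]] <- tr_id[k]
          d$gap_closed[idx[j]] <- (f - tr_frame[k]) > 1
          tr_frame[k] <- f; tr_pos[k] <- pos[j]
        } else {
          d$track_id[idx[j]] <- next_id
          tr_id <- c(tr_id, next_id)
          tr_frame <- c(tr_frame, f); tr_pos <- c(tr_pos, pos[j])
          next_id <- next_id + 1L
        }
      }
    }
  }
  # lifetime rule: the longest run of detections uninterrupted by more than
  # the bridged gap must reach the minimum (a bridged single-frame gap
  # counts as continuous presence, but is flagged above)
  keep_ids <- integer(0); dropped <- 0L
  for (id in unique(d$track_id)) {
    fr <- sort(d$frame[d$track_id == id])
    runs <- split(fr, cumsum(c(1, diff(fr) > 1 + gap_frames)))
    max_run <- max(vapply(runs, length, 0L))
    if (max_run >= min_lifetime_frames)
      keep_ids <- c(keep_ids, id) else dropped <- dropped + 1L
  }
  out <- d[d$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded_tracks") <- dropped
  out
}

# Minimum-total-cost one-to-one assignment of rows (detections) to columns
# (tracks) of a finite/Inf cost matrix.  Exhaustive for small problems,
# greedy beyond; deterministic tie-breaking by column (track) order.
assign_min_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0) return(integer(0))
  if (nc == 0) return(rep(NA_integer_, nr))
  if (max(nr, nc) <= 3) {
    # enumerate injective maps rows -> columns (with NA allowed via Inf)
    best <- NULL; best_cost <- Inf
    cols <- seq_len(nc)
    perms <- perm_subsets(cols, nr)
    for (p in seq_len(nrow(perms))) {
      sel <- perms[p, ]
      cc <- 0; ok_n <- 0
      for (r in seq_len(nr)) {
        cl <- sel[r]
        if (!is.na(cl) && is.finite(cost[r, cl])) {
          cc <- cc + cost[r, cl]; ok_n <- ok_n + 1
        }
      }
      # prefer more matches, then lower cost, then earlier columns
      score <- -ok_n * 1e12 + cc
      if (score < best_cost - 1e-12) { best_cost <- score; best <- sel }
    }
    res <- best
    for (r in seq_len(nr))
      if (!is.na(res[r]) && !is.finite(cost[r, res[r]])) res[r] <- NA_integer_
    return(res)
  }
  # greedy fallback
  res <- rep(NA_integer_, nr)
  used <- rep(FALSE, nc)
  ord <- order(apply(cost, 1, min))
  for (r in ord) {
    j <- which.min(ifelse(used, Inf, cost[r, ]))
    if (is.finite(cost[r, j]) && !used[j]) { res[r] <- j; used[j] <- TRUE }
  }
  res
}

# all injective assignments of `size` slots to values from `cols` or NA
perm_subsets <- function(cols, size) {
  opts <- c(NA_integer_, cols)
  grid <- do.call(expand.grid, rep(list(opts), size))
  grid <- as.matrix(grid)
  ok <- apply(grid, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) == length(unique(r))
  })
  grid[ok, , drop = FALSE]
}
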