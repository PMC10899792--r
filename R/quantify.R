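#' Position-resolved plectoneme density profile
#'
#' Histogram of all per-frame plectoneme positions, normalized per molecule
#' to a probability per bin, plus the pooled mean across molecules.  In
#' `mode = "relative"` positions are mapped per frame to a normalized
#' coordinate with the RNAP at 0 and the tether points at -1/+1.
#'
#' @param tracks track table (DNA channel; typically
#'   [reported_plectonemes()] output) with a `molecule` column (added if
#'   absent).
#' @param total_bp construct length, bp (needed for genomic bin edges).
#' @param bin_bp genomic bin width, bp.
#' @param mode `"genomic"` or `"relative"`.
#' @param rnap_positions for `mode = "relative"`: data frame
#'   (molecule, frame, position_bp) of RNAP positions, e.g. the RNAP channel
#'   of the track table.
#' @param n_bins_relative number of bins over \[-1, 1\] in relative mode.
#' @return a list of class `density_profile`: `edges`, `mids`,
#'   `per_molecule` (molecules x bins probability matrix), `pooled` (mean
#'   across molecules), `n_molecules`.  Empty input gives an empty profile.
#' @export
density_profile <- function(tracks, total_bp, bin_bp = 500,
                            mode = c("genomic", "relative"),
                            rnap_positions = NULL, n_bins_relative = 40) {
  mode <- match.arg(mode)
  tr <- as_molecule_table(tracks)
  if (mode == "genomic") {
    edges <- seq(0, total_bp + bin_bp, by = bin_bp)
    x <- tr$position_bp
  } else {
    if (is.null(rnap_positions))
      stop("relative mode needs rnap_positions (molecule, frame, position_bp)")
    edges <- seq(-1, 1, length.out = n_bins_relative + 1)
    key <- paste(tr$molecule, tr$frame)
    rk <- paste(rnap_positions$molecule, rnap_positions$frame)
    rn <- rnap_positions$position_bp[match(key, rk)]
    x <- ifelse(tr$position_bp >= rn,
                (tr$position_bp - rn) / pmax(total_bp - rn, 1),
                (tr$position_bp - rn) / pmax(rn, 1))
    keep <- !is.na(x)
    tr <- tr[keep, , drop = FALSE]; x <- x[keep]
  }
  mols <- unique(tr$molecule)
  per <- matrix(0, length(mols), length(edges) - 1,
                dimnames = list(mols, NULL))
  for (m in mols) {
    xi <- x[tr$molecule == m]
    h <- graphics::hist(pmin(pmax(xi, edges[1]), edges[length(edges)] - 1e-9),
                        breaks = edges, plot = FALSE)
    if (sum(h$counts) > 0) per[m, ] <- h$counts / sum(h$counts)
  }
  out <- list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
              per_molecule = per,
              pooled = if (nrow(per)) colMeans(per) else
                numeric(length(edges) - 1),
              n_molecules = length(mols), mode = mode)
  class(out) <- "density_profile"
  out
}

as_molecule_table <- function(tracks) {
  tr <- tracks
  if (!"molecule" %in% names(tr))
    tr$molecule <- rep("1", nrow(tr))
  tr
}

#' Distribution of the number of co-existing plectonemes
#'
#' Probability that `n` plectonemes are detected simultaneously in a frame,
#' pooled over molecules.  Frames without detections count as `n = 0`, so
#' the number of frames per molecule must be supplied (or is taken as
#' `max(frame) + 1`).
#'
#' @param tracks plectoneme track table (use [reported_plectonemes()]).
#' @param n_frames integer vector of frame counts, named by molecule
#'   (recycled if unnamed length-1).
#' @return data frame with columns `n` and `probability` (summing to 1).
#' @export
count_distribution <- function(tracks, n_frames = NULL) {
  tr <- as_molecule_table(tracks)
  mols <- unique(tr$molecule)
  if (length(mols) == 0) {
    if (is.null(n_frames) || sum(n_frames) == 0)
      return(data.frame(n = 0L, probability = 1))
    return(data.frame(n = 0L, probability = 1))
  }
  if (is.null(n_frames))
    n_frames <- stats::setNames(rep(max(tr$frame) + 1L, length(mols)), mols)
  if (is.null(names(n_frames)) && length(n_frames) == 1)
    n_frames <- stats::setNames(rep(n_frames, length(mols)), mols)
  counts <- integer(0)
  for (m in mols) {
    f <- tr$frame[tr$molecule == m]
    tab <- table(factor(f, levels = 0:(n_frames[[m]] - 1L)))
    counts <- c(counts, as.integer(tab))
  }
  tab <- table(counts)
  data.frame(n = as.integer(names(tab)),
             probability = as.numeric(tab) / sum(tab))
}

#' Plectoneme-RNAP colocalization
#'
#' Fraction of plectoneme detections lying within `tolerance_px` of the
#' same-frame RNAP position, plus the joint position histogram.  Frames with
#' no RNAP detection are excluded and counted.
#'
#' @param plectonemes plectoneme track table.
#' @param rnap RNAP track table (same molecules/frames).
#' @param tolerance_px colocalization tolerance, px (default 3, the
#'   motion-blur-limited localization accuracy).
#' @param bin_bp bin width of the joint histogram, bp.
#' @param total_bp construct length for the histogram axes.
#' @return list: `fraction`, `n_pairs`, `n_frames_no_rnap`, `joint` (2-D
#'   count matrix, RNAP x plectoneme position).
#' @export
colocalization <- function(plectonemes, rnap, tolerance_px = 3,
                           bin_bp = 1000, total_bp = NULL) {
  pl <- as_molecule_table(plectonemes)
  rn <- as_molecule_table(rnap)
  key_p <- paste(pl$molecule, pl$frame)
  key_r <- paste(rn$molecule, rn$frame)
  m <- match(key_p, key_r)
  miss_frames <- unique(key_p[is.na(m)])
  ok <- !is.na(m)
  dpx <- abs(pl$position_px[ok] - rn$position_px[m[ok]])
  joint <- NULL
  if (!is.null(total_bp)) {
    edges <- seq(0, total_bp + bin_bp, by = bin_bp)
    cut_p <- cut(pl$position_bp[ok], edges, include.lowest = TRUE)
    cut_r <- cut(rn$position_bp[m[ok]], edges, include.lowest = TRUE)
    joint <- table(rnap = cut_r, plectoneme = cut_p)
  }
  list(fraction = if (length(dpx)) mean(dpx <= tolerance_px) else NA_real_,
       n_pairs = length(dpx), n_frames_no_rnap = length(miss_frames),
       joint = joint)
}

#' Up/downstream supercoil partition fractions
#'
#' Per frame, the sizes of all plectonemes upstream (genomic position below
#' the RNAP position, after orientation normalization) and downstream are
#' summed; the upstream fraction is their ratio to the total.  RNAP gaps of
#' up to `interp_gap` frames are bridged by linear interpolation; frames
#' with zero total plectoneme size are skipped.  Reported are the
#' per-molecule time means and the pooled (molecule-weighted, primary) and
#' frame-weighted means with SDs.
#'
#' @param plectonemes plectoneme track table.
#' @param rnap RNAP track table.
#' @param interp_gap maximum RNAP gap bridged by interpolation, frames.
#' @return list of class `partition_summary`: `series` (per molecule/frame),
#'   `per_molecule`, `pooled` (mean, sd, n), `frame_weighted`.
#' @export
partition_fractions <- function(plectonemes, rnap, interp_gap = 2) {
  pl <- as_molecule_table(plectonemes)
  rn <- as_molecule_table(rnap)
  mols <- unique(pl$molecule)
  series <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    m <- mols[i]
    rni <- rn[rn$molecule == m, , drop = FALSE]
    if (nrow(rni) == 0)
      stop("no RNAP track for molecule '", m, "'")
    pli <- pl[pl$molecule == m, , drop = FALSE]
    frames <- sort(unique(pli$frame))
    # RNAP position per needed frame, interpolating short gaps
    rn_pos <- interp_series(rni$frame, rni$position_bp, frames, interp_gap)
    up <- dn <- rep(NA_real_, length(frames))
    for (j in seq_along(frames)) {
      if (is.na(rn_pos[j])) next
      sel <- pli$frame == frames[j]
      up[j] <- sum(pli$size_bp[sel & pli$position_bp < rn_pos[j]])
      dn[j] <- sum(pli$size_bp[sel & pli$position_bp >= rn_pos[j]])
    }
    tot <- up + dn
    keep <- !is.na(tot) & tot > 0
    series[[i]] <- data.frame(molecule = m, frame = frames[keep],
                              rnap_bp = rn_pos[keep], upstream_bp = up[keep],
                              downstream_bp = dn[keep],
                              upstream_fraction = up[keep] / tot[keep])
  }
  series <- do.call(rbind, series)
  per_mol <- do.call(rbind, lapply(split(series, series$molecule),
    function(s) data.frame(molecule = s$molecule[1],
                           n_frames = nrow(s),
                           mean_upstream = mean(s$upstream_fraction),
                           sd_upstream = stats::sd(s$upstream_fraction))))
  rownames(per_mol) <- NULL
  out <- list(
    series = series, per_molecule = per_mol,
    pooled = list(mean = mean(per_mol$mean_upstream),
                  sd = stats::sd(per_mol$mean_upstream),
                  n = nrow(per_mol)),
    frame_weighted = list(mean = mean(series$upstream_fraction),
                          sd = stats::sd(series$upstream_fraction),
                          n = nrow(series)))
  class(out) <- "partition_summary"
  out
}

interp_series <- function(frame, value, at, max_gap) {
  o <- order(frame)
  frame <- frame[o]; value <- value[o]
  out <- value[match(at, frame)]
  need <- which(is.na(out))
  for (j in need) {
    f <- at[j]
    below <- frame[frame < f]; above <- frame[frame > f]
    if (length(below) == 0 || length(above) == 0) next
    f0 <- max(below); f1 <- min(above)
    if (f1 - f0 - 1 > max_gap) next
    v0 <- value[frame == f0][1]; v1 <- value[frame == f1][1]
    out[j] <- v0 + (v1 - v0) * (f - f0) / (f1 - f0)
  }
  out
}

#' Total plectoneme size versus time
#'
#' Per-frame sum of plectoneme sizes (zero for frames without detections),
#' an optional moving-average display copy, and a least-squares linear
#' growth fit over a chosen time window.
#'
#' @param tracks plectoneme track table (single molecule, or pass a
#'   `molecule` to select one).
#' @param frame_interval_s frame interval, s.
#' @param n_frames total number of frames (default `max(frame) + 1`).
#' @param smooth_s moving-average window for the display copy, s (`NULL`
#'   disables).
#' @param fit_window length-2 time window (s) for the linear fit (`NULL`
#'   fits the whole series).
#' @param molecule optional molecule id to select.
#' @return list of class `size_series`: `series` (frame, time_s, total_bp,
#'   smoothed), `fit` (slope_bp_s, intercept, delta_bp over the window).
#'   Empty input yields an empty series.
#' @export
total_size_series <- function(tracks, frame_interval_s = 1, n_frames = NULL,
                              smooth_s = NULL, fit_window = NULL,
                              molecule = NULL) {
  tr <- as_molecule_table(tracks)
  if (!is.null(molecule)) tr <- tr[tr$molecule == molecule, , drop = FALSE]
  if (nrow(tr) == 0) {
    out <- list(series = data.frame(frame = integer(0), time_s = numeric(0),
                                    total_bp = numeric(0)), fit = NULL)
    class(out) <- "size_series"
    return(out)
  }
  if (is.null(n_frames)) n_frames <- max(tr$frame) + 1L
  tot <- rep(0, n_frames)
  agg <- tapply(tr$size_bp, tr$frame, sum)
  tot[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  s <- data.frame(frame = seq_len(n_frames) - 1L,
                  time_s = (seq_len(n_frames) - 1L) * frame_interval_s,
                  total_bp = tot)
  if (!is.null(smooth_s)) {
    k <- max(1L, round(smooth_s / frame_interval_s))
    if (k %% 2 == 0) k <- k + 1L
    s$smoothed <- as.numeric(stats::filter(s$total_bp, rep(1 / k, k),
                                           sides = 2))
  }
  sel <- if (is.null(fit_window)) rep(TRUE, n_frames) else
    s$time_s >= fit_window[1] & s$time_s <= fit_window[2]
  fit <- stats::lm(total_bp ~ time_s, data = s[sel, , drop = FALSE])
  co <- stats::coef(fit)
  tw <- range(s$time_s[sel])
  out <- list(series = s,
              fit = list(slope_bp_s = unname(co[2]),
                         intercept_bp = unname(co[1]),
                         delta_bp = unname(co[2]) * diff(tw),
                         window_s = tw))
  class(out) <- "size_series"
  out
}

#' After/Before treatment-epoch ratio
#'
#' Mean total plectoneme size after a treatment marker divided by the mean
#' before it.
#'
#' @param series data frame with `time_s` and `total_bp` (e.g.
#'   `total_size_series()$series`).
#' @param t_split treatment marker time, s.
#' @param min_frames minimum frames required in each epoch (default 10).
#' @return list: `ratio`, `mean_before`, `mean_after`, `n_before`,
#'   `n_after`.
#' @export
epoch_ratio <- function(series, t_split, min_frames = 10) {
  before <- series$total_bp[series$time_s < t_split]
  after <- series$total_bp[series$time_s >= t_split]
  if (length(before) < min_frames || length(after) < min_frames)
    stop("epochs too short: need >= ", min_frames, " frames on each side")
  list(ratio = mean(after) / mean(before),
       mean_before = mean(before), mean_after = mean(after),
       n_before = length(before), n_after = length(after))
}

#' Diffusion constant from mean squared displacement
#'
#' Per track, the time-averaged MSD over the first `n_lags` lags is fitted
#' by weighted least squares to `MSD = 2 D tau + offset`; the intercept
#' absorbs the localization-error offset.  Fitting few lags keeps the
#' estimate in the short-time regime where confinement between the tether
#' points has not yet bent the MSD.  Tracks shorter than
#' `min_track_frames` are skipped and counted; tracks whose MSD is better
#' described by ballistic drift (significant positive curvature) are
#' flagged.
#'
#' @param tracks track table with `position_px`, `frame` (one or more
#'   tracks; `molecule`/`track_id` identify tracks).
#' @param pixel_size_nm pixel size, nm.
#' @param frame_interval_s frame interval, s.
#' @param n_lags number of MSD lags fitted.
#' @param min_track_frames minimum track length used.
#' @param weighted weight lag `k` by the number of contributing pairs / k.
#' @return list of class `diffusion_estimate`: `D_um2_s` (pooled mean),
#'   `sd`, `per_track` (D, intercept, n, drift flag), `n_skipped`.
#' @export
diffusion_constant <- function(tracks, pixel_size_nm = 109,
                               frame_interval_s = 1, n_lags = 10,
                               min_track_frames = 20, weighted = TRUE) {
  tr <- as_molecule_table(tracks)
  key <- paste(tr$molecule, tr$track_id)
  per <- list()
  n_skipped <- 0L
  for (k in unique(key)) {
    s <- tr[key == k, , drop = FALSE]
    s <- s[order(s$frame), , drop = FALSE]
    if (nrow(s) < min_track_frames) { n_skipped <- n_skipped + 1L; next }
    x <- rep(NA_real_, max(s$frame) - min(s$frame) + 1L)
    x[s$frame - min(s$frame) + 1L] <- s$position_px * pixel_size_nm / 1000
    lags <- seq_len(min(n_lags, length(x) - 1))
    msd <- vapply(lags, function(L) {
      d <- (x[seq_len(length(x) - L) + L] - x[seq_len(length(x) - L)])^2
      mean(d, na.rm = TRUE)
    }, 0)
    npairs <- vapply(lags, function(L) {
      d <- x[seq_len(length(x) - L) + L] - x[seq_len(length(x) - L)]
      sum(!is.na(d))
    }, 0)
    tau <- lags * frame_interval_s
    wts <- if (weighted) npairs / lags else rep(1, length(lags))
    fit <- stats::lm(msd ~ tau, weights = wts)
    co <- stats::coef(fit)
    drift <- FALSE
    if (length(tau) >= 4) {
      fq <- stats::lm(msd ~ tau + I(tau^2), weights = wts)
      # perfect fits (deterministic drift) are legitimate here
      cq <- suppressWarnings(summary(fq))$coefficients
      if (nrow(cq) >= 3 && !is.na(cq[3, 4]))
        drift <- cq[3, 1] > 0 && cq[3, 4] < 0.01 &&
          cq[3, 1] * max(tau)^2 > 0.5 * abs(cq[2, 1]) * max(tau)
    }
    per[[k]] <- data.frame(track = k, D_um2_s = unname(co[2]) / 2,
                           intercept_um2 = unname(co[1]),
                           n_frames = nrow(s), drift = drift)
  }
  per <- do.call(rbind, per)
  out <- list(
    D_um2_s = if (!is.null(per)) mean(per$D_um2_s) else NA_real_,
    sd = if (!is.null(per) && nrow(per) > 1) stats::sd(per$D_um2_s) else
      NA_real_,
    per_track = per, n_skipped = n_skipped)
  class(out) <- "diffusion_estimate"
  out
}

#' Supercoil relaxation time after a nicking event
#'
#' Time from the nick until the total plectoneme size first falls below
#' `threshold_frac` of its pre-nick mean.
#'
#' @param series data frame with `time_s` and `total_bp`.
#' @param nick_time_s time of the nick, s.
#' @param threshold_frac decay threshold as a fraction of the pre-nick mean
#'   (default 0.1).
#' @return list: `relaxation_s` (NA when unresolved), `resolved`,
#'   `pre_nick_mean_bp`.
#' @export
relaxation_time <- function(series, nick_time_s, threshold_frac = 0.1) {
  if (nrow(series) == 0 || all(series$total_bp == 0))
    return(list(relaxation_s = NA_real_, resolved = FALSE,
                pre_nick_mean_bp = NA_real_))
  pre <- series$total_bp[series$time_s < nick_time_s]
  if (length(pre) == 0) stop("no frames before the nick")
  ref <- mean(pre)
  post <- series[series$time_s >= nick_time_s, , drop = FALSE]
  idx <- which(post$total_bp < threshold_frac * ref)
  if (length(idx) == 0)
    return(list(relaxation_s = NA_real_, resolved = FALSE,
                pre_nick_mean_bp = ref))
  list(relaxation_s = post$time_s[idx[1]] - nick_time_s, resolved = TRUE,
       pre_nick_mean_bp = ref)
}

#' Median relaxation time over several nicking events
#'
#' @param series_list list of series data frames (see [relaxation_time()]).
#' @param nick_times_s nick time per series (recycled).
#' @param threshold_frac decay threshold.
#' @return list: `median_s`, `times_s`, `n_unresolved`.
#' @export
relaxation_times <- function(series_list, nick_times_s,
                             threshold_frac = 0.1) {
  nick_times_s <- rep_len(nick_times_s, length(series_list))
  res <- mapply(function(s, t0)
    relaxation_time(s, t0, threshold_frac)$relaxation_s,
    series_list, nick_times_s)
  list(median_s = stats::median(res, na.rm = TRUE), times_s = res,
       n_unresolved = sum(is.na(res)))
}

#' Unpaired two-tailed t-test
#'
#' Welch's unequal-variance test by default (Student's pooled-variance test
#' via `var_equal = TRUE`).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param var_equal assume equal variances.
#' @return list: `t`, `dof`, `p`.
#' @export
ttest_unpaired <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, dof = length(a) + length(b) - 2, p = 1))
  ht <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = unname(ht$p.value))
}
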