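fake_tracks <- function(position_bp, frame = seq_along(position_bp) - 1,
                        size_bp = 3000, molecule = "1", channel = "dna",
                        track_id = 1L) {
  data.frame(molecule = molecule, channel = channel, track_id = track_id,
             frame = frame, time_s = frame, position_px = position_bp / 100,
             position_bp = position_bp, size_bp = size_bp,
             below_floor = FALSE)
}

test_that("density profiles normalize per molecule and handle edge cases", {
  tr <- fake_tracks(10500, frame = 0)
  dp <- density_profile(tr, total_bp = 21000, bin_bp = 500)
  expect_equal(sum(dp$per_molecule[1, ]), 1)
  expect_equal(sum(dp$per_molecule[1, ] > 0), 1)  # delta profile
  # empty input: empty profile, not an exception
  dp0 <- density_profile(tr[0, ], total_bp = 21000)
  expect_equal(dp0$n_molecules, 0)
  # uniform positions: flat pooled profile within 3-sigma binomial bands
  set.seed(1)
  x <- runif(20000, 1200, 19800)
  dpu <- density_profile(fake_tracks(x), total_bp = 21000, bin_bp = 1860)
  inner <- dpu$mids > 1860 & dpu$mids < 21000 - 2 * 1860
  p0 <- 1860 / (19800 - 1200)
  band <- 3 * sqrt(p0 * (1 - p0) / 20000)
  expect_true(all(abs(dpu$pooled[inner] - p0) < band + 0.002))
})

test_that("relative-coordinate densities put the RNAP at zero", {
  tr <- fake_tracks(c(5000, 25000), frame = c(0, 0))
  rn <- data.frame(molecule = "1", frame = 0, position_bp = 10000)
  dp <- density_profile(tr, 31000, mode = "relative", rnap_positions = rn,
                        n_bins_relative = 10)
  expect_equal(sum(dp$pooled), 1)
  # 5000 -> (5000-10000)/10000 = -0.5 ; 25000 -> 15000/21000 = +0.71
  occ <- which(dp$pooled > 0)
  expect_equal(dp$mids[occ], c(-0.5, 0.7), tolerance = 0.11)
})

test_that("plectoneme count distribution pools frames correctly", {
  expect_equal(count_distribution(fake_tracks(1000)[0, ], n_frames = 5),
               data.frame(n = 0L, probability = 1))
  tr <- rbind(fake_tracks(c(5000, 5100, 15000, 15100),
                          frame = c(0, 1, 0, 1), track_id = c(1, 1, 2, 2)))
  cd <- count_distribution(tr, n_frames = c("1" = 4))
  expect_equal(cd$probability[cd$n == 2], 0.5)
  expect_equal(cd$probability[cd$n == 0], 0.5)
  expect_equal(sum(cd$probability), 1)
})

test_that("colocalization fractions hit the trivial limits", {
  pl <- fake_tracks(rep(8000, 5))
  rn <- fake_tracks(rep(8000, 5), channel = "rnap")
  expect_equal(colocalization(pl, rn)$fraction, 1)
  rn2 <- fake_tracks(rep(20000, 5), channel = "rnap")
  expect_equal(colocalization(pl, rn2)$fraction, 0)
  # frames without RNAP are excluded and counted
  co <- colocalization(pl, rn[1:3, ])
  expect_equal(co$n_pairs, 3)
  expect_equal(co$n_frames_no_rnap, 2)
})

test_that("partition fractions: trivial split, frame-wise closure, errors", {
  pl <- fake_tracks(rep(5000, 6), size_bp = 4000)
  rn <- fake_tracks(rep(10000, 6), channel = "rnap")
  pf <- partition_fractions(pl, rn)
  expect_true(all(pf$series$upstream_fraction == 1))
  expect_equal(pf$pooled$mean, 1)
  both <- rbind(fake_tracks(rep(5000, 6), size_bp = 3000, track_id = 1),
                fake_tracks(rep(15000, 6), size_bp = 1500, track_id = 2))
  pf2 <- partition_fractions(both, rn)
  expect_true(all(abs(pf2$series$upstream_bp + pf2$series$downstream_bp -
                        4500) < 1e-9))
  expect_equal(pf2$pooled$mean, 3000 / 4500)
  expect_error(partition_fractions(pl, rn[rn$molecule == "none", ]),
               "no RNAP")
})

test_that("RNAP gaps up to two frames are interpolated", {
  pl <- fake_tracks(rep(5000, 7))
  rn <- fake_tracks(c(10000, 10600), frame = c(0, 6), channel = "rnap")
  pf <- partition_fractions(pl, rn)     # 5-frame gap: not bridged
  expect_equal(nrow(pf$series), 2)
  rn2 <- fake_tracks(c(10000, 10300), frame = c(0, 3), channel = "rnap")
  pf2 <- partition_fractions(pl[1:4, ], rn2)
  expect_equal(nrow(pf2$series), 4)
  expect_equal(pf2$series$rnap_bp, c(10000, 10100, 10200, 10300))
})

test_that("total-size series fits growth and degenerates gracefully", {
  tr <- fake_tracks(rep(8000, 50), size_bp = 100 + 20 * (0:49))
  ss <- total_size_series(tr, frame_interval_s = 1)
  expect_equal(ss$fit$slope_bp_s, 20, tolerance = 1e-9)
  flat <- fake_tracks(rep(8000, 50), size_bp = 4000)
  expect_equal(total_size_series(flat, 1)$fit$slope_bp_s, 0,
               tolerance = 1e-9)
  expect_equal(nrow(total_size_series(flat[0, ], 1)$series), 0)
})

test_that("epoch ratio is directional and reciprocal under time reversal", {
  t <- 0:99
  grow <- data.frame(time_s = t, total_bp = 100 + 10 * t)
  er <- epoch_ratio(grow, 50)
  expect_gt(er$ratio, 1)
  flat <- data.frame(time_s = t, total_bp = rep(500, 100))
  expect_equal(epoch_ratio(flat, 50)$ratio, 1)
  decay <- data.frame(time_s = t, total_bp = 1000 - 9 * t)
  expect_lt(epoch_ratio(decay, 50)$ratio, 1)
  rev <- data.frame(time_s = t, total_bp = rev(grow$total_bp))
  expect_equal(epoch_ratio(rev, 50)$ratio, 1 / er$ratio, tolerance = 0.02)
  expect_error(epoch_ratio(grow, 3), "epochs too short")
})

test_that("MSD estimator: stationary tracks give D ~ 0 and drift is flagged", {
  still <- fake_tracks(rep(8000, 60))
  de <- diffusion_constant(still, frame_interval_s = 1, n_lags = 5)
  expect_lt(abs(de$D_um2_s), 1e-9)
  drift <- fake_tracks(8000 + 200 * (0:59))   # ballistic, 2 px/frame
  dd <- diffusion_constant(drift, frame_interval_s = 1, n_lags = 10)
  expect_true(dd$per_track$drift[1])
  # too-short tracks are skipped and counted
  short <- fake_tracks(rep(8000, 5))
  ds <- diffusion_constant(short, min_track_frames = 20)
  expect_equal(ds$n_skipped, 1)
  expect_true(is.na(ds$D_um2_s))
})

test_that("relaxation time matches the closed-form threshold crossing", {
  t <- seq(0, 40, by = 0.5)
  nick <- 10
  v <- ifelse(t < nick, 1000, 1000 * exp(-(t - nick) / 5))
  s <- data.frame(time_s = t, total_bp = v)
  rt <- relaxation_time(s, nick)
  # ln(10) * 5 = 11.51 s; first 2-Hz sample below threshold is 12.0 s
  expect_equal(rt$relaxation_s, 12)
  expect_true(rt$resolved)
  # instantaneous decay resolves within one frame interval
  vi <- ifelse(t <= nick, 1000, 0)
  expect_equal(relaxation_time(data.frame(time_s = t, total_bp = vi),
                               nick + 0.01)$relaxation_s, 0.49,
               tolerance = 0.011)
  # non-decaying series is flagged unresolved
  rflat <- relaxation_time(data.frame(time_s = t, total_bp = 1000), nick)
  expect_false(rflat$resolved)
  expect_true(is.na(rflat$relaxation_s))
  # median over events
  rr <- relaxation_times(list(s, s), nick)
  expect_equal(rr$median_s, 12)
})

test_that("unpaired two-tailed t-test behaves at the limits", {
  expect_equal(ttest_unpaired(c(1, 1, 1), c(1, 1, 1)),
               list(t = 0, dof = 4, p = 1))
  sep <- ttest_unpaired(c(0, 0.01, -0.01, 0), c(1, 1.01, 0.99, 1))
  expect_lt(sep$p, 1e-6)
  same <- ttest_unpaired(rnorm(20), rnorm(20, sd = 1.000001))
  expect_true(is.finite(same$p))
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
})
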