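test_that("size follows excess-intensity proportionality", {
  # a punctum holding 10% of the row intensity on a 31-kb construct
  expect_equal(size_from_intensity(10, 100, 31000), 3100)
  expect_equal(size_from_intensity(-3, 100, 31000), 0)   # negative -> 0
  expect_equal(size_from_intensity(5, 0, 31000), 0)
})

test_that("backbone-only fixtures yield almost no detections", {
  mol <- molecule_spec(21000)
  dyn <- dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                       termination_rate = 0)
  truth <- simulate_plectonemes(mol, dyn, 2 * 149, 2, seed = 21)
  st <- render_stack(truth, render_spec(), seed = 22)
  an <- analyze_stack(st)
  det <- an$tracks[an$tracks$channel == "dna", ]
  frames_with_det <- length(unique(det$frame))
  expect_lte(frames_with_det / 150, 0.01)
})

test_that("a single large plectoneme is found in nearly every frame within 3 px", {
  fix <- diffusing_fixture(23, n_frames = 150, plect_size = 8000)
  st <- render_stack(fix$truth, render_spec(frame_interval_s = 2), seed = 24)
  an <- analyze_stack(st)
  pl <- reported_plectonemes(an$tracks)
  ob <- fix$truth$objects[fix$truth$objects$kind == "plectoneme", ]
  counts <- table(factor(pl$frame, levels = 0:149))
  expect_gte(mean(counts == 1), 0.9)
  err_px <- (pl$position_bp -
               ob$position_bp[match(pl$frame, ob$frame)]) /
    an$geometry$bp_per_px
  expect_lte(sqrt(mean(err_px^2)), 3)
  # detected sizes never exceed the construct length, frame-wise
  expect_true(all(tapply(pl$size_bp, pl$frame, sum) <= 21000))
  # tracks stay within the localized geometry span
  expect_true(all(pl$position_px >= an$geometry$end_left_px &
                    pl$position_px <= an$geometry$end_right_px))
})

test_that("two well-separated plectonemes give two matched detections", {
  mol <- molecule_spec(31000, promoter_bp = 8000)
  ob <- static_objects(20, plect_bp = c(8000, 22000),
                       plect_size = c(5000, 6000), frame_interval_s = 2)
  truth <- make_truth(mol, ob, frame_interval_s = 2)
  st <- render_stack(truth, render_spec(frame_interval_s = 2), seed = 31)
  an <- analyze_stack(st)
  pl <- reported_plectonemes(an$tracks)
  counts <- table(factor(pl$frame, levels = 0:19))
  expect_gte(mean(counts == 2), 0.9)
  near <- function(bp) pl[abs(pl$position_bp - bp) < 2500, ]
  expect_gt(nrow(near(8000)), 15)
  expect_gt(nrow(near(22000)), 15)
  expect_equal(mean(near(8000)$size_bp), 5000, tolerance = 0.15)
  expect_equal(mean(near(22000)$size_bp), 6000, tolerance = 0.15)
})

test_that("linking builds one full-length track for a stationary punctum", {
  det <- data.frame(frame = 0:9, position_px = 30 + 0.01 * (0:9),
                    prominence = 10, excess = 100, row_total = 1000)
  tr <- link_tracks(det, max_link_px = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("puncta alive for under three consecutive frames are dropped", {
  det <- data.frame(frame = c(0, 1), position_px = c(30, 30.2),
                    prominence = 10, excess = 100, row_total = 1000)
  tr <- link_tracks(det, max_link_px = 5)
  expect_equal(nrow(tr), 0)
  expect_equal(attr(tr, "n_discarded_tracks"), 1)
})

test_that("crossing trajectories conserve detections and link deterministically", {
  fr <- 0:10
  det <- rbind(
    data.frame(frame = fr, position_px = 20 + 2 * fr, prominence = 10,
               excess = 100, row_total = 1000),
    data.frame(frame = fr, position_px = 40 - 2 * fr, prominence = 10,
               excess = 100, row_total = 1000))
  tr1 <- link_tracks(det, max_link_px = 6)
  tr2 <- link_tracks(det, max_link_px = 6)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), nrow(det))   # all detections retained
  expect_equal(length(unique(tr1$track_id)), 2)
})

test_that("single missed frames are bridged and flagged", {
  det <- data.frame(frame = c(0, 1, 3, 4), position_px = c(30, 30, 31, 31),
                    prominence = 10, excess = 100, row_total = 1000)
  tr <- link_tracks(det, max_link_px = 5, gap_frames = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_true(any(tr$gap_closed))
  # with gap closing disabled the fragments die by the lifetime rule
  tr0 <- link_tracks(det, max_link_px = 5, gap_frames = 0)
  expect_equal(nrow(tr0), 0)
})
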