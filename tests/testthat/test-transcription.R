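test_that("degenerate split sends all injected supercoil upstream", {
  mol <- molecule_spec(31000, promoter_bp = 8000)
  dyn <- dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                       termination_rate = 0)
  tx <- transcription_spec(start_time_s = 0, upstream_fraction = 1)
  tr <- simulate_transcription(mol, dyn, tx, 200, 1, seed = 2)
  fr <- tr$frames
  expect_true(all(fr$downstream_bp == 0, na.rm = TRUE))
  expect_gt(max(fr$upstream_bp, na.rm = TRUE), 3000)
  pl <- tr$objects[tr$objects$kind == "plectoneme", ]
  rn <- tr$objects[tr$objects$kind == "rnap", ]
  rn_at <- rn$position_bp[match(pl$frame, rn$frame)]
  expect_true(all(pl$position_bp < rn_at))
})

test_that("injection rate reproduces the ~4 kb total-size growth in 220 s", {
  mol <- molecule_spec(31000, promoter_bp = 8000)
  dyn <- dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                       termination_rate = 0)
  tx <- transcription_spec(start_time_s = 10,
                           injection_rate_bp_s = 4000 / 220)
  tr <- simulate_transcription(mol, dyn, tx, 240, 1, seed = 3)
  fr <- tr$frames
  d <- fr$total_plectoneme_bp[fr$time_s == 230] -
    fr$total_plectoneme_bp[fr$time_s == 10]
  expect_lt(abs(d - 4000), 50)   # quantized per helical turn
})

test_that("symmetric injection yields a 0.5 truth partition within binomial noise", {
  mol <- molecule_spec(31000, promoter_bp = 8000)
  dyn <- dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                       termination_rate = 0)
  tx <- transcription_spec(start_time_s = 0, upstream_fraction = 0.5)
  tr <- simulate_transcription(mol, dyn, tx, 300, 1, seed = 7)
  fr <- tr$frames
  n <- nrow(fr)
  f_up <- fr$upstream_bp[n] / (fr$upstream_bp[n] + fr$downstream_bp[n])
  n_quanta <- (fr$upstream_bp[n] + fr$downstream_bp[n]) / 10.5
  expect_lt(abs(f_up - 0.5), 4 * sqrt(0.25 / n_quanta))
})

test_that("plectonemes respect the RNAP barrier and RNAP advances monotonically", {
  mol <- molecule_spec(31000, promoter_bp = 8000)
  dyn <- dynamics_spec(total_supercoiled_bp = 6000, nucleation_rate = 0,
                       termination_rate = 0)
  tx <- transcription_spec(start_time_s = 50, rnase_time_s = 200)
  tr <- simulate_transcription(mol, dyn, tx, 300, 1, seed = 8)
  ob <- tr$objects
  rn <- ob[ob$kind == "rnap", ]
  expect_true(all(diff(rn$position_bp) >= 0))
  pl <- ob[ob$kind == "plectoneme", ]
  started <- pl$time_s >= 50
  rn_at <- rn$position_bp[match(pl$frame, rn$frame)]
  expect_true(all(abs(pl$position_bp - rn_at)[started] >= 1500 - 1e-9))
  expect_setequal(unique(tr$frames$epoch),
                  c("pre_ntp", "transcription", "post_treatment"))
})

test_that("a nick decays plectoneme sizes exponentially", {
  fix <- pinned_fixture(4, n_frames = 100, frame_interval_s = 1)
  tr <- apply_nick(fix$truth, nick_time_s = 50, tau_s = 5)
  fr <- tr$frames
  expect_equal(fr$total_plectoneme_bp[fr$time_s == 50], 9000)
  expect_equal(fr$total_plectoneme_bp[fr$time_s == 60],
               9000 * exp(-10 / 5), tolerance = 1e-10)
})
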