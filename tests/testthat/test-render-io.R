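test_that("a backbone-only truth renders a flat-top noiseless profile", {
  mol <- molecule_spec(21000)
  # frames with zero plectonemes (an RNAP row defines the frame set)
  ob <- data.frame(frame = 0:2, time_s = 0:2, id = 0L, kind = "rnap",
                   position_bp = 10000, size_bp = NA_real_)
  truth <- make_truth(mol, ob)
  st <- render_stack(truth, render_spec(frame_interval_s = 1), noise = FALSE)
  ky <- build_kymograph(st, "dna")
  row <- ky$mat[1, ]
  interior <- seq(ceiling(mol$tether_px[1]) + 6,
                  floor(mol$tether_px[2]) - 6)
  expect_lt(diff(range(row[interior])) / mean(row[interior]), 1e-3)
  # expected integrated signal proportional to total_bp
  expect_equal(sum(row), 21000 * 0.12, tolerance = 1e-6)
})

test_that("noiseless total intensity is invariant to plectoneme arrangement", {
  fix <- diffusing_fixture(2, n_frames = 40)
  st <- render_stack(fix$truth, render_spec(), noise = FALSE)
  tots <- apply(st$channels$dna, 3, sum)
  expect_lt(diff(range(tots)) / mean(tots), 0.001)
})

test_that("rendering is bit-identical under a fixed seed", {
  fix <- diffusing_fixture(5, n_frames = 10)
  a <- render_stack(fix$truth, render_spec(), seed = 42)
  b <- render_stack(fix$truth, render_spec(), seed = 42)
  expect_identical(a$channels, b$channels)
  c <- render_stack(fix$truth, render_spec(), seed = 43)
  expect_false(identical(a$channels$dna, c$channels$dna))
})

test_that("saturated pixels are reported, not silently clipped", {
  fix <- pinned_fixture(1, n_frames = 3)
  rs <- render_spec(rnap_photons = 1e7, frame_interval_s = 2)
  expect_warning(st <- render_stack(fix$truth, rs, seed = 1), "saturated")
  expect_gt(st$n_saturated, 0)
  expect_lte(max(st$channels$rnap), 65535)
})

test_that("fixtures round-trip exactly through TIFF + JSON + CSV", {
  fix <- pinned_fixture(2, n_frames = 5)
  st <- render_stack(fix$truth, render_spec(frame_interval_s = 2), seed = 9)
  d <- file.path(tempdir(), "fixture_roundtrip")
  unlink(d, recursive = TRUE)
  write_fixture(st, fix$truth, d)
  back <- read_fixture(d)
  expect_identical(dim(back$stack$channels$dna), dim(st$channels$dna))
  expect_true(all(back$stack$channels$dna == st$channels$dna))
  expect_true(all(back$stack$channels$rnap == st$channels$rnap))
  # ledger bookkeeping: one plectoneme + one RNAP row per frame
  expect_equal(nrow(back$objects), 5 * 2)
  # refuse accidental overwrite
  expect_error(write_fixture(st, fix$truth, d), "overwrite")
  expect_silent(write_fixture(st, fix$truth, d, overwrite = TRUE))
  # missing directories are created recursively
  d2 <- file.path(tempdir(), "no", "such", "dir")
  unlink(file.path(tempdir(), "no"), recursive = TRUE)
  write_fixture(st, NULL, d2)
  expect_true(file.exists(file.path(d2, "stack.tif")))
})
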