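test_that("zero diffusion keeps a plectoneme exactly in place", {
  fix <- diffusing_fixture(3, n_frames = 50, D = 0)
  ob <- fix$truth$objects
  pl <- ob[ob$kind == "plectoneme", ]
  expect_equal(length(unique(pl$position_bp)), 1)
  expect_equal(nrow(pl), 50)
})

test_that("truth-level MSD over the first lags recovers the input D", {
  # long, well-extended molecule sampled at 2 Hz: short-lag fitting stays in
  # the regime where confinement between the tethers is negligible
  mol <- molecule_spec(38000, extension = 0.95)
  dyn <- dynamics_spec(diffusion_um2_s = 0.5, nucleation_rate = 0,
                       termination_rate = 0, total_supercoiled_bp = 8000,
                       n_init = 1)
  D_one <- function(seed) {
    truth <- simulate_plectonemes(mol, dyn, duration_s = 0.1 * 1999,
                                  frame_interval_s = 0.1, seed = seed)
    ob <- truth$objects[truth$objects$kind == "plectoneme", ]
    x_um <- ob$position_bp * mol$nm_per_bp / 1000
    msd <- vapply(1:10, function(L)
      mean((x_um[-(1:L)] - x_um[seq_len(length(x_um) - L)])^2), 0)
    fit <- stats::lm(msd ~ tau, data.frame(tau = (1:10) * 0.1, msd = msd))
    unname(coef(fit)[2]) / 2
  }
  D_hat <- mean(vapply(11:14, D_one, 0))   # 4 independent trajectories
  expect_lt(abs(D_hat - 0.5) / 0.5, 0.2)
})

test_that("supercoiled base pairs are conserved between pool and plectonemes", {
  mol <- molecule_spec(21000)
  dyn <- dynamics_spec(nucleation_rate = 0.1, termination_rate = 0.05,
                       total_supercoiled_bp = 6000)
  truth <- simulate_plectonemes(mol, dyn, 300, 2, seed = 5)
  fr <- truth$frames
  expect_true(all(abs(fr$total_plectoneme_bp + fr$pool_bp - 6000) < 1e-6))
  # reflected-walk support: no truth position outside the allowed span
  pl <- truth$objects[truth$objects$kind == "plectoneme", ]
  expect_true(all(pl$position_bp >= 1200 & pl$position_bp <= 21000 - 1200))
})

test_that("pinning merges everything into one immobile plectoneme", {
  fix <- pinned_fixture(7, n_frames = 60)
  pl <- fix$truth$objects[fix$truth$objects$kind == "plectoneme", ]
  expect_equal(nrow(pl), 60)              # exactly one per frame
  expect_true(all(pl$position_bp == 8029))
  expect_true(all(pl$size_bp == 9000))
})

test_that("simulation guards reject invalid stepping and pinning", {
  mol <- molecule_spec(21000)
  dyn <- dynamics_spec(pinned_site_bp = 500)  # inside the exclusion zone
  expect_error(simulate_plectonemes(mol, dyn, 10, 2, seed = 1), "exclusion")
  dyn2 <- dynamics_spec(diffusion_um2_s = 40)
  expect_error(simulate_plectonemes(mol, dyn2, 10, 2, dt_s = 2, seed = 1),
               "RMS")
  expect_error(simulate_plectonemes(mol, dynamics_spec(), 10,
                                    frame_interval_s = 1, dt_s = 2,
                                    seed = 1), "exceed")
})

test_that("identical seeds give identical trajectories", {
  a <- diffusing_fixture(9, n_frames = 30)$truth
  b <- diffusing_fixture(9, n_frames = 30)$truth
  expect_identical(a$objects, b$objects)
  c <- diffusing_fixture(10, n_frames = 30)$truth
  expect_false(identical(a$objects$position_bp, c$objects$position_bp))
})

test_that("binomial fluctuation of the truth partition shrinks with time", {
  sd_at <- function(dur) {
    f <- vapply(1:8, function(i) {
      mol <- molecule_spec(31000, promoter_bp = 8000)
      dyn <- dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                           termination_rate = 0)
      tx <- transcription_spec(start_time_s = 0)
      tr <- simulate_transcription(mol, dyn, tx, dur, 2, seed = 100 + i)
      fr <- tr$frames
      n <- nrow(fr)
      fr$upstream_bp[n] / (fr$upstream_bp[n] + fr$downstream_bp[n])
    }, 0)
    stats::sd(f)
  }
  r <- sd_at(100) / sd_at(400)
  expect_gt(r, 1.1)   # ~2 expected for 4x the injected quanta
  expect_lt(r, 4.5)
})
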