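# Fixture builders shared across test files.  Everything is generated in
# code; no stored image data.

# Construct a ground_truth object from explicit per-frame object tables,
# for fixtures where full control over positions/sizes is needed.
make_truth <- function(mol, objects, frame_interval_s = 1) {
  frames <- sort(unique(objects$frame))
  pl <- objects[objects$kind == "plectoneme", , drop = FALSE]
  tot <- vapply(frames, function(f) sum(pl$size_bp[pl$frame == f]), 0)
  fr <- data.frame(frame = frames, time_s = frames * frame_interval_s,
                   total_plectoneme_bp = tot, pool_bp = 0,
                   epoch = "fixture", rnap_bp = NA_real_)
  plectotrack:::new_ground_truth(mol, objects, fr, frame_interval_s,
                                 max(frames) * frame_interval_s,
                                 list(), seed = NA)
}

# n_frames of a static plectoneme (and optional RNAP) as an object table
static_objects <- function(n_frames, plect_bp, plect_size,
                           rnap_bp = NULL, frame_interval_s = 1) {
  rows <- list()
  for (f in seq_len(n_frames) - 1L) {
    k <- length(plect_bp)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = rep(f, k + !is.null(rnap_bp)),
      time_s = rep(f * frame_interval_s, k + !is.null(rnap_bp)),
      id = c(seq_len(k), if (!is.null(rnap_bp)) 0L),
      kind = c(rep("plectoneme", k), if (!is.null(rnap_bp)) "rnap"),
      position_bp = c(plect_bp, rnap_bp),
      size_bp = c(plect_size, if (!is.null(rnap_bp)) NA_real_))
  }
  do.call(rbind, rows)
}

# pinned-open-complex fixture (one immobile plectoneme at the stall site)
pinned_fixture <- function(seed, n_frames = 150, total_bp = 21000,
                           plect_size = 9000, frame_interval_s = 2) {
  mol <- molecule_spec(total_bp, promoter_bp = 8000)
  dyn <- dynamics_spec(nucleation_rate = 0, termination_rate = 0,
                       total_supercoiled_bp = plect_size,
                       pinned_site_bp = 8029)
  tx <- transcription_spec(start_time_s = Inf)
  truth <- simulate_transcription(mol, dyn, tx,
                                  duration_s = (n_frames - 1) *
                                    frame_interval_s,
                                  frame_interval_s = frame_interval_s,
                                  seed = seed)
  list(mol = mol, truth = truth)
}

# single diffusing plectoneme, no nucleation/termination
diffusing_fixture <- function(seed, n_frames = 150, total_bp = 21000,
                              plect_size = 8000, D = 0.5,
                              frame_interval_s = 2, extension = 0.7) {
  mol <- molecule_spec(total_bp, promoter_bp = 8000, extension = extension)
  dyn <- dynamics_spec(diffusion_um2_s = D, nucleation_rate = 0,
                       termination_rate = 0,
                       total_supercoiled_bp = plect_size, n_init = 1)
  truth <- simulate_plectonemes(mol, dyn,
                                duration_s = (n_frames - 1) *
                                  frame_interval_s,
                                frame_interval_s = frame_interval_s,
                                seed = seed)
  list(mol = mol, truth = truth)
}

expect_unit_pNnm <- function(x) {
  expect_identical(attr(x, "unit"), "pN nm")
}
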