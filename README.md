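# plectotrack

Detection, tracking and quantification of DNA plectonemes in two-channel
single-molecule fluorescence kymographs — the measurement behind direct
visualization of the *twin-supercoiled domains* that a transcribing RNA
polymerase generates.

## The scientific problem

On a stretched, doubly-tethered, torsionally constrained DNA molecule
stained with an intercalating dye, supercoils condense into plectonemes:
intertwined loops that appear as bright puncta diffusing along the
molecule, because a plectoneme concentrates kilobases of DNA (hence
fluorescence) at one position. With a labeled RNA polymerase (RNAP) in a
second channel, the assay can watch transcription twist its own template in
real time. The twin-supercoiled-domain model predicts that a translocating
RNAP that cannot rotate about the helix overwinds the DNA ahead of itself
(positive supercoils, downstream) and underwinds it behind (negative
supercoils, upstream), in equal measure:

  ΔLk_downstream(t) = −ΔLk_upstream(t) = v·t / h,  h = 10.5 bp/turn,

with the twist converting to writhe (plectonemes) whenever the torsional
torque exceeds the buckling torque τ_b = √(2 k_BT L_p F) — only ~4.5 pN·nm
at the assay tension of ~0.05 pN.

`plectotrack` provides, for users of such assays (and for anyone who wants
a fully controlled testbed for kymograph analysis):

* **Synthetic two-channel image stacks with ground truth** — diffusing,
  nucleating and terminating plectonemes; promoter-pinned open complexes;
  transcription with per-helical-turn stochastic partitioning of injected
  supercoil; Gaussian PSF, shot and read noise at 109 nm/px
  (`simulate_plectonemes()`, `simulate_transcription()`, `render_stack()`,
  `write_fixture()`).
* **The detection pipeline** — 3-px median filter, white top-hat,
  kymograph construction, DNA-end localization by Gaussian peak peeling,
  punctum detection with sub-pixel centroids, track linking with a
  three-consecutive-frame lifetime rule, and intensity-based base-pair
  sizing with a ~1500-bp detection floor (`analyze_stack()` and friends).
* **Quantification** — position-resolved densities, co-existing-plectoneme
  count distributions, RNAP colocalization, upstream/downstream partition
  fractions, total-supercoil time series and treatment-epoch ratios,
  MSD-based diffusion constants, post-nick relaxation times, and Welch
  t-tests (`density_profile()`, `partition_fractions()`, ...).
* **A torque-balance model of supercoil induction** — rotational drag of
  the RNAP sphere and its nascent-RNA blob versus the DNA's torsional
  stiffness, swept over buffer viscosity with and without a transcript
  (`rotational_drag()`, `buckling_torque()`, `simulate_induction()`,
  `viscosity_sweep()`).
* **Scenario orchestration** — validated configurations and deterministic
  end-to-end runs with truth-comparison reports (`experiment_config()`,
  `run_scenario()`).

## Worked example: a promoter-pinned plectoneme

A stalled RNAP open complex merges all supercoils into a single immobile
plectoneme at its position. Simulate it, render it, and run the full
pipeline:

```r
library(plectotrack)

mol <- molecule_spec(21000, promoter_bp = 8000)            # 21-kb construct
dyn <- dynamics_spec(nucleation_rate = 0, termination_rate = 0,
                     total_supercoiled_bp = 9000, pinned_site_bp = 8029)
truth <- simulate_transcription(mol, dyn,
                                transcription_spec(start_time_s = Inf),
                                duration_s = 300, frame_interval_s = 2,
                                seed = 1)
stack <- render_stack(truth, render_spec(frame_interval_s = 2), seed = 2)
stack
#> <image_stack> 151 frames x 11 x 76 px, channels: dna, rnap

analysis <- analyze_stack(stack)
analysis$geometry
#> <molecule_geometry> ends 15.12 .. 60.74 px, 21000 bp (460.3 bp/px)

plect <- reported_plectonemes(analysis$tracks)
rnap  <- analysis$tracks[analysis$tracks$channel == "rnap", ]

count_distribution(plect, n_frames = analysis$n_frames)
#>   n probability
#> 1 1           1
colocalization(plect, rnap)$fraction
#> [1] 1
round(c(position_bp = mean(plect$position_bp), size_bp = mean(plect$size_bp)))
#> position_bp     size_bp
#>        8019        8555
```

Reading the output: the peeled ends sit within ~0.2 px of the true tether
positions (15 and 60.85 px), giving a 460 bp/px scale; in every one of the
151 frames exactly one plectoneme is detected, it colocalizes with the RNAP
punctum in the second channel, its mean position (8019 bp) matches the
pinning site at the stall position (promoter + 29 nt = 8029 bp), and its
mean recovered size (8.6 kb) is within ~5% of the 9-kb truth.

`plot(analysis$kymographs$dna)` displays the kymograph itself.

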