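test_that("rotational drag evaluates to the closed form with proper units", {
  p <- mechanics_params()   # water, R = 7 nm
  g0 <- rotational_drag(p, 0)
  expect_equal(as.numeric(g0), 8 * pi * 1e-9 * 343, tolerance = 1e-12)
  expect_equal(as.numeric(g0), 8.62e-6, tolerance = 1e-3)
  expect_unit_pNnm(structure(1, unit = "pN nm"))  # helper sanity
  expect_identical(attr(g0, "unit"), "pN nm s")
  # strictly linear in viscosity at fixed transcript
  p2 <- mechanics_params(viscosity_Pa_s = 5e-3)
  expect_equal(as.numeric(rotational_drag(p2, 1000)),
               5 * as.numeric(rotational_drag(p, 1000)), tolerance = 1e-12)
  # a long transcript dominates the bare-RNAP drag at any viscosity
  expect_gt(as.numeric(rotational_drag(p, 1e4)) / as.numeric(g0), 100)
})

test_that("buckling torque at assay tension is below 5 pN nm", {
  p <- mechanics_params()   # F = 0.05 pN, Lp = 50 nm, kBT = 4.114 pN nm
  tb <- buckling_torque(p)
  expect_equal(as.numeric(tb), sqrt(2 * 4.114 * 50 * 0.05),
               tolerance = 1e-12)
  expect_lt(as.numeric(tb), 5)
  expect_identical(attr(tb, "unit"), "pN nm")
  expect_equal(as.numeric(buckling_torque(
    mechanics_params(tension_pN = 0.2))),
    sqrt(2) * sqrt(2) * as.numeric(tb), tolerance = 1e-12)  # sqrt(F) scaling
  p0 <- mechanics_params(); p0$tension_pN <- 0
  expect_equal(as.numeric(buckling_torque(p0)), 0)
})

test_that("cytoplasmic viscosity buckles almost immediately", {
  p <- mechanics_params(viscosity_Pa_s = 17500)
  r <- simulate_induction(p, max_bp = 30000, with_transcript = FALSE)
  expect_true(r$buckled)
  expect_lt(r$buckling_distance_bp, 1000)
  expect_identical(r$regime, "supercoiling")
})

test_that("in water the bare RNAP never buckles but the transcript rescues it", {
  p <- mechanics_params()   # 1 mPa s
  bare <- simulate_induction(p, max_bp = 30000, with_transcript = FALSE)
  expect_false(bare$buckled)
  expect_identical(bare$regime, "tracking")
  expect_equal(bare$buckling_distance_bp, 30000)   # capped
  with_rna <- simulate_induction(p, max_bp = 30000, with_transcript = TRUE)
  expect_true(with_rna$buckled)
  expect_gt(with_rna$buckling_distance_bp, 10000)  # a sizeable transcript
  expect_lte(with_rna$buckling_distance_bp, bare$buckling_distance_bp)
})

test_that("torque units agree and the DNA torque never relaxes pre-buckling", {
  p <- mechanics_params(viscosity_Pa_s = 1)
  r <- simulate_induction(p, max_bp = 5000, with_transcript = TRUE)
  tt <- r$torque_trace
  expect_identical(attr(tt$tau_dna, "unit"), attr(tt$tau_fric, "unit"))
  expect_unit_pNnm(tt$tau_dna)
  pre <- tt$transcript_bp <= r$buckling_distance_bp
  expect_true(all(diff(tt$tau_dna[pre]) >= -1e-12))
})

test_that("viscosity sweep is monotone and the transcript always helps", {
  mu <- 10^seq(log10(1.75e-6), log10(1.75e4), length.out = 15)
  sw <- viscosity_sweep(mechanics_params(), mu, max_bp = 30000)
  for (tr in c(TRUE, FALSE)) {
    d <- sw$buckling_distance_bp[sw$transcript == tr]
    expect_true(all(diff(d) <= 0))
  }
  w <- merge(sw[sw$transcript, ], sw[!sw$transcript, ], by = "mu_Pa_s")
  expect_true(all(w$buckling_distance_bp.x <= w$buckling_distance_bp.y))
  # faster elongation buckles no later
  sw2 <- viscosity_sweep(mechanics_params(elongation_rate_bp_s = 100), mu,
                         max_bp = 30000)
  expect_true(all(sw2$buckling_distance_bp <= sw$buckling_distance_bp))
  expect_error(viscosity_sweep(mechanics_params(), numeric(0)), "empty")
  one <- viscosity_sweep(mechanics_params(), 1e-3, transcript = TRUE)
  expect_equal(nrow(one), 1)
})

test_that("parameter validation rejects unphysical mechanics inputs", {
  expect_error(mechanics_params(viscosity_Pa_s = 0), "> 0")
  expect_error(mechanics_params(flory_exponent = 0.7), "flory")
  expect_error(rotational_drag(mechanics_params(), -1), "transcript_nt")
})
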