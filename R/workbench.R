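#' Build an experiment configuration
#'
#' A single configuration object drives [run_scenario()]: scenario name,
#' molecule/dynamics/transcription/render specifications, detection
#' parameters and the run seed.  Missing pieces are filled with
#' scenario-appropriate defaults by [validate_config()].
#'
#' @param scenario one of `"bare_supercoiled"`, `"pinned_open_complex"`,
#'   `"transcription"`, `"transcription_rnase"`, `"nicking"`.
#' @param molecule,dynamics,transcription,render optional spec objects.
#' @param detection optional [detect_params()].
#' @param duration_s,frame_interval_s acquisition settings.
#' @param n_molecules number of molecules simulated.
#' @param seed integer run seed.
#' @param ... further scenario fields (e.g. `nick_time_s`, `relax_tau_s`).
#' @return a list of class `experiment_config` (not yet validated).
#' @export
experiment_config <- function(scenario, molecule = NULL, dynamics = NULL,
                              transcription = NULL, render = NULL,
                              detection = NULL, duration_s = NULL,
                              frame_interval_s = NULL, n_molecules = 1,
                              seed = 1, ...) {
  cfg <- c(as.list(environment()), list(...))
  class(cfg) <- "experiment_config"
  cfg
}

SCENARIOS <- c("bare_supercoiled", "pinned_open_complex", "transcription",
               "transcription_rnase", "nicking")

#' Validate and normalize an experiment configuration
#'
#' Fills scenario defaults, checks cross-field consistency (e.g. a pinned
#' site inside an end-exclusion zone) and returns the fully resolved
#' configuration; all problems are reported together.
#'
#' @param cfg an [experiment_config()] (or a bare list with `scenario`).
#' @return the normalized `experiment_config`.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  if (is.null(cfg$scenario) || !cfg$scenario %in% SCENARIOS)
    stop("unknown scenario '", cfg$scenario, "'; must be one of: ",
         paste(SCENARIOS, collapse = ", "))
  sc <- cfg$scenario
  if (is.null(cfg$molecule))
    cfg$molecule <- if (sc %in% c("bare_supercoiled", "pinned_open_complex"))
      molecule_spec(21000) else molecule_spec(31000)
  if (is.null(cfg$dynamics)) {
    cfg$dynamics <- switch(sc,
      bare_supercoiled = dynamics_spec(),
      pinned_open_complex = dynamics_spec(
        nucleation_rate = 0, termination_rate = 0,
        total_supercoiled_bp = 9000,
        pinned_site_bp = cfg$molecule$promoter_bp + 29),
      nicking = dynamics_spec(total_supercoiled_bp = 6000,
                              nucleation_rate = 0, termination_rate = 0),
      dynamics_spec(total_supercoiled_bp = 0, nucleation_rate = 0,
                    termination_rate = 0))
  }
  if (is.null(cfg$transcription) && sc %in%
        c("pinned_open_complex", "transcription", "transcription_rnase",
          "nicking"))
    cfg$transcription <- switch(sc,
      pinned_open_complex = transcription_spec(start_time_s = Inf),
      transcription = transcription_spec(),
      transcription_rnase = transcription_spec(rnase_time_s = 330),
      nicking = transcription_spec())
  if (is.null(cfg$render)) cfg$render <- render_spec()
  if (is.null(cfg$detection)) cfg$detection <- detect_params()
  if (is.null(cfg$duration_s))
    cfg$duration_s <- switch(sc, bare_supercoiled = 300,
                             pinned_open_complex = 300,
                             transcription = 360,
                             transcription_rnase = 630, nicking = 360)
  if (is.null(cfg$frame_interval_s))
    cfg$frame_interval_s <- if (sc %in% c("bare_supercoiled",
                                          "pinned_open_complex")) 2 else 1
  if (is.null(cfg$n_molecules)) cfg$n_molecules <- 1
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (sc == "nicking") {
    if (is.null(cfg$nick_time_s)) cfg$nick_time_s <- cfg$duration_s / 2
    if (is.null(cfg$relax_tau_s)) cfg$relax_tau_s <- 5
  }
  # cross-field checks
  dyn <- cfg$dynamics; mol <- cfg$molecule
  if (dyn$diffusion_um2_s < 0)
    errs <- c(errs, "dynamics: diffusion coefficient is negative")
  if (dyn$total_supercoiled_bp >= mol$total_bp)
    errs <- c(errs, "dynamics: supercoiled budget exceeds construct length")
  lo <- dyn$end_exclusion_bp; hi <- mol$total_bp - dyn$end_exclusion_bp
  if (!is.null(dyn$pinned_site_bp) &&
      (dyn$pinned_site_bp < lo || dyn$pinned_site_bp > hi))
    errs <- c(errs, "dynamics: pinned site lies inside an end-exclusion zone")
  if (!(mol$promoter_bp > 0 && mol$promoter_bp < mol$total_bp))
    errs <- c(errs, "molecule: promoter outside the construct")
  if (!is.null(cfg$transcription)) {
    stall <- mol$promoter_bp + cfg$transcription$stall_offset_nt
    if (stall <= lo || stall >= hi)
      errs <- c(errs, "transcription: stall site inside an exclusion zone")
  }
  cfg$render$frame_interval_s <- cfg$frame_interval_s
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$validated <- TRUE
  cfg
}

#' Run a complete scenario: generate, render, detect, quantify
#'
#' Deterministically simulates the configured scenario, renders the image
#' stacks, runs the detection pipeline, computes scenario-appropriate
#' summary statistics, and assembles a machine-readable report comparing the
#' pipeline output against the ground truth (detection rate, position bias
#' and RMSE, size bias).
#'
#' @param cfg an [experiment_config()]; validated here if needed.
#' @param out_dir optional directory; when given, fixtures and the report
#'   JSON are written there.
#' @return a list of class `scenario_report`.
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  if (!isTRUE(cfg$validated)) cfg <- validate_config(cfg)
  sc <- cfg$scenario
  analyses <- list(); truths <- list()
  for (i in seq_len(cfg$n_molecules)) {
    sd_i <- child_seed(cfg$seed, i)
    truth <- switch(sc,
      bare_supercoiled = simulate_plectonemes(
        cfg$molecule, cfg$dynamics, cfg$duration_s, cfg$frame_interval_s,
        seed = sd_i),
      pinned_open_complex = simulate_transcription(
        cfg$molecule, cfg$dynamics, cfg$transcription, cfg$duration_s,
        cfg$frame_interval_s, seed = sd_i),
      simulate_transcription(
        cfg$molecule, cfg$dynamics, cfg$transcription, cfg$duration_s,
        cfg$frame_interval_s, seed = sd_i))
    if (sc == "nicking")
      truth <- apply_nick(truth, cfg$nick_time_s, cfg$relax_tau_s)
    stack <- render_stack(truth, cfg$render, seed = child_seed(sd_i, 1))
    if (!is.null(out_dir))
      write_fixture(stack, truth,
                    file.path(out_dir, sprintf("molecule_%02d", i)),
                    overwrite = TRUE)
    analyses[[i]] <- analyze_stack(stack, params = cfg$detection)
    truths[[i]] <- truth
  }
  names(analyses) <- names(truths) <- sprintf("m%02d", seq_along(analyses))
  comb <- combine_analyses(analyses)
  plect <- reported_plectonemes(comb$tracks, cfg$detection$floor_bp)
  rnap <- comb$tracks[comb$tracks$channel == "rnap", , drop = FALSE]

  fidelity <- truth_fidelity(comb, truths)
  quant <- list(
    count_distribution = count_distribution(plect, comb$n_frames),
    density = density_profile(plect, cfg$molecule$total_bp))
  if (nrow(rnap) > 0) {
    quant$colocalization <- colocalization(plect, rnap,
                                           total_bp = cfg$molecule$total_bp)
    if (sc %in% c("transcription", "transcription_rnase", "nicking"))
      quant$partition <- tryCatch(partition_fractions(plect, rnap),
                                  error = function(e) conditionMessage(e))
  }
  series <- lapply(names(analyses), function(m)
    total_size_series(plect, cfg$frame_interval_s,
                      n_frames = comb$n_frames[[m]], molecule = m)$series)
  names(series) <- names(analyses)
  quant$total_size <- series
  if (sc == "transcription_rnase")
    quant$epoch_ratio <- lapply(series, epoch_ratio,
                                t_split = cfg$transcription$rnase_time_s)
  if (sc == "nicking")
    quant$relaxation <- relaxation_times(series, cfg$nick_time_s)

  report <- list(scenario = sc, seed = cfg$seed,
                 n_molecules = cfg$n_molecules,
                 config_hash = config_hash(cfg), fidelity = fidelity,
                 quantification = quant)
  class(report) <- "scenario_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}

# strip non-serializable pieces for the JSON report
report_to_json <- function(report) {
  q <- report$quantification
  list(scenario = report$scenario, seed = report$seed,
       n_molecules = report$n_molecules, config_hash = report$config_hash,
       fidelity = report$fidelity,
       count_distribution = q$count_distribution,
       colocalization_fraction = if (!is.null(q$colocalization))
         q$colocalization$fraction,
       partition_pooled = if (!is.null(q$partition) &&
                              inherits(q$partition, "partition_summary"))
         q$partition$pooled,
       epoch_ratio = if (!is.null(q$epoch_ratio))
         lapply(q$epoch_ratio, `[[`, "ratio"),
       relaxation_median_s = if (!is.null(q$relaxation))
         q$relaxation$median_s)
}

config_hash <- function(cfg) {
  cfg$validated <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

# detection-vs-truth metrics pooled over molecules
truth_fidelity <- function(comb, truths) {
  pos_err <- numeric(0); size_rel <- numeric(0)
  n_truth <- 0L; n_matched <- 0L
  for (m in seq_along(truths)) {
    tr <- comb$tracks
    tr <- tr[tr$channel == "dna" &
               tr$molecule == names(truths)[m], , drop = FALSE]
    ob <- truths[[m]]$objects
    ob <- ob[ob$kind == "plectoneme", , drop = FALSE]
    n_truth <- n_truth + nrow(ob)
    if (nrow(tr) == 0 || nrow(ob) == 0) next
    for (f in unique(tr$frame)) {
      ti <- tr[tr$frame == f, , drop = FALSE]
      oi <- ob[ob$frame == f, , drop = FALSE]
      if (nrow(oi) == 0) next
      for (j in seq_len(nrow(ti))) {
        k <- which.min(abs(oi$position_bp - ti$position_bp[j]))
        pos_err <- c(pos_err, ti$position_bp[j] - oi$position_bp[k])
        if (oi$size_bp[k] > 0)
          size_rel <- c(size_rel,
                        (ti$size_bp[j] - oi$size_bp[k]) / oi$size_bp[k])
        n_matched <- n_matched + 1L
      }
    }
  }
  list(n_truth_records = n_truth, n_matched_detections = n_matched,
       detection_rate = if (n_truth > 0) n_matched / n_truth else NA_real_,
       position_bias_bp = if (length(pos_err)) mean(pos_err) else NA_real_,
       position_rmse_bp = if (length(pos_err)) sqrt(mean(pos_err^2)) else
         NA_real_,
       size_bias_rel = if (length(size_rel)) mean(size_rel) else NA_real_)
}
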