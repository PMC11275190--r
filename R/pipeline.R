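#' Default end-to-end run configuration
#'
#' @param conditions Named list of [condition_spec] objects (default: the
#'   built-in study conditions).
#' @param n_spikes Spikes generated per condition (default 500; use a
#'   smaller value for quick runs).
#' @param harmonic_K Highest harmonic index for the baseline decomposition.
#' @param n_neurons Artificial neuron count (default 30).
#' @param current_duration Duration of generated current traces, s.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(conditions = builtin_conditions(),
                               n_spikes = 500, harmonic_K = 16,
                               n_neurons = 30, current_duration = 3600,
                               seed = 1L) {
  structure(list(conditions = conditions, n_spikes = n_spikes,
                 harmonic_K = harmonic_K, n_neurons = n_neurons,
                 current_duration = current_duration,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    ps_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pipeline_stage_failure")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates, per condition: synthetic-trace generation, spike-aware
#' B-spline detrending, spike detection and moment summaries; then the
#' cross-condition dose-response report, a harmonic decomposition of the
#' control baseline oscillation, current-trace generation with binary
#' temporal coding, random synaptic-weight initialization, and LZ76
#' complexity of the weight maps and activity codes.  Outputs are written
#' under `out_dir` (metrics CSVs, JSON reports, weight-matrix CSVs) with
#' the seed and parameters embedded in `provenance.json`.  A failure in
#' any stage raises an error naming the stage.
#'
#' @param config A `run_config` (see [default_run_config]).
#' @param out_dir Output directory; `NULL` skips writing files.
#' @return List with `summaries`, `dose_response`, `harmonics`, `neuro`
#'   (per-condition weight/code/complexity results), `provenance`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  labs <- names(config$conditions)

  summaries <- pipeline_stage("synthetic_data/spike_metrics", {
    res <- lapply(seq_along(config$conditions), function(i) {
      spec <- config$conditions[[i]]
      recover_condition(spec, n_spikes = config$n_spikes,
                        seed = config$seed + i)
    })
    names(res) <- labs
    res
  })
  sums <- lapply(summaries, `[[`, "summary")

  dose <- pipeline_stage("dose_response",
    dose_response_report(sums, reference = labs[1]))

  harm <- pipeline_stage("harmonics", {
    # harmonic content of the slow baseline oscillation of the first
    # (reference) condition
    fit <- summaries[[1]]$fit
    bl <- trace(fit$baseline, dt = summaries[[1]]$generated$trace$dt,
                unit = "mV", label = labs[1])
    # short runs may span too few drift periods for spectral estimation;
    # fall back to the configured drift frequency
    omega <- tryCatch(estimate_base_frequency(bl),
                      error = function(e)
                        2 * pi / config$conditions[[1]]$drift_period)
    K <- config$harmonic_K
    while (K * omega / (2 * pi) >= 1 / (2 * bl$dt) && K > 1) K <- K - 1
    harmonic_decompose(bl, omega = omega, K = K)
  })

  neuro <- pipeline_stage("neuro_abstraction/complexity", {
    res <- lapply(seq_along(labs), function(i) {
      ct <- generate_current_trace(labs[i], config$current_duration,
                                   seed = config$seed + 100L + i)
      code <- binarize_current(ct)
      w <- init_weights(config$n_neurons, seed = config$seed + 200L + i)
      wbits <- binarize_matrix(w)
      list(label = labs[i],
           current_stats = current_distribution_stats(ct),
           charge_total = utils::tail(cumulative_charge(ct), 1),
           active_subset = subsample_active(code, config$n_neurons,
                                            seed = config$seed + 300L + i),
           n_active = sum(code$bits),
           weights = w,
           code_lz = if (length(code$bits) >= 2) lz_normalized(code) else NA,
           weights_lz = lz_normalized(wbits))
    })
    names(res) <- labs
    res
  })

  provenance <- list(seed = config$seed, n_spikes = config$n_spikes,
                     harmonic_K = config$harmonic_K,
                     n_neurons = config$n_neurons,
                     current_duration = config$current_duration,
                     package_version =
                       as.character(utils::packageVersion("protospike")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    amp_tab <- do.call(rbind, lapply(sums, `[[`, "amplitude"))
    isi_tab <- do.call(rbind, lapply(sums, `[[`, "isi"))
    write_metrics_table(amp_tab, file.path(out_dir, "amplitude_metrics.csv"))
    write_metrics_table(isi_tab, file.path(out_dir, "isi_metrics.csv"))
    write_dose_response(dose,
                        json_path = file.path(out_dir, "dose_response.json"),
                        md_path = file.path(out_dir, "dose_response.md"))
    utils::write.csv(harm, file.path(out_dir, "harmonics.csv"),
                     row.names = FALSE)
    for (lab in labs) {
      safe <- gsub("[^A-Za-z0-9]+", "_", lab)
      write_weight_matrix(neuro[[lab]]$weights,
                          file.path(out_dir, paste0("weights_", safe, ".csv")))
    }
    lz_tab <- data.frame(
      Condition = labs,
      WeightsLZ = vapply(neuro, `[[`, numeric(1), "weights_lz"),
      CodeLZ = vapply(neuro, function(x) as.numeric(x$code_lz), numeric(1)),
      row.names = NULL)
    utils::write.csv(lz_tab, file.path(out_dir, "complexity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(summaries = sums, dose_response = dose, harmonics = harm,
       neuro = neuro, provenance = provenance)
}
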