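#!/usr/bin/env Rscript
# Per-condition spike analysis: B-spline baseline removal, spike detection
# and the amplitude/ISI moment tables.  Reads the simulated voltage traces
# from scratch/traces (falling back to regeneration with the same seeds),
# and writes the two canonical metrics tables under results/tables.

library(protospike)

seed <- 20260925L
n_spikes <- 120L
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

specs <- builtin_conditions()
summaries <- list()
for (i in seq_along(specs)) {
  spec <- specs[[i]]
  safe <- gsub("[^A-Za-z0-9]+", "_", spec$label)
  path <- file.path("scratch/traces", paste0("voltage_", safe, ".csv"))
  tr <- if (file.exists(path)) {
    read_trace_csv(path, unit = "mV", label = spec$label)
  } else {
    message("  (regenerating ", spec$label, ")")
    generate_voltage_trace(spec, n_spikes = n_spikes, seed = seed + i)$trace
  }
  fit <- detrend_trace(tr)
  ev <- detect_spikes(fit$residual)
  s <- summarize_spikes(ev, condition = spec$label)
  summaries[[spec$label]] <- s
  message(sprintf(
    "  %-9s %3d spikes | amp %6.3f mV (target %6.3f) | ISI %7.1f s (target %7.1f, SEM %5.1f)",
    spec$label, s$n_spikes, s$amplitude$Mean, spec$amp_mean,
    s$isi$Mean, spec$isi_mean, s$sem_isi))
}

amp_tab <- do.call(rbind, lapply(summaries, `[[`, "amplitude"))
isi_tab <- do.call(rbind, lapply(summaries, `[[`, "isi"))
write_metrics_table(amp_tab, "results/tables/amplitude_metrics.csv")
write_metrics_table(isi_tab, "results/tables/isi_metrics.csv")
metrics_to_json(amp_tab, "results/tables/amplitude_metrics.json")
metrics_to_json(isi_tab, "results/tables/isi_metrics.json")
message("Metrics tables written under results/tables")
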