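#!/usr/bin/env Rscript
# Generate the synthetic study recordings: one voltage trace per exposure
# condition (calibrated to the published amplitude/ISI moments) and one
# chronoamperometric current trace per condition.  Raw traces are bulky and
# go to scratch/; downstream scripts regenerate them from the same seeds if
# scratch/ is absent.

library(protospike)

seed <- 20260925L
n_spikes <- 120L          # per-condition spikes for the narrative run
out <- "scratch/traces"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- builtin_conditions()
message(sprintf("Simulating %d conditions, %d spikes each (seed %d)",
                length(specs), n_spikes, seed))

for (i in seq_along(specs)) {
  spec <- specs[[i]]
  gen <- generate_voltage_trace(spec, n_spikes = n_spikes, seed = seed + i)
  safe <- gsub("[^A-Za-z0-9]+", "_", spec$label)
  write_trace_csv(gen$trace, file.path(out, paste0("voltage_", safe, ".csv")))
  fit <- gen$isi_fit
  message(sprintf(
    "  %-9s %6d samples | ISI target %7.2f s (attained %7.2f, SD %6.1f of %6.1f%s)",
    spec$label, length(gen$trace$values), fit$target_mean, fit$attained_mean,
    fit$attained_sd, fit$target_sd,
    if (fit$feasible) "" else ", SD target infeasible on printed range"))

  ct <- generate_current_trace(spec$label, duration = 3600,
                               seed = seed + 100L + i)
  write_trace_csv(ct, file.path(out, paste0("current_", safe, ".csv")))
}

message("Traces written under ", out)
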