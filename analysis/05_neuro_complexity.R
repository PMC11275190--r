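#!/usr/bin/env Rscript
# Neuromorphic abstraction of the chronoamperometric traces: binary temporal
# coding at the 1e-4 uA activity threshold, inverse-scaled event
# subsampling for a 30-neuron population, random synaptic-weight
# initialization on [-1, 1), cumulative charge, current boxplot statistics,
# and LZ76 complexity of the weight maps and activity codes.

library(protospike)

seed <- 20260925L
n_neurons <- 30L
dir.create("results/neuro", recursive = TRUE, showWarnings = FALSE)

specs <- builtin_conditions()
rows <- list()
for (i in seq_along(specs)) {
  lab <- names(specs)[i]
  safe <- gsub("[^A-Za-z0-9]+", "_", lab)
  path <- file.path("scratch/traces", paste0("current_", safe, ".csv"))
  ct <- if (file.exists(path)) read_trace_csv(path, unit = "uA", label = lab)
        else generate_current_trace(lab, 3600, seed = seed + 100L + i)

  stats <- current_distribution_stats(ct)
  q <- cumulative_charge(ct)
  code <- binarize_current(ct)
  subset <- subsample_active(code, n_neurons, seed = seed + 300L + i)
  w <- init_weights(n_neurons, seed = seed + 200L + i)
  write_weight_matrix(w, file.path("results/neuro",
                                   paste0("weights_", safe, ".csv")))
  rows[[lab]] <- data.frame(
    Condition = lab, MeanCurrent_uA = stats$mean, Median_uA = stats$median,
    Q1_uA = stats$q1, Q3_uA = stats$q3, Outliers = length(stats$outliers),
    TotalCharge_uC = q[length(q)], ActiveSamples = sum(code$bits),
    SubsetSize = length(subset),
    WeightsLZ = lz_normalized(binarize_matrix(w)),
    CodeLZ = lz_normalized(code))
  message(sprintf(
    "  %-9s mean %6.0f uA, median %6.0f | charge %9.3g uC | subset %3d | LZ(weights) %.3f LZ(code) %.4f",
    lab, stats$mean, stats$median, q[length(q)], length(subset),
    rows[[lab]]$WeightsLZ, rows[[lab]]$CodeLZ))
}

tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/neuro/summary.csv", row.names = FALSE)
message("Current ordering check: 0.5 cm2 above control, 25 mg/mL below: ",
        tab["0.5 cm2", "MeanCurrent_uA"] > tab["control", "MeanCurrent_uA"] &&
        tab["25 mg/mL", "MeanCurrent_uA"] < tab["control", "MeanCurrent_uA"])
message("Neuromorphic summaries written under results/neuro")
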