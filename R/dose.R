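#' Percent change relative to a reference value
#'
#' `100 * (1 - treated / reference)`: positive values are reductions
#' (attenuation) relative to the reference condition.
#'
#' @param reference Reference value (> 0).
#' @param treated Treated-condition value.
#' @return Percent change; vectorized over `treated`.
#' @export
#'
#' @examples
#' percent_change(0.895, 0.065)  # ~92.7% amplitude attenuation
percent_change <- function(reference, treated) {
  if (any(reference <= 0))
    ps_stop("reference must be > 0", "dose_invalid")
  100 * (1 - treated / reference)
}

#' Convert seconds to minutes, one decimal, half-up rounding
#' @param x Time in seconds (>= 0).
#' @return Minutes rounded half-up to one decimal.
#' @export
#'
#' @examples
#' seconds_to_minutes(1392.86)  # 23.2
seconds_to_minutes <- function(x) {
  if (any(x < 0)) ps_stop("x must be >= 0", "dose_invalid")
  round_half_up(x / 60, 1)
}

#' Cross-condition dose-response report
#'
#' Assembles the headline attenuation statistics from per-condition spike
#' summaries: percent change of amplitude mean and ISI mean versus the
#' reference condition (default the first, normally the control), pairwise
#' step changes between consecutive conditions, and ISI means converted to
#' minutes (one decimal).
#'
#' @param summaries Named list of `spike_summary` objects (or a list with
#'   `$amplitude$Mean` / `$isi$Mean`), in exposure order.
#' @param reference Label of the reference condition (default: first).
#' @return An object of class `dose_response_report`: list with `conditions`
#'   (per-condition table incl. minutes), `vs_reference` (percent changes
#'   vs the reference), `stepwise` (consecutive-condition percent changes).
#' @export
dose_response_report <- function(summaries, reference = names(summaries)[1]) {
  if (length(summaries) < 2)
    ps_stop("need at least two conditions", "dose_invalid")
  if (!reference %in% names(summaries))
    ps_stop("reference condition not among the summaries", "dose_invalid")
  amp <- vapply(summaries, function(s) s$amplitude$Mean, numeric(1))
  isi <- vapply(summaries, function(s) s$isi$Mean, numeric(1))
  labs <- names(summaries)
  conditions <- data.frame(
    Condition = labs, AmplitudeMean_mV = amp, ISIMean_s = isi,
    ISIMean_min = seconds_to_minutes(isi), row.names = NULL,
    stringsAsFactors = FALSE)
  vs_ref <- data.frame(
    Condition = labs,
    AmplitudeReduction_pct = percent_change(amp[[reference]], amp),
    ISIReduction_pct = percent_change(isi[[reference]], isi),
    row.names = NULL, stringsAsFactors = FALSE)
  step <- data.frame(
    From = labs[-length(labs)], To = labs[-1],
    AmplitudeReduction_pct = percent_change(amp[-length(amp)], amp[-1]),
    ISIReduction_pct = percent_change(isi[-length(isi)], isi[-1]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(reference = reference, conditions = conditions,
                 vs_reference = vs_ref, stepwise = step),
            class = "dose_response_report")
}

#' @export
print.dose_response_report <- function(x, ...) {
  cat(sprintf("<dose_response_report> reference: %s\n", x$reference))
  print(cbind(x$conditions,
              x$vs_reference[, c("AmplitudeReduction_pct",
                                 "ISIReduction_pct")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a dose-response report as JSON and Markdown
#' @param report A `dose_response_report`.
#' @param json_path,md_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_dose_response <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "dose_response_report"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(md_path)) {
    md_table <- function(df) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
      c(paste0("| ", paste(names(df), collapse = " | "), " |"),
        paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
        apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
    }
    writeLines(c("# Dose-response report", "",
                 paste0("Reference condition: ", report$reference), "",
                 "## Per-condition means", md_table(report$conditions), "",
                 "## Percent change vs reference",
                 md_table(report$vs_reference), "",
                 "## Stepwise percent change", md_table(report$stepwise)),
               md_path)
  }
  invisible(report)
}
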