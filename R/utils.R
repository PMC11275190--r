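# internal helpers

ps_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "protospike_error"), call = call))
}

ps_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "protospike_warning")))
}

# Run `code` under a fixed RNG seed when `seed` is given; otherwise draw from
# the current stream.  All package randomness funnels through this.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# round half up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
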