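# Internal helpers shared across modules.

# Structured errors so the CLI can map validation problems to exit code 2.
rp_stop <- function(msg, class = "riskplot_input_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "riskplot_error", "error", "condition")))
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

rms <- function(x) sqrt(mean(x^2))

# Signal-to-noise ratio in dB of `x` against a known clean reference.
snr_db <- function(signal, noisy) {
  err <- noisy - signal
  10 * log10(sum(signal^2) / sum(err^2))
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
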