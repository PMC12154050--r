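# Internal helpers shared across modules.

# Classed error helper so callers can distinguish configuration, input,
# estimation and contract failures programmatically.
cc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "connectocoh_error", "error")))
}

cc_config_error     <- function(msg) cc_stop(msg, "cc_config_error")
cc_input_error      <- function(msg) cc_stop(msg, "cc_input_error")
cc_estimation_error <- function(msg) cc_stop(msg, "cc_estimation_error")
cc_contract_error   <- function(msg) cc_stop(msg, "cc_contract_error")

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded package internals never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Fixed counter scheme expanding one global seed into per-unit sub-seeds.
# Lehmer-style mix, exact in double precision, result always in [1, 2^31-2].
mix_seed <- function(seed, counter) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + counter * 16807 + 12345) %% m
  as.integer(s + 1)
}

# Seconds -> samples with round-half-up (exact at 500 Hz: 0.4 s -> 200).
sec_to_samples <- function(seconds, sfreq) {
  as.integer(floor(seconds * sfreq + 0.5))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
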