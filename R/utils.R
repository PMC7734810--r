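`%||%` <- function(x, y) if (is.null(x)) y else x

# round() uses half-to-even; stratum and corpus counts use half-up.
round_half_up <- function(x) floor(x + 0.5)

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic per-task seeds below 2^31, derived from a master seed.
derive_seed <- function(master_seed, offset) {
  as.integer((abs(as.numeric(master_seed)) * 48271 + abs(as.numeric(offset)) * 9973) %% 2147483587)
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)
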