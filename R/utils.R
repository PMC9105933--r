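# Internal helpers shared across modules.

# Round half away from zero (Table-style reporting; base round() is
# round-half-even and would print 0.245 as 0.24).
.round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Deterministic per-iteration substream seed: a pure function of the root
# seed and a counter, kept inside 32-bit integer range. Synthetic-data
# generators use counters >= 1e6 so their streams never coincide with
# null-ensemble iteration streams (counters 1..n_iter) at equal root seeds.
.iter_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + as.double(i) * 1000003) %% 2147483647)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
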