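# internal helpers: seeded evaluation, sub-seed derivation, small hashing

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Independent sub-stream seed k derived from a master seed.  A multiplicative
# congruential step keeps the value inside the 32-bit signed range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 7919 * k) %% 2147483647)
}

# Polynomial rolling hash of a character vector, as 8 hex digits; used to
# stamp output files with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Full-precision numeric formatting so TSV output round-trips bit-identically.
num_chr <- function(x) formatC(x, digits = 17, format = "g")

stop_invalid <- function(...) stop(..., call. = FALSE)
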