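# Internal helpers: seeded RNG scoping, hashing, error conditions.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All exported stochastic entry points go
# through this so that a call never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_meioconj <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "meioconj_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

# Undefined-ratio errors are an explicit condition class: a ratio whose
# denominator class has probability (or count) zero is an answer about the
# scenario, never a numeric sentinel.
stop_undefined_ratio <- function(what) {
  stop_meioconj(
    sprintf("%s is undefined: its denominator class has probability/count zero", what),
    "meioconj_undefined_ratio"
  )
}

# 32-bit FNV-1a over a character string, returned as 8 hex digits.
# Split 16-bit multiplication keeps every intermediate below 2^53 (exact in
# doubles); no external hashing package is required.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  lo <- as.integer(h %% 65536)
  hi <- as.integer((h - lo) / 65536)
  sprintf("%04x%04x", hi, lo)
}

# bitwXor for doubles in [0, 2^32)
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
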