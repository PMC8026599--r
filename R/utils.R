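# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Counter-based substream derivation: resample/stage k draws its seed from
# (seed, k) so results do not depend on execution order. Kept below 2^31.
substream <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(k) * 69621 + 12345) %% 2147483587
  as.integer(x)
}

# Deterministic integer from a stage label, for fanning one pipeline seed out
# to per-stage substreams.
stage_offset <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)
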