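# Internal helpers: seed scoping and deterministic seed streams.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based expansion of a base seed into a stream of child seeds,
# kept inside the 32-bit integer range.
deriveSeed <- function(baseSeed, index) {
  as.integer((as.numeric(baseSeed) %% 2147483647 +
              as.numeric(index) * 1000003) %% 2147483629 + 1)
}

.posixct <- function(x) as.POSIXct(x, tz = "UTC")

# Default recording anchor: lights on at 09:00 on an arbitrary reference
# date (recordings start when white lights turn on).
.default_start <- function() .posixct("2024-01-01 09:00:00")

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
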