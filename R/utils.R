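# Run expr under a temporary RNG state seeded with `seed`, restoring any
# pre-existing global state afterwards. Keeps all randomness explicit and
# seedable without touching the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Positive-truncated normal draw (simple rejection; lower bound `lo`).
rnorm_trunc <- function(n, mean, sd, lo) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo]
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- lo; break }
  }
  out
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
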