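# Shared numeric helpers.

# Nearest-integer rounding with ties-to-even, with a tolerance that snaps
# values within 1e-9 of an exact half before rounding. Scaled counts are
# products like 3 * 1.2^-1 whose floating representation may sit a few ulps
# either side of 2.5; the snap keeps the tie-break deterministic.
round_half_even <- function(x) {
  half <- floor(x) + 0.5
  x <- ifelse(abs(x - half) <= 1e-9, half, x)
  round(x)
}

# Round half away from zero to `digits` decimals (display convention for
# GFLOPs tables; base round() would take 2.965 -> 2.96).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
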