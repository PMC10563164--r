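# Internal helpers.

# Run expr with a local RNG state so library functions never disturb the
# caller's random stream; seed-deterministic.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fixed-notation number formatting for deterministic, byte-stable files.
fmt_num <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)
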