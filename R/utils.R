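# Seed scoping: every randomized operation takes an integer seed, uses a
# private RNG scope and restores the caller's RNG state, so cohort
# generation is reproducible without clobbering the session.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Per-subject / per-purpose substream seeds derived from one cohort seed by
# fixed offsets (kept well below .Machine$integer.max).
sub_seed <- function(seed, subject, purpose) {
  as.integer(seed + subject * 10000L + purpose)
}
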