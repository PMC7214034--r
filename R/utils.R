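# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
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
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-chromosome child seed so that parallel and serial
# execution see identical RNG streams regardless of scheduling.
child_seed <- function(seed, chrom, salt = 0L) {
  h <- sum(utf8ToInt(chrom) * seq_along(utf8ToInt(chrom)))
  as.integer((as.numeric(seed) * 1009 + h * 31 + salt * 7919) %% 2147483647)
}
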