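## small shared helpers

## run code with a private RNG state so library calls never disturb the
## caller's random stream (and are reproducible under `seed`)
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## md5 digest of an arbitrary R object via serialization (no digest dep)
.object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

.dense_rank <- function(keys) {
  match(keys, sort(unique(keys)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
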