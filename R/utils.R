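## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible sub-seed from a master seed and a string key
## (case/condition/role), so every volume in a study has its own stream.
## FNV-style accumulation kept inside 31-bit integer range.
hash_seed <- function(master, key) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}
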