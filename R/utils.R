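# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Splittable-seed contract: derive a substream seed from (seed, index) so
# per-subject streams are stable under partial regeneration. Kept < 2^31.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 1299721 + 17) %% 2147483647
}

.onLoad <- function(libname, pkgname) {
  register_plugin("synthetic", synthetic_plugin)
}
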