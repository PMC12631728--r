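.isosip <- new.env(parent = emptyenv())

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# cached copy of the shipped isotope table; custom paths bypass the cache
default_iso_table <- function() {
  if (is.null(.isosip$iso_table)) .isosip$iso_table <- iso_table()
  .isosip$iso_table
}
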