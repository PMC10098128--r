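# run code with a private RNG state so seeded helpers do not disturb the
# caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop a possibly stale edge-ordering attribute so reorder() really reorders
canon_tree <- function(tree) {
  attr(tree, "order") <- NULL
  tree
}
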