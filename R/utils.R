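# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without touching global RNG state.
# `seed = NULL` leaves the current RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
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

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

stop_ctx <- function(...) stop(..., call. = FALSE)

# union-find with path compression; `n` elements, 1-based
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  i <- as.integer(i)
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a)
  rb <- uf_find(parent, b)
  if (ra != rb) parent[rb] <- ra
  parent
}
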