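# Internal helpers: seed streams, array shifts, assertions.

# Deterministic sub-seed derivation: one user seed drives independent named
# streams, so e.g. adding bullae never perturbs the parenchyma noise draw.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 5381
  for (ch in utf8ToInt(stream)) h <- (h * 33 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483646 + 1)
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(derive_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# voxel index grids for an array dim (n1, n2, n3); returns list of 3 arrays
index_grids <- function(dim) {
  list(
    i = array(rep(seq_len(dim[1]), times = dim[2] * dim[3]), dim = dim),
    j = array(rep(rep(seq_len(dim[2]), each = dim[1]), times = dim[3]), dim = dim),
    k = array(rep(seq_len(dim[3]), each = dim[1] * dim[2]), dim = dim)
  )
}

# shift array by integer offset along axis, replicate padding
shift_array <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  sel <- rep(list(quote(expr = )), 3)
  sel[[axis]] <- idx
  do.call(`[`, c(list(a), sel, list(drop = FALSE)))
}
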