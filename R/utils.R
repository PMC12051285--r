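#' @keywords internal
"_PACKAGE"

# Rectifier used throughout the network (paper uses ReLU everywhere).
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Sum rows of `m` into `n_groups` buckets given by `groups` (1-based).
# Returns an n_groups x ncol(m) matrix; empty groups are zero rows
# (the empty-neighbour-sum convention).
rowsum_into <- function(m, groups, n_groups) {
  out <- matrix(0, n_groups, ncol(m))
  if (nrow(m) > 0L) {
    s <- rowsum(m, group = groups, reorder = FALSE)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside
# the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435761 + stream * 97) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_binary01 <- function(x) all(x %in% c(0, 1))
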