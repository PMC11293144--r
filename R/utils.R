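# numeric helpers shared across the model code

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)        # all -Inf
  m + log(sum(exp(x - m)))
}

# row-wise softmax, numerically stable
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fan-in scaled uniform initialisation
init_mat <- function(nr, nc, scale = 1 / sqrt(nr)) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# broadcast a length-d vector over the rows of an n x d matrix
row_bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)
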