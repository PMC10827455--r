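#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif rpois rbeta predict
#' @importFrom utils head
NULL

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed derivation; stays well below 2^31
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 7919 + (as.numeric(k) %% 1000003) + 1) %% 2147483629
  as.integer(h) + 1L
}

# broadcast a per-channel vector over an (H, W, C, N) array
bcast_ch <- function(v, dims) {
  array(rep(v, each = dims[1] * dims[2]), dim = dims)
}

# per-channel sum / mean over an (H, W, C, N) array -> length-C vector
channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  rowSums(matrix(colSums(m), nrow = d[3]))
}
channel_mean <- function(x) channel_sum(x) / (dim(x)[1] * dim(x)[2] * dim(x)[4])

assert_that <- function(cond, msg) if (!isTRUE(cond)) abort(msg)

CLASS_LEVELS <- c("benign", "malignant")
MAGNIFICATIONS <- c(40L, 100L, 200L, 400L)

as_class_factor <- function(x) factor(as.character(x), levels = CLASS_LEVELS)

# one-hot (N x 2) matrix from class labels
one_hot <- function(labels) {
  f <- as_class_factor(labels)
  if (anyNA(f)) abort("labels must be 'benign' or 'malignant'")
  m <- matrix(0, nrow = length(f), ncol = 2L,
              dimnames = list(NULL, CLASS_LEVELS))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}
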