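#' @keywords internal
"_PACKAGE"

# Numerically stable row-wise softmax of a matrix (or vector).
softmax_rows <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Run an expression under a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so fixture generators are bit-reproducible without
#' disturbing an enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# ---- nested parameter-list helpers ------------------------------------------
# A ParameterStore is a nested named list whose leaves are numeric
# matrices/vectors.  Gradients and Adam moments mirror its structure.

param_map <- function(p, f) {
  if (is.list(p)) return(lapply(p, param_map, f = f))
  f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    return(out)
  }
  f(a, b)
}

# Sum of all leaf elements transformed by f (e.g. squared-norm accumulation).
param_reduce <- function(p, f, acc = 0) {
  if (is.list(p)) {
    for (el in p) acc <- param_reduce(el, f, acc)
    return(acc)
  }
  acc + f(p)
}

param_zeros_like <- function(p) param_map(p, function(x) x * 0)

# Flatten leaves to a single numeric vector / unflatten (used by gradient
# checks and checkpoint serialization).
param_flatten <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, param_flatten), use.names = FALSE))
  as.numeric(p)
}

param_unflatten <- function(template, v) {
  idx <- 0L
  rec <- function(p) {
    if (is.list(p)) return(lapply(p, rec))
    n <- length(p)
    out <- p
    out[] <- v[(idx + 1L):(idx + n)]
    idx <<- idx + n
    out
  }
  rec(template)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
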