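# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded draws inside the package
#' never disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Deterministic derived seed kept strictly below 2^31 (R integers are 32-bit).
mix_seed <- function(base, a = 0L, b = 0L) {
  s <- (as.double(base) * 2654435761 + as.double(a) * 40503 +
          as.double(b) * 9176) %% 2147483629
  as.integer(s) + 1L
}

# ---- parameter-tree utilities -------------------------------------------------
# Model weights/gradients/optimizer moments are nested lists whose leaves are
# numeric vectors or matrices with identical shapes across trees.

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_flatten <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_flatten), use.names = FALSE)
  else as.numeric(tree)
}

tree_unflatten <- function(template, vec) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    n <- length(t)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(t)) dim(out) <- dim(t)
    out
  }
  out <- rec(template)
  stopifnot(pos == length(vec))
  out
}
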