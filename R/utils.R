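# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Minimum Euclidean distance between two coordinate sets (n x 3 matrices)
#' @noRd
cross_min_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a * a), rowSums(b * b), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' All pairwise Euclidean distances between two coordinate sets
#' @noRd
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a * a), rowSums(b * b), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# contiguous integer runs of a sorted vector -> data.frame(start, end)
int_runs <- function(v) {
  v <- sort(unique(as.integer(v)))
  if (length(v) == 0L) return(data.frame(start = integer(), end = integer()))
  brk <- which(diff(v) != 1L)
  data.frame(start = v[c(1L, brk + 1L)], end = v[c(brk, length(v))])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
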