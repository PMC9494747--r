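`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (!positive || x >= 1)
}

## decimal text at full double precision; guarantees bit-identical
## write -> read round trips for matrix entries
fmt_num <- function(x) sprintf("%.17g", x)

normalize_weights <- function(w) w / sum(w)

#' Draw a Dirichlet-distributed weight vector
#'
#' @param alpha vector of positive concentration parameters (its length sets
#'   the dimension); a scalar is recycled to `k`.
#' @param k dimension when `alpha` is scalar.
#' @return a positive vector summing to 1.
#' @keywords internal
rdirichlet1 <- function(alpha, k = length(alpha)) {
  if (length(alpha) == 1L) alpha <- rep(alpha, k)
  g <- rgamma(k, shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

## Shrink a weight vector (in log space, order-preserving) until
## max(w)/min(w) <= max_ratio, then renormalize.  Keeps every pairwise ratio
## w_i/w_j inside the Saaty judgment scale [1/9, 9] so that a noise-free PCM
## built from w is exactly consistent after scale clipping.
bound_ratio <- function(w, max_ratio = 9) {
  stopifnot(all(w > 0))
  r <- max(w) / min(w)
  if (r <= max_ratio) return(normalize_weights(w))
  p <- log(max_ratio) / log(r)
  normalize_weights(w^p)
}

## max over rows of (max - min) across columns: how far a matrix is from
## having identical columns
col_spread <- function(m) {
  max(apply(m, 1L, max) - apply(m, 1L, min))
}

sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
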