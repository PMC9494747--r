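# shared fixtures, all built in code

# exactly consistent PCM from a weight vector
consistent_pcm <- function(w, items = names(w) %||% paste0("V", seq_along(w))) {
  pcm(outer(w, w, "/"), items = items)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small 2-category protocol for cheap end-to-end runs
small_protocol <- function() {
  protocol_config(list(
    list(code = "A", label = "first", variables = data.frame(
      name = c("a1", "a2", "a3"), stage = c(1L, 1L, 2L))),
    list(code = "B", label = "second", variables = data.frame(
      name = c("b1", "b2"), stage = c(1L, 2L)))
  ), n_stages = 2L)
}

# random positive reciprocal PCM (not consistent in general)
random_pcm <- function(n, spread = 1) {
  a <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a[i, j] <- exp(rnorm(1, 0, spread))
    a[j, i] <- 1 / a[i, j]
  }
  pcm(a)
}

# brute-force tie-corrected Kendall W, written directly from the defining
# formula with explicit tie-group enumeration (independent of kendall_w)
brute_force_w <- function(ranks) {
  m <- nrow(ranks); n <- ncol(ranks)
  sums <- colSums(ranks)
  ss <- sum((sums - mean(sums))^2)
  f <- 0
  for (i in seq_len(m)) {
    for (v in unique(ranks[i, ])) {
      t <- sum(ranks[i, ] == v)
      f <- f + (t^3 - t)
    }
  }
  12 * ss / (m^2 * (n^3 - n) - m * f)
}

# random mid-rank table: each judge ranks n items, with ties injected by
# coarsening scores to a small number of levels
random_rank_table <- function(m, n, levels = NULL) {
  t(sapply(seq_len(m), function(i) {
    x <- runif(n)
    if (!is.null(levels)) x <- round(x * levels)
    rank(x)
  }))
}
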