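#' Direct-influence matrix over variable categories
#'
#' A non-negative square matrix of perceived direct influence of each
#' category (row) on each other category (column), with zero diagonal.
#'
#' @param entries non-negative square numeric matrix with zero diagonal.
#' @param items optional item (category code) labels.
#' @param tol diagonal tolerance.
#' @return object of class `direct_influence`.
#' @export
direct_influence <- function(entries, items = NULL, tol = 1e-12) {
  m <- as.matrix(entries)
  if (nrow(m) != ncol(m)) stop_("influence matrix must be square")
  if (!is.numeric(m) || any(!is.finite(m)))
    stop_("influence entries must be finite numbers")
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop_("influence entries must be non-negative; entry (%d, %d) is %g",
          ij[1L], ij[2L], m[ij[1L], ij[2L]])
  }
  if (any(abs(diag(m)) > tol))
    stop_("influence matrix must have a zero diagonal")
  diag(m) <- 0
  items <- items %||% rownames(m) %||% paste0("C", seq_len(nrow(m)))
  dimnames(m) <- list(items, items)
  structure(m, class = c("direct_influence", "matrix"), items = items)
}

#' Normalize a direct-influence matrix
#'
#' Scales the direct matrix by `s = max(max row sum, max column sum)`, the
#' usual normalization that keeps the spectral radius of the result below 1
#' so that the total-relation series converges. The spectral radius is
#' checked numerically; degenerate inputs for which it reaches 1 are
#' rejected.
#'
#' @param d a [direct_influence()] matrix.
#' @return the normalized matrix `N = d / s` (plain matrix with dimnames).
#' @export
normalize_direct <- function(d) {
  m <- unclass(as.matrix(d))
  s <- max(max(rowSums(m)), max(colSums(m)))
  if (s <= 0) stop_("all-zero influence matrix: no relations to analyze")
  n <- m / s
  rho <- max(Mod(eigen(n, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12)
    stop_("normalized influence matrix has spectral radius %g >= 1; total relation undefined", rho)
  n
}

#' Total relation matrix (direct plus all indirect influence)
#'
#' Sums the direct influence and every indirect influence path:
#' `T = N (I - N)^{-1} = N + N^2 + N^3 + ...`, which converges because the
#' normalized matrix has spectral radius below 1.
#'
#' @param n a normalized influence matrix from [normalize_direct()].
#' @return the total relation matrix `T` (same dimnames).
#' @export
total_relation <- function(n) {
  n <- as.matrix(n)
  i <- diag(nrow(n))
  tr <- tryCatch(n %*% solve(i - n),
                 error = function(e)
                   stop_("(I - N) is singular: spectral radius of N must be < 1"))
  dimnames(tr) <- dimnames(n)
  tr
}

#' Influence profiles of each category
#'
#' From a total relation matrix, computes per category the influence given
#' `G` (row sum), received `R` (column sum), the net influence `G - R`, the
#' dominance `G + R` and the outgoing share `G/(G + R)`. Categories with
#' positive net influence are classified as `influencer`, negative as
#' `receiver`; a net within `1e-9` of zero is reported as `neutral`.
#'
#' @param t a total relation matrix.
#' @return data.frame with columns `category`, `given`, `received`, `net`,
#'   `dominance`, `outgoing_share`, `class`.
#' @export
influence_profiles <- function(t) {
  t <- as.matrix(t)
  g <- rowSums(t); r <- colSums(t)
  net <- g - r; dom <- g + r
  share <- ifelse(dom > 0, g / dom, NA_real_)
  cls <- ifelse(net > 1e-9, "influencer", ifelse(net < -1e-9, "receiver", "neutral"))
  data.frame(category = rownames(t) %||% paste0("C", seq_along(g)),
             given = g, received = r, net = net, dominance = dom,
             outgoing_share = share, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pool influence profiles across modelers
#'
#' Computes the total relation matrix and influence profile per modeler
#' first, then averages the profile quantities across modelers (Fig-3 style
#' mean and standard deviation, `sd` with denominator `n - 1`, zero for a
#' single modeler). Classification uses the sign of the mean net influence.
#'
#' @param bundle a [survey_bundle()].
#' @param retained optional character vector of modeler ids to pool
#'   (e.g. from [screen_modelers()]); defaults to all profiles.
#' @return data.frame with per-category mean and sd of `given`, `received`,
#'   `net`, `dominance`, `outgoing_share`, plus `class`.
#' @export
pool_influence <- function(bundle, retained = NULL) {
  ids <- retained %||% bundle$profiles$modeler_id
  if (length(ids) == 0L) stop_("no retained modelers with an influence matrix")
  profs <- lapply(ids, function(id)
    influence_profiles(total_relation(normalize_direct(bundle$influence[[id]]))))
  cats <- profs[[1L]]$category
  num_cols <- c("given", "received", "net", "dominance", "outgoing_share")
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  for (col in num_cols) {
    m <- vapply(profs, `[[`, numeric(length(cats)), col)
    m <- matrix(m, nrow = length(cats))
    out[[paste0(col, "_mean")]] <- rowMeans(m)
    out[[paste0(col, "_sd")]] <- apply(m, 1L, sd0)
  }
  net <- out$net_mean
  out$class <- ifelse(net > 1e-9, "influencer",
                      ifelse(net < -1e-9, "receiver", "neutral"))
  out
}

#' Export the total relation matrix as a causal edge list
#'
#' Convenience for plotting the causal diagram: every entry of `T` at or
#' above `cutoff` becomes a directed edge `(from, to, weight)`.
#'
#' @param t a total relation matrix.
#' @param cutoff minimum weight for an edge to be emitted (default 0, i.e.
#'   all positive entries).
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
influence_edges <- function(t, cutoff = 0) {
  t <- as.matrix(t)
  idx <- which(t > 0 & t >= cutoff, arr.ind = TRUE)
  items <- rownames(t) %||% paste0("C", seq_len(nrow(t)))
  out <- data.frame(from = items[idx[, 1L]], to = items[idx[, 2L]],
                    weight = t[idx], stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}
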