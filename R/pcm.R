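#' Reciprocal pairwise comparison matrix
#'
#' Constructs and validates a pairwise comparison matrix (PCM): a positive
#' square matrix of ratio judgments with unit diagonal and reciprocal
#' symmetry `a_ji = 1/a_ij`. Entries are not restricted to the discrete
#' 1-9 judgment scale by default (only positivity and reciprocity are
#' enforced); set `strict_scale = TRUE` to additionally require membership of
#' the Saaty set \{1/9, ..., 1/2, 1, 2, ..., 9\}.
#'
#' @param entries square numeric matrix of positive judgments.
#' @param items optional character vector of item labels (defaults to the
#'   matrix dimnames, else `V1..Vn`).
#' @param tol tolerance for the unit-diagonal and reciprocity checks
#'   (`|a_ij * a_ji - 1| <= tol`).
#' @param strict_scale if `TRUE`, reject entries off the discrete 1-9 scale.
#' @return an object of class `pcm` (the matrix, with `items` attribute).
#' @export
pcm <- function(entries, items = NULL, tol = 1e-9, strict_scale = FALSE) {
  m <- as.matrix(entries)
  if (nrow(m) != ncol(m)) stop_("PCM must be square, got %dx%d", nrow(m), ncol(m))
  n <- nrow(m)
  if (n < 2L) stop_("PCM needs at least 2 items")
  if (!is.numeric(m) || any(!is.finite(m)))
    stop_("PCM entries must be finite numbers")
  if (any(m <= 0)) {
    ij <- which(m <= 0, arr.ind = TRUE)[1L, ]
    stop_("PCM entries must be positive; entry (%d, %d) is %g",
          ij[1L], ij[2L], m[ij[1L], ij[2L]])
  }
  if (any(abs(diag(m) - 1) > tol))
    stop_("PCM diagonal must be 1; item %d has a_ii = %g",
          which(abs(diag(m) - 1) > tol)[1L], diag(m)[abs(diag(m) - 1) > tol][1L])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(m[i, j] * m[j, i] - 1) > tol)
      stop_("PCM not reciprocal at (%d, %d): a_ij = %g but a_ji = %g (expected %g)",
            i, j, m[i, j], m[j, i], 1 / m[i, j])
  }
  if (strict_scale) {
    scale_vals <- c(1 / (9:2), 1:9)
    off <- abs(outer(as.vector(m), scale_vals, "-"))
    if (any(apply(off, 1L, min) > 1e-6)) {
      k <- which(apply(off, 1L, min) > 1e-6)[1L]
      ij <- arrayInd(k, dim(m))
      stop_("entry (%d, %d) = %g is not on the 1-9 judgment scale",
            ij[1L], ij[2L], m[k])
    }
  }
  items <- items %||% rownames(m) %||% paste0("V", seq_len(n))
  if (length(items) != n) stop_("items must have length %d", n)
  dimnames(m) <- list(items, items)
  structure(m, class = c("pcm", "matrix"), items = items)
}

#' @export
print.pcm <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise comparison matrix (%d items)\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Priority vector of a pairwise comparison matrix
#'
#' Derives item priorities as the normalized principal right eigenvector of
#' the PCM, computed by power iteration. For a consistent matrix
#' (`a_ij = w_i/w_j`) this recovers `w` exactly and the principal eigenvalue
#' equals `n`; inconsistency inflates `lambda_max` above `n`.
#'
#' @param x a [pcm()] (or a positive reciprocal matrix).
#' @param max_iter iteration cap for the power method.
#' @param tol convergence tolerance on the max absolute change of the
#'   normalized weight vector.
#' @return object of class `priority_vector`: list with `items`, `weights`
#'   (positive, summing to 1), `lambda_max` and `iterations`.
#' @export
priority_vector <- function(x, max_iter = 10000L, tol = 1e-12) {
  a <- unclass(as.matrix(x))
  n <- nrow(a)
  items <- attr(x, "items") %||% rownames(a) %||% paste0("V", seq_len(n))
  v <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- as.vector(a %*% v)
    w <- w / sum(w)
    if (max(abs(w - v)) < tol) { v <- w; converged <- TRUE; break }
    v <- w
  }
  if (!converged)
    stop_("power iteration did not converge after %d iterations (pathological input?)",
          max_iter)
  lambda <- mean(as.vector(a %*% v) / v)
  if (lambda < n - 1e-10)
    stop_("principal eigenvalue %g below matrix order %d; invalid PCM", lambda, n)
  structure(list(items = items, weights = stats::setNames(v, items),
                 lambda_max = lambda, iterations = it),
            class = "priority_vector")
}

#' @export
print.priority_vector <- function(x, digits = 4, ...) {
  cat(sprintf("Priority vector (%d items, lambda_max = %.6f)\n",
              length(x$weights), x$lambda_max))
  print(round(x$weights, digits))
  invisible(x)
}

## Saaty's published random index values, matrix orders 1..15
saaty_ri <- function() {
  c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51, 1.48,
    1.56, 1.57, 1.59)
}

#' Consistency index, ratio and screening flag of a PCM
#'
#' The consistency index is `CI = (lambda_max - n)/(n - 1)` and the
#' consistency ratio `CR = CI / RI(n)` with `RI` the random index for
#' matrices of order `n`. Judgments with `CR` above `review` (default 10%)
#' are flagged for review; above `exclude` (default 30%) they are flagged
#' for exclusion from the analysis. Matrices of order 2 are always perfectly
#' consistent and return `cr = 0` by convention.
#'
#' @param x a [pcm()].
#' @param review,exclude CR thresholds for the `review` and `exclude` flags.
#' @return object of class `consistency_report`: list with `n`, `lambda_max`,
#'   `ci`, `cr` and `flag` (one of `ok`, `review`, `exclude`).
#' @export
consistency <- function(x, review = 0.10, exclude = 0.30) {
  n <- nrow(as.matrix(x))
  ri <- saaty_ri()
  if (n > length(ri))
    stop_("unsupported PCM order %d: random index table covers n <= %d",
          n, length(ri))
  pv <- priority_vector(x)
  if (n <= 2L) {
    ci <- 0; cr <- 0
  } else {
    ci <- (pv$lambda_max - n) / (n - 1)
    cr <- ci / ri[n]
  }
  flag <- if (cr > exclude) "exclude" else if (cr > review) "review" else "ok"
  structure(list(n = n, lambda_max = pv$lambda_max, ci = ci, cr = cr,
                 flag = flag),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency: n = %d, lambda_max = %.6f, CI = %.4f, CR = %.4f [%s]\n",
              x$n, x$lambda_max, x$ci, x$cr, x$flag))
  invisible(x)
}

#' Aggregate individual judgments across judges
#'
#' Element-wise geometric mean of a list of PCMs over the same items
#' (aggregation of individual judgments). Reciprocity is preserved exactly:
#' the lower triangle is rebuilt from the aggregated upper triangle.
#'
#' @param pcms non-empty list of [pcm()] objects sharing one item list.
#' @return a [pcm()].
#' @export
aggregate_pcms <- function(pcms) {
  if (length(pcms) == 0L) stop_("cannot aggregate an empty list of PCMs")
  items <- attr(pcms[[1L]], "items")
  for (k in seq_along(pcms)) {
    if (!identical(attr(pcms[[k]], "items"), items))
      stop_("PCM %d has a different item list", k)
  }
  n <- length(items)
  logs <- Reduce(`+`, lapply(pcms, function(p) log(unclass(as.matrix(p)))))
  g <- exp(logs / length(pcms))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) g[j, i] <- 1 / g[i, j]
  diag(g) <- 1
  pcm(g, items = items)
}

#' Arithmetic mean of per-judge priority vectors
#'
#' The aggregation-of-priorities alternative to [aggregate_pcms()]: derive a
#' priority vector per judge, then average the weight vectors and
#' renormalize.
#'
#' @param pvs list of `priority_vector` objects over the same items.
#' @return named numeric weight vector summing to 1.
#' @export
mean_priorities <- function(pvs) {
  if (length(pvs) == 0L) stop_("empty list of priority vectors")
  items <- pvs[[1L]]$items
  w <- rowMeans(vapply(pvs, function(p) {
    if (!identical(p$items, items)) stop_("priority vectors disagree on items")
    p$weights
  }, numeric(length(items))))
  stats::setNames(normalize_weights(w), items)
}

#' Consistency screening of all judges in a survey bundle
#'
#' Computes a consistency report for every matrix of every modeler (the
#' per-category variable PCMs plus the category-level PCM) and applies the
#' screening rule: a modeler is excluded when any of their matrices carries
#' the `exclude` flag (CR above 30% by default); matrices between the review
#' and exclusion thresholds are listed for reporting but do not drop the
#' modeler.
#'
#' @param bundle a [survey_bundle()].
#' @param review,exclude CR thresholds passed to [consistency()].
#' @return object of class `screening`: list with `table` (one row per
#'   modeler x matrix: `modeler_id`, `matrix`, `n`, `ci`, `cr`, `flag`),
#'   `retained` and `excluded` modeler ids (in profile order), and `review`
#'   (the subset of rows flagged for review).
#' @export
screen_modelers <- function(bundle, review = 0.10, exclude = 0.30) {
  ids <- bundle$profiles$modeler_id
  rows <- list()
  for (id in ids) {
    mats <- c(bundle$pcms[[id]], list(categories = bundle$category_pcm[[id]]))
    for (nm in names(mats)) {
      cr <- consistency(mats[[nm]], review = review, exclude = exclude)
      rows[[length(rows) + 1L]] <- data.frame(
        modeler_id = id, matrix = nm, n = cr$n, ci = cr$ci, cr = cr$cr,
        flag = cr$flag, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  excluded <- unique(tab$modeler_id[tab$flag == "exclude"])
  retained <- ids[!ids %in% excluded]
  structure(list(table = tab,
                 retained = retained,
                 excluded = ids[ids %in% excluded],
                 review = tab[tab$flag == "review", , drop = FALSE]),
            class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat(sprintf("Consistency screening: %d retained, %d excluded, %d matrices flagged for review\n",
              length(x$retained), length(x$excluded), nrow(x$review)))
  cat(sprintf("Mean CR over retained matrices: %.3f\n",
              mean(x$table$cr[x$table$modeler_id %in% x$retained])))
  if (length(x$excluded))
    cat("Excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
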