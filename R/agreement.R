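#' Mid-rank score table from per-judge priorities
#'
#' Converts each judge's importance scores into mid-ranks of `1..n`
#' ascending in importance (the most important item gets rank `n`; tied
#' scores share the average of the ranks they span), so every row sums to
#' `n(n+1)/2`.
#'
#' @param x either a list of `priority_vector` objects over a shared item
#'   list, or a numeric matrix of scores with one row per judge.
#' @return numeric matrix of mid-ranks, judges in rows, items in columns.
#' @export
rank_scores <- function(x) {
  if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) {
    items <- x[[1L]]$items
    m <- t(vapply(x, function(p) {
      if (!identical(p$items, items))
        stop_("judge is missing items or has them in a different order")
      p$weights
    }, numeric(length(items))))
    colnames(m) <- items
  } else {
    m <- as.matrix(x)
  }
  ranks <- t(apply(m, 1L, rank))
  dimnames(ranks) <- dimnames(m)
  ranks
}

## per-judge tie correction: sum over tie groups of (t^3 - t)
tie_correction <- function(row) {
  t <- table(row)
  sum(t^3 - t)
}

#' Kendall's coefficient of concordance with tie correction
#'
#' Measures the agreement among `m` judges ranking `n` items:
#' `W = 12 SS / (m^2 (n^3 - n) - m F)`, where `SS` is the sum of squared
#' deviations of the per-item rank sums from their mean and
#' `F = sum_judges sum_tie-groups (t^3 - t)` corrects for tied ranks (with
#' no ties `F = 0` and the classic formula is recovered). `W = 1` indicates
#' identical rankings; `W = 0` indicates no agreement (all rank sums equal).
#' Significance is assessed against the no-agreement null via the chi-square
#' approximation `chi2 = m (n - 1) W` on `n - 1` degrees of freedom; an
#' exact permutation test (independent random permutations of each judge's
#' ranks) is available for small tables.
#'
#' @param ranks mid-rank matrix from [rank_scores()], judges in rows.
#' @param alpha significance level (default 0.05).
#' @param permutation if `TRUE`, also compute a permutation p-value.
#' @param n_perm number of permutations.
#' @return object of class `concordance_result`: list with `w`, `ss`,
#'   `f_correction`, `m`, `n`, `chi2`, `df`, `p_value`, `significant` and
#'   (optionally) `p_perm`.
#' @export
kendall_w <- function(ranks, alpha = 0.05, permutation = FALSE, n_perm = 999L) {
  r <- as.matrix(ranks)
  m <- nrow(r); n <- ncol(r)
  if (m < 2L) stop_("need at least 2 judges")
  if (n < 2L) stop_("need at least 2 items")
  expected <- n * (n + 1) / 2
  if (any(abs(rowSums(r) - expected) > 1e-8))
    stop_("row %d is not a mid-rank assignment of 1..%d (row sum %g != %g)",
          which(abs(rowSums(r) - expected) > 1e-8)[1L], n,
          rowSums(r)[abs(rowSums(r) - expected) > 1e-8][1L], expected)
  w_of <- function(r) {
    sums <- colSums(r)
    ss <- sum((sums - mean(sums))^2)
    f <- sum(apply(r, 1L, tie_correction))
    denom <- m^2 * (n^3 - n) - m * f
    if (denom <= 0)
      stop_("degenerate all-tied table: tie correction exhausts the rank variance")
    list(w = 12 * ss / denom, ss = ss, f = f)
  }
  res <- w_of(r)
  chi2 <- m * (n - 1) * res$w
  df <- n - 1
  p <- pchisq(chi2, df, lower.tail = FALSE)
  out <- list(w = res$w, ss = res$ss, f_correction = res$f, m = m, n = n,
              chi2 = chi2, df = df, p_value = p, significant = p < alpha)
  if (permutation) {
    obs <- res$w
    hits <- 0L
    for (b in seq_len(n_perm)) {
      rp <- t(apply(r, 1L, sample))
      if (w_of(rp)$w >= obs - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (m = %d judges, n = %d items)\n", x$w, x$m, x$n))
  cat(sprintf("chi2 = %.3f on %d df, p = %.4g%s\n", x$chi2, x$df, x$p_value,
              if (x$significant) " *" else ""))
  if (!is.null(x$p_perm)) cat(sprintf("permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Concordance among modelers, per category and overall
#'
#' For each variable category, derives every retained modeler's priority
#' vector from their PCM, ranks it and computes the tie-corrected Kendall
#' coefficient; a final row does the same for the category-level PCMs over
#' the categories themselves.
#'
#' @param bundle a [survey_bundle()].
#' @param retained modeler ids to use (default: [screen_modelers()]'s
#'   retained list). At least 2 required.
#' @param alpha significance level.
#' @return data.frame with one row per category plus a `categories` row:
#'   `matrix`, `n_items`, `n_judges`, `w`, `chi2`, `df`, `p_value`,
#'   `significant`.
#' @export
concordance_by_category <- function(bundle, retained = NULL, alpha = 0.05) {
  retained <- retained %||% screen_modelers(bundle)$retained
  if (length(retained) < 2L) stop_("need at least 2 retained judges")
  codes <- protocol_categories(bundle$protocol)
  one <- function(label, pcms) {
    pvs <- lapply(pcms, priority_vector)
    res <- kendall_w(rank_scores(pvs), alpha = alpha)
    data.frame(matrix = label, n_items = res$n, n_judges = res$m, w = res$w,
               chi2 = res$chi2, df = res$df, p_value = res$p_value,
               significant = res$significant, stringsAsFactors = FALSE)
  }
  rows <- lapply(codes, function(code)
    one(code, lapply(retained, function(id) bundle$pcms[[id]][[code]])))
  rows <- c(rows, list(one("categories",
                           lapply(retained, function(id) bundle$category_pcm[[id]]))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilks' lambda one-way MANOVA
#'
#' Tests whether group mean vectors differ across a multivariate response:
#' `Lambda = det(W) / det(W + B)` with `W` and `B` the within- and
#' between-group cross-product matrices; values near 1 indicate no group
#' separation. The p-value uses Rao's F approximation. The within-group
#' matrix must be non-singular, which requires more observations than
#' feature columns (reduce the feature set otherwise, e.g. analyze one
#' category at a time and drop one column of a sum-constrained weight
#' matrix).
#'
#' @param features numeric matrix or data.frame, one row per judge.
#' @param groups group labels, one per row of `features`; at least 2 groups
#'   with at least 2 judges each.
#' @param factor_label optional label naming the grouping factor.
#' @param alpha significance level.
#' @return object of class `manova_result`: list with `wilks_lambda`,
#'   `statistic` (approximate F), `df1`, `df2`, `p_value`, `significant`,
#'   `group_factor`, `n`, `p`, `n_groups`.
#' @export
wilks_manova <- function(features, groups, factor_label = "group", alpha = 0.05) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  g <- droplevels(as.factor(groups))
  if (length(g) != nrow(x)) stop_("groups must have one label per row of features")
  if (nlevels(g) < 2L) stop_("need at least 2 groups")
  if (any(table(g) < 2L)) stop_("every group needs at least 2 judges")
  n <- nrow(x); p <- ncol(x); k <- nlevels(g)
  if (n <= p)
    stop_("more feature columns (%d) than residual degrees of freedom allow (n = %d); reduce the feature set",
          p, n)
  grand <- colMeans(x)
  w <- matrix(0, p, p); b <- matrix(0, p, p)
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    mu <- colMeans(xi)
    ci <- sweep(xi, 2L, mu)
    w <- w + crossprod(ci)
    b <- b + nrow(xi) * tcrossprod(mu - grand)
  }
  det_w <- det(w)
  det_t <- det(w + b)
  if (!is.finite(det_w) || det_w <= 0 || !is.finite(det_t) || det_t <= 0)
    stop_("singular within-group cross-product matrix; reduce the feature set")
  lambda <- det_w / det_t
  lambda <- min(lambda, 1)
  q <- k - 1
  t_exp <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  ww <- n - 1 - (p + k) / 2
  df2 <- ww * t_exp - (p * q - 2) / 2
  lam_t <- lambda^(1 / t_exp)
  fstat <- (1 - lam_t) / lam_t * df2 / df1
  pval <- pf(fstat, df1, df2, lower.tail = FALSE)
  structure(list(wilks_lambda = lambda, statistic = fstat, df1 = df1,
                 df2 = df2, p_value = pval, significant = pval < alpha,
                 group_factor = factor_label, n = n, p = p, n_groups = k),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4f (factor: %s; %d groups, n = %d, p = %d)\n",
              x$wilks_lambda, x$group_factor, x$n_groups, x$n, x$p))
  cat(sprintf("approx F = %.3f on (%g, %g) df, p = %.4g%s\n", x$statistic,
              x$df1, x$df2, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Group-difference test of modeler ratings for one category
#'
#' Builds the judges-by-variables rating matrix for one category (each
#' retained modeler's priority weights from their PCM), drops one column
#' (weights sum to 1, so the full matrix is rank-deficient by construction)
#' and runs a one-way Wilks' lambda MANOVA on the chosen grouping factor.
#' Groups with fewer than 2 modelers are dropped with a message (a survey
#' over many model types inevitably has singleton groups). Univariate
#' per-variable follow-up ANOVAs are reported with unadjusted p-values by
#' default; Holm adjustment is available via `adjust = "holm"`.
#'
#' @param bundle a [survey_bundle()].
#' @param factor `"model_type"` or `"experience_class"`.
#' @param category category code, or `"categories"` for the category-level
#'   PCMs.
#' @param retained modeler ids (default: screening).
#' @param drop_item item whose column is dropped from the MANOVA features
#'   (default: the last item).
#' @param adjust `"none"` (default) or `"holm"` for the univariate p-values.
#' @param alpha significance level.
#' @return list with elements `factor`, `manova` (a [wilks_manova()]
#'   result), `univariate` (data.frame: `variable`, `f`, `p_value`,
#'   `significant`), `groups` (table of group sizes used).
#' @export
group_difference <- function(bundle, factor = c("model_type", "experience_class"),
                             category, retained = NULL, drop_item = NULL,
                             adjust = c("none", "holm"), alpha = 0.05) {
  factor <- match.arg(factor)
  adjust <- match.arg(adjust)
  retained <- retained %||% screen_modelers(bundle)$retained
  mats <- if (identical(category, "categories"))
    lapply(retained, function(id) bundle$category_pcm[[id]])
  else
    lapply(retained, function(id) {
      p <- bundle$pcms[[id]][[category]]
      if (is.null(p)) stop_("unknown category: %s", category)
      p
    })
  weights <- t(vapply(mats, function(p) priority_vector(p)$weights,
                      numeric(nrow(mats[[1L]]))))
  colnames(weights) <- attr(mats[[1L]], "items")
  prof <- bundle$profiles[match(retained, bundle$profiles$modeler_id), ]
  g <- prof[[factor]]
  sizes <- table(g)
  keep_lev <- names(sizes)[sizes >= 2L]
  if (length(keep_lev) < length(sizes))
    message(sprintf("group_difference: dropping %d singleton group(s) of %s",
                    sum(sizes < 2L), factor))
  keep <- g %in% keep_lev
  if (length(unique(g[keep])) < 2L)
    stop_("need at least 2 groups with at least 2 judges each")
  x <- weights[keep, , drop = FALSE]
  gg <- factor(g[keep])
  drop_item <- drop_item %||% colnames(x)[ncol(x)]
  feat <- x[, setdiff(colnames(x), drop_item), drop = FALSE]
  man <- wilks_manova(feat, gg, factor_label = factor, alpha = alpha)
  uni <- do.call(rbind, lapply(colnames(x), function(v) {
    fit <- stats::anova(stats::lm(x[, v] ~ gg))
    data.frame(variable = v, f = fit[["F value"]][1L],
               p_value = fit[["Pr(>F)"]][1L], stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") uni$p_value <- stats::p.adjust(uni$p_value, "holm")
  uni$significant <- uni$p_value < alpha
  rownames(uni) <- NULL
  list(factor = factor, manova = man, univariate = uni,
       groups = table(droplevels(gg)))
}
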