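#' Cumulative stage importance
#'
#' Running sum of the per-stage importance shares: `sigma_p[s]` is the
#' cumulative modeling importance of all input variables released up to and
#' including stage `s`. Every stage must carry strictly positive importance
#' (a zero stage would divide the error rate by zero downstream).
#'
#' @param x an [importance_table()], a data.frame with `stage`/`total`
#'   columns, or a numeric vector of per-stage importances.
#' @return numeric vector of cumulative importances, named `stage_1..`.
#' @export
cumulative_importance <- function(x) {
  totals <- if (inherits(x, "importance_table")) x$stages$total
  else if (is.data.frame(x)) x$total
  else as.numeric(x)
  if (any(totals <= 0))
    stop_("stage %d has zero (or negative) total importance",
          which(totals <= 0)[1L])
  stats::setNames(cumsum(totals), paste0("stage_", seq_along(totals)))
}

#' Model error rate per unit of cumulative importance (MER)
#'
#' Links the ensemble prediction error to the modeling importance of the
#' data released up to each stage. In the default (ratio) form the model
#' error rate at stage `s` is `mer_s = rrmse_s / sigma_p_s`: the error per
#' unit of cumulative importance accessed. The stage-over-stage summary
#' `pct_change_vs_stage1 = 100 (mer_s - mer_1) / mer_1` expresses each
#' stage's error rate relative to the blind first stage. The incremental
#' alternative (`incremental = TRUE`) uses stage-to-stage differences,
#' `delta rrmse / delta sigma_p` (stage 1 keeps the ratio form), and is
#' labelled distinctly in the output.
#'
#' @param series an [rrmse_series()] or bare numeric vector of per-stage
#'   RRMSE values.
#' @param sigma_p cumulative per-stage importance from
#'   [cumulative_importance()]; strictly positive, same length as the
#'   series.
#' @param incremental use the incremental (first-difference) form.
#' @return a data.frame of class `mer_table` with columns `output`, `stage`,
#'   `rrmse`, `sigma_p`, `mer`, `pct_change_vs_stage1`; attributes `unit`
#'   and `method` (`"cumulative_ratio"` or `"incremental"`).
#' @export
mer <- function(series, sigma_p, incremental = FALSE) {
  if (is.numeric(series)) series <- rrmse_series("output", series)
  rr <- series$values
  sp <- as.numeric(sigma_p)
  if (length(rr) != length(sp))
    stop_("series has %d stages but sigma_p has %d", length(rr), length(sp))
  if (any(sp <= 0)) stop_("sigma_p must be strictly positive at every stage")
  if (incremental) {
    d_rr <- c(rr[1L], diff(rr))
    d_sp <- c(sp[1L], diff(sp))
    if (any(d_sp == 0)) stop_("incremental form undefined: zero importance increment")
    m <- d_rr / d_sp
  } else {
    m <- rr / sp
  }
  pct <- if (m[1L] == 0) rep(NA_real_, length(m)) else 100 * (m - m[1L]) / m[1L]
  out <- data.frame(output = series$output, stage = seq_along(rr), rrmse = rr,
                    sigma_p = sp, mer = m, pct_change_vs_stage1 = pct,
                    stringsAsFactors = FALSE)
  attr(out, "unit") <- series$unit
  attr(out, "method") <- if (incremental) "incremental" else "cumulative_ratio"
  class(out) <- c("mer_table", "data.frame")
  out
}

#' Combine MER tables into one long-format report
#'
#' Stacks one or more [mer()] tables into a single long table ordered by
#' output name and stage, optionally writing it as CSV.
#'
#' @param tables a `mer_table` or list of them.
#' @param path optional CSV output path.
#' @return data.frame with columns `output`, `stage`, `rrmse`, `sigma_p`,
#'   `mer`, `pct_change_vs_stage1`, `unit`, `method`.
#' @export
mer_report <- function(tables, path = NULL) {
  if (inherits(tables, "mer_table")) tables <- list(tables)
  if (length(tables) == 0L) stop_("no MER tables to report")
  out <- do.call(rbind, lapply(tables, function(tt) {
    df <- as.data.frame(tt)
    df$unit <- attr(tt, "unit")
    df$method <- attr(tt, "method")
    df
  }))
  out <- out[order(out$output, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
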