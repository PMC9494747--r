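#' Survey bundle: profiles, judgment matrices and influence matrices
#'
#' Bundles everything one survey wave produced: the protocol, the modeler
#' profiles, one variable-level PCM per (modeler, category), one
#' category-level PCM per modeler and one direct-influence matrix per
#' modeler. Item lists of every matrix are checked against the protocol, in
#' protocol order.
#'
#' @param protocol an [protocol_config()] object.
#' @param profiles data.frame with columns `modeler_id`, `model_type`,
#'   `experience_class`; `modeler_id` must be unique.
#' @param pcms named list (by modeler id) of named lists (by category code)
#'   of [pcm()] objects over that category's variables.
#' @param category_pcm named list (by modeler id) of [pcm()] objects over the
#'   category codes.
#' @param influence named list (by modeler id) of [direct_influence()]
#'   matrices over the category codes.
#' @return an object of class `survey_bundle`.
#' @export
survey_bundle <- function(protocol, profiles, pcms, category_pcm, influence) {
  validate_protocol(protocol)
  need <- c("modeler_id", "model_type", "experience_class")
  if (!all(need %in% names(profiles)))
    stop_("profiles must have columns: %s", paste(need, collapse = ", "))
  ids <- profiles$modeler_id
  if (anyDuplicated(ids))
    stop_("duplicate modeler_id: %s", ids[duplicated(ids)][1L])
  codes <- protocol_categories(protocol)
  for (id in ids) {
    pm <- pcms[[id]]
    if (is.null(pm)) stop_("missing variable PCMs for modeler %s", id)
    for (code in codes) {
      p <- pm[[code]]
      if (is.null(p)) stop_("missing PCM for (modeler %s, category %s)", id, code)
      want <- category_items(protocol, code)
      if (!identical(attr(p, "items"), want))
        stop_("PCM items for (modeler %s, category %s) do not match the protocol order",
              id, code)
    }
    cp <- category_pcm[[id]]
    if (is.null(cp)) stop_("missing category-level PCM for modeler %s", id)
    if (!identical(attr(cp, "items"), as.character(codes)))
      stop_("category-level PCM items for modeler %s do not match the protocol categories", id)
    im <- influence[[id]]
    if (is.null(im)) stop_("missing influence matrix for modeler %s", id)
    if (!identical(attr(im, "items"), as.character(codes)))
      stop_("influence matrix items for modeler %s do not match the protocol categories", id)
  }
  extra <- setdiff(unique(c(names(pcms), names(category_pcm), names(influence))), ids)
  if (length(extra))
    stop_("matrices reference modeler_id absent from profiles: %s", extra[1L])
  structure(list(protocol = protocol,
                 profiles = profiles[, need, drop = FALSE],
                 pcms = pcms[ids],
                 category_pcm = category_pcm[ids],
                 influence = influence[ids]),
            class = "survey_bundle")
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat(sprintf("Survey bundle: %d modelers, %d categories, %d variables\n",
              nrow(x$profiles), length(x$protocol$categories),
              nrow(protocol_variables(x$protocol))))
  invisible(x)
}

matrix_long_rows <- function(id, type, category, m) {
  items <- rownames(m)
  n <- nrow(m)
  data.frame(modeler_id = id, matrix_type = type, category = category,
             row_item = rep(items, times = n), col_item = rep(items, each = n),
             value = fmt_num(as.vector(unclass(m))), stringsAsFactors = FALSE)
}

#' Write a survey bundle to CSV files
#'
#' Two on-disk dialects are supported. `"long"` writes `profiles.csv` plus a
#' single `matrices.csv` in long format (`modeler_id`, `matrix_type` in
#' \{`variables`, `categories`, `influence`\}, `category`, `row_item`,
#' `col_item`, `value`). `"per-matrix"` writes `profiles.csv` plus one square
#' CSV per matrix, named `<modeler>__<category>.csv`,
#' `<modeler>__categories.csv` and `<modeler>__influence.csv`. Matrix entries
#' are stored as decimal text at full double precision, so a write/read
#' round trip is bit-identical.
#'
#' @param bundle a [survey_bundle()].
#' @param dir output directory (created if needed).
#' @param dialect `"long"` (default) or `"per-matrix"`.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(bundle, dir, dialect = c("long", "per-matrix")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$profiles, file.path(dir, "profiles.csv"), row.names = FALSE)
  ids <- bundle$profiles$modeler_id
  if (dialect == "long") {
    rows <- list()
    for (id in ids) {
      for (code in names(bundle$pcms[[id]]))
        rows[[length(rows) + 1L]] <-
          matrix_long_rows(id, "variables", code, bundle$pcms[[id]][[code]])
      rows[[length(rows) + 1L]] <-
        matrix_long_rows(id, "categories", "", bundle$category_pcm[[id]])
      rows[[length(rows) + 1L]] <-
        matrix_long_rows(id, "influence", "", bundle$influence[[id]])
    }
    write.csv(do.call(rbind, rows), file.path(dir, "matrices.csv"),
              row.names = FALSE)
  } else {
    wide <- function(m, path) {
      df <- data.frame(item = rownames(m), stringsAsFactors = FALSE)
      vals <- apply(unclass(m), 2L, fmt_num)
      df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
      names(df) <- c("item", colnames(m))
      write.csv(df, path, row.names = FALSE)
    }
    for (id in ids) {
      for (code in names(bundle$pcms[[id]]))
        wide(bundle$pcms[[id]][[code]],
             file.path(dir, sprintf("%s__%s.csv", id, code)))
      wide(bundle$category_pcm[[id]], file.path(dir, sprintf("%s__categories.csv", id)))
      wide(bundle$influence[[id]], file.path(dir, sprintf("%s__influence.csv", id)))
    }
  }
  invisible(dir)
}

build_matrix <- function(rows, items, what) {
  m <- matrix(NA_real_, length(items), length(items), dimnames = list(items, items))
  ri <- match(rows$row_item, items)
  ci <- match(rows$col_item, items)
  if (any(is.na(ri)) || any(is.na(ci)))
    stop_("%s: item not in protocol: %s", what,
          c(rows$row_item[is.na(ri)], rows$col_item[is.na(ci)])[1L])
  m[cbind(ri, ci)] <- as.numeric(rows$value)
  if (any(is.na(m)))
    stop_("%s: missing matrix entries", what)
  m
}

#' Read a survey bundle written by [write_survey()]
#'
#' Detects the dialect: if `dir` contains `matrices.csv` the long format is
#' read, otherwise the per-matrix files are globbed. Every matrix is
#' re-validated on load (shape, positivity, unit diagonal, reciprocity
#' within `1e-9`; influence matrices: non-negativity, zero diagonal).
#'
#' @param dir directory holding the survey CSV files.
#' @param protocol the protocol the responses refer to.
#' @return a [survey_bundle()].
#' @export
load_survey <- function(dir, protocol) {
  validate_protocol(protocol)
  pf <- file.path(dir, "profiles.csv")
  if (!file.exists(pf)) stop_("profiles.csv not found in %s", dir)
  profiles <- read.csv(pf, stringsAsFactors = FALSE, colClasses = "character")
  codes <- protocol_categories(protocol)
  ids <- profiles$modeler_id
  pcms <- list(); category_pcm <- list(); influence <- list()
  longf <- file.path(dir, "matrices.csv")
  if (file.exists(longf)) {
    long <- read.csv(longf, stringsAsFactors = FALSE,
                     colClasses = c(value = "character"))
    for (id in ids) {
      sub <- long[long$modeler_id == id, , drop = FALSE]
      pm <- list()
      for (code in codes) {
        rows <- sub[sub$matrix_type == "variables" & sub$category == code, ,
                    drop = FALSE]
        if (!nrow(rows)) stop_("missing matrix for (modeler %s, category %s)", id, code)
        pm[[code]] <- pcm(build_matrix(rows, category_items(protocol, code),
                                       sprintf("modeler %s, category %s", id, code)))
      }
      pcms[[id]] <- pm
      rows <- sub[sub$matrix_type == "categories", , drop = FALSE]
      if (!nrow(rows)) stop_("missing category-level PCM for modeler %s", id)
      category_pcm[[id]] <- pcm(build_matrix(rows, codes,
                                             sprintf("modeler %s, categories", id)))
      rows <- sub[sub$matrix_type == "influence", , drop = FALSE]
      if (!nrow(rows)) stop_("missing influence matrix for modeler %s", id)
      influence[[id]] <- direct_influence(build_matrix(rows, codes,
                                                       sprintf("modeler %s, influence", id)))
    }
  } else {
    read_wide <- function(path, items, what) {
      if (!file.exists(path)) stop_("missing matrix file: %s", path)
      df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = "character")
      m <- as.matrix(df[, -1L, drop = FALSE])
      storage.mode(m) <- "double"
      rownames(m) <- df$item
      if (!identical(rownames(m), items) || !identical(colnames(m), items))
        stop_("%s: items do not match the protocol order", what)
      m
    }
    for (id in ids) {
      pm <- list()
      for (code in codes)
        pm[[code]] <- pcm(read_wide(file.path(dir, sprintf("%s__%s.csv", id, code)),
                                    category_items(protocol, code),
                                    sprintf("modeler %s, category %s", id, code)))
      pcms[[id]] <- pm
      category_pcm[[id]] <- pcm(read_wide(file.path(dir, sprintf("%s__categories.csv", id)),
                                          codes, sprintf("modeler %s, categories", id)))
      influence[[id]] <- direct_influence(
        read_wide(file.path(dir, sprintf("%s__influence.csv", id)),
                  codes, sprintf("modeler %s, influence", id)))
    }
  }
  survey_bundle(protocol, profiles, pcms, category_pcm, influence)
}

#' Per-stage ensemble error series
#'
#' @param output name of the simulated output (e.g. `"N2O"`, `"yield"`).
#' @param values non-negative RRMSE values, one per stage.
#' @param unit `"fraction"` or `"percent"`; recorded, never converted.
#' @return object of class `rrmse_series`.
#' @export
rrmse_series <- function(output, values, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_("RRMSE values must be finite numbers")
  if (any(values < 0))
    stop_("RRMSE values must be non-negative; %s has %g", output, min(values))
  structure(list(output = output, values = as.numeric(values), unit = unit),
            class = "rrmse_series")
}

#' Load per-stage RRMSE series from a CSV table
#'
#' Expects one row per output and one column per stage named `stage_1`,
#' `stage_2`, ...; a column `output` and optionally a column `unit`
#' (`fraction` or `percent`, default `fraction`). All stages `1..n_stages`
#' must be present and all values non-negative.
#'
#' @param path CSV file path.
#' @param n_stages expected number of stages (default 5).
#' @return list of [rrmse_series()] objects.
#' @export
load_rrmse <- function(path, n_stages = 5L) {
  if (!file.exists(path)) stop_("RRMSE file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"output" %in% names(df)) stop_("RRMSE table needs an 'output' column")
  stage_cols <- paste0("stage_", seq_len(n_stages))
  missing <- setdiff(stage_cols, names(df))
  if (length(missing))
    stop_("RRMSE table missing stage column(s): %s", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    rrmse_series(df$output[i], as.numeric(df[i, stage_cols]),
                 unit = if ("unit" %in% names(df)) df$unit[i] else "fraction")
  })
}

#' Write RRMSE series to the CSV layout read by [load_rrmse()]
#' @param series a [rrmse_series()] or list of them.
#' @param path CSV file path.
#' @export
write_rrmse <- function(series, path) {
  if (inherits(series, "rrmse_series")) series <- list(series)
  k <- length(series[[1L]]$values)
  df <- do.call(rbind, lapply(series, function(s) {
    row <- data.frame(output = s$output, unit = s$unit, stringsAsFactors = FALSE)
    vals <- as.data.frame(as.list(s$values))
    names(vals) <- paste0("stage_", seq_len(k))
    cbind(row, vals)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
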