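#' Protocol configuration: categories, variables and release stages
#'
#' A protocol describes the structure of a staged model-intercomparison
#' survey: input variables grouped into categories, each variable tagged with
#' the stage of the protocol at which it was first released to the modelers.
#' Every downstream table (priorities, influence profiles, importances) is
#' indexed by this structure, in protocol order.
#'
#' @param categories list of categories, each a list with elements `code`
#'   (short unique identifier), `label` (free text) and `variables` (a
#'   data.frame with columns `name` and `stage`).
#' @param n_stages number of release stages (default 5).
#' @return an object of class `mcdm_protocol`.
#' @seealso [load_protocol()], [default_protocol()], [protocol_variables()]
#' @export
protocol_config <- function(categories, n_stages = 5L) {
  x <- structure(list(categories = categories, n_stages = as.integer(n_stages)),
                 class = "mcdm_protocol")
  validate_protocol(x)
}

validate_protocol <- function(x) {
  if (!is.list(x$categories) || length(x$categories) == 0L)
    stop_("protocol must contain at least one category")
  if (!is_count(x$n_stages))
    stop_("n_stages must be a positive integer")
  codes <- vapply(x$categories, function(cc) as.character(cc$code %||% ""), "")
  if (any(codes == ""))
    stop_("every category needs a non-empty code")
  if (anyDuplicated(codes))
    stop_("duplicate category code: %s", codes[duplicated(codes)][1L])
  for (cc in x$categories) {
    v <- cc$variables
    if (is.null(v) || nrow(v) < 2L)
      stop_("category %s has fewer than 2 variables; a pairwise comparison matrix needs n >= 2",
            cc$code)
    if (!all(c("name", "stage") %in% names(v)))
      stop_("category %s: variables need columns 'name' and 'stage'", cc$code)
    if (anyDuplicated(v$name))
      stop_("duplicate variable '%s' in category %s",
            v$name[duplicated(v$name)][1L], cc$code)
    st <- v$stage
    if (!is.numeric(st) || any(is.na(st)) || any(st != round(st)) ||
        any(st < 1L) || any(st > x$n_stages))
      stop_("category %s: stages must be integers in 1..%d", cc$code, x$n_stages)
  }
  vars <- protocol_variables(x)
  missing_stage <- setdiff(seq_len(x$n_stages), unique(vars$stage))
  if (length(missing_stage))
    stop_("no variable assigned to stage(s): %s",
          paste(missing_stage, collapse = ", "))
  x
}

#' Load a protocol configuration from a JSON file
#'
#' The file holds `n_stages` and a `categories` array; each category has a
#' `code`, a `label` and a `variables` array of `{name, stage}` records. The
#' parsed protocol is validated: category codes must be unique, every
#' category needs at least two variables, variable names must be unique
#' within a category and every stage must receive at least one variable.
#'
#' @param path path to the JSON config file.
#' @return an `mcdm_protocol` object.
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop_("protocol file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- lapply(raw$categories, function(cc) {
    vars <- data.frame(
      name  = vapply(cc$variables, function(v) as.character(v$name), ""),
      stage = vapply(cc$variables, function(v) as.integer(v$stage), 1L),
      stringsAsFactors = FALSE
    )
    list(code = as.character(cc$code), label = as.character(cc$label %||% cc$code),
         variables = vars)
  })
  protocol_config(cats, n_stages = raw$n_stages %||% 5L)
}

#' The packaged default protocol (7 categories, 55 variables, 5 stages)
#'
#' Encodes the staged ensemble design analyzed by the package: 55 input
#' variables in the categories SOI, CL, MPDE, SI, LTCL, LTMP and EDS,
#' released across five calibration stages (28 variables at stage 1).
#'
#' @return an `mcdm_protocol` object.
#' @export
default_protocol <- function() {
  load_protocol(system.file("extdata", "protocol_default.json",
                            package = "danpsurvey", mustWork = TRUE))
}

#' Category codes of a protocol, in protocol order
#' @param protocol an `mcdm_protocol`.
#' @export
protocol_categories <- function(protocol) {
  vapply(protocol$categories, `[[`, "", "code")
}

#' Flat variable table of a protocol
#'
#' @param protocol an `mcdm_protocol`.
#' @return data.frame with columns `variable`, `category`, `stage`, one row
#'   per input variable in protocol order.
#' @export
protocol_variables <- function(protocol) {
  out <- do.call(rbind, lapply(protocol$categories, function(cc) {
    data.frame(variable = cc$variables$name, category = cc$code,
               stage = as.integer(cc$variables$stage), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## variable names of one category, protocol order
category_items <- function(protocol, code) {
  for (cc in protocol$categories) if (cc$code == code) return(cc$variables$name)
  stop_("unknown category code: %s", code)
}

#' @export
print.mcdm_protocol <- function(x, ...) {
  vars <- protocol_variables(x)
  cat(sprintf("Survey protocol: %d categories, %d variables, %d stages\n",
              length(x$categories), nrow(vars), x$n_stages))
  for (cc in x$categories)
    cat(sprintf("  %-5s %-42s %2d variables\n", cc$code, cc$label,
                nrow(cc$variables)))
  cat("Variables per stage:",
      paste(sprintf("s%d=%d", seq_len(x$n_stages),
                    tabulate(vars$stage, x$n_stages)), collapse = " "), "\n")
  invisible(x)
}
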