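# File formats.
#
# Quarterly tables (raw or published) are comma-separated with a header:
# case_id, quarter, one column per QID attribute (numeric intervals
# serialized "lo-hi", taxonomy nodes by label), then semicolon-joined
# `drugs` and `sensitive` lists.  Taxonomies are tab-separated edge lists,
# configs are YAML.

#' Read / write a quarterly SRS table
#'
#' Round-trips both raw quarters and published releases: QID columns are
#' kept as text (`"32"`, `"30-40"`, `"ANY"`) so that write-then-read
#' reproduces the structure exactly.
#'
#' @param df quarterly data frame.
#' @param path file path.
#' @return `read_srs_table()` returns a data frame with integer `case_id`
#'   and `quarter` and character remaining columns.
#' @export
read_srs_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("case_id", "quarter") %in% names(df)))
    stop(path, ": quarterly tables need 'case_id' and 'quarter' columns")
  df$case_id <- as.integer(df$case_id)
  df$quarter <- as.integer(df$quarter)
  df
}

#' @rdname read_srs_table
#' @export
write_srs_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' The YAML configuration names the QID schema (taxonomy files are resolved
#' relative to the config file), the privacy parameters, the threshold
#' scheme, the algorithm variant and the file layout.  See the packaged
#' example under `system.file("extdata", "demo_config.yaml", package =
#' "ppmsanon")`.
#'
#' @param path YAML file path.
#' @return List with `schema` ([srs_schema]), `params` ([privacy_params]),
#'   `variant`, `threshold_spec`, and any of `quarters` (input paths),
#'   `synth` ([synth_config]), `rules` (list of [adr_rule]) and `output`
#'   that the file provides.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  if (is.null(cfg$schema)) stop("config needs a 'schema' section")
  attrs <- lapply(cfg$schema, function(a) {
    if (identical(a$kind, "numeric"))
      attr_numeric(a$name, a$min, a$max)
    else if (identical(a$kind, "categorical"))
      attr_categorical(a$name, read_taxonomy(rel(a$taxonomy)))
    else stop("attribute kind must be 'numeric' or 'categorical'")
  })
  schema <- srs_schema(attrs)

  ts <- cfg$thresholds
  thresholds <- if (is.null(ts)) threshold_map()
  else if (!is.null(ts$file)) read_thresholds(rel(ts$file))
  else if (identical(ts$mode, "uniform"))
    set_thresholds(NULL, "uniform", theta = ts$theta)
  else if (identical(ts$mode, "levelwise")) {
    lv <- utils::read.table(rel(ts$levels), sep = "\t", header = TRUE,
                            colClasses = "character")
    set_thresholds(stats::setNames(rep(1, nrow(lv)), lv$term), "levelwise",
                   levels = stats::setNames(lv$level, lv$term))
  } else if (identical(ts$mode, "frequency"))
    ts  # frequency bands are derived from the data at run time
  else stop("unknown threshold mode")

  params <- if (inherits(thresholds, "threshold_map"))
    privacy_params(k = cfg$k %||% 5, thresholds = thresholds,
                   lifespan_x = cfg$lifespan_x %||% 8,
                   seed = cfg$seed %||% 1)
  else NULL
  out <- list(schema = schema, params = params,
              threshold_spec = ts, variant = cfg$variant %||% "ppms++",
              k = cfg$k %||% 5, lifespan_x = cfg$lifespan_x %||% 8,
              seed = cfg$seed %||% 1, output = cfg$output %||% base)
  if (!is.null(cfg$quarters)) out$quarters <- rel(unlist(cfg$quarters))
  if (!is.null(cfg$synth))
    out$synth <- do.call(synth_config,
                         c(cfg$synth, list(seed = cfg$seed %||% 1)))
  if (!is.null(cfg$rules)) out$rules <- read_rules(rel(cfg$rules))
  if (!grepl("^/", out$output)) out$output <- file.path(base, out$output)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
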