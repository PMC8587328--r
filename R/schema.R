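#' Define the quasi-identifier schema of an SRS table
#'
#' The schema lists the quasi-identifier (QID) attributes of a spontaneous
#' reporting system table: numeric attributes carry a global `[min, max]`
#' range (used to normalize information loss), categorical attributes carry a
#' [taxonomy] tree rooted at `"ANY"`.
#'
#' @param ... attribute definitions created by [attr_numeric()] or
#'   [attr_categorical()].
#' @return An object of class `srs_schema`.
#' @examples
#' sch <- srs_schema(attr_categorical("Sex", sex_taxonomy()),
#'                   attr_numeric("Age", 0, 100))
#' @export
srs_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && is.list(attrs[[1]]) &&
      !inherits(attrs[[1]], "srs_attr"))
    attrs <- attrs[[1]]
  nm <- vapply(attrs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate attribute names")
  names(attrs) <- nm
  structure(list(
    attrs = attrs,
    num = nm[vapply(attrs, `[[`, "", "kind") == "numeric"],
    cat = nm[vapply(attrs, `[[`, "", "kind") == "categorical"]),
    class = "srs_schema")
}

#' @rdname srs_schema
#' @param name attribute name (a column of the quarterly table).
#' @param global_min,global_max global range of a numeric attribute over the
#'   whole data set (units are the attribute's own, e.g. years or kg).
#' @export
attr_numeric <- function(name, global_min, global_max) {
  if (!(global_min < global_max))
    stop("numeric attribute '", name, "': global_min must be < global_max")
  structure(list(name = name, kind = "numeric",
                 min = global_min, max = global_max),
            class = "srs_attr")
}

#' @rdname srs_schema
#' @param tax a [taxonomy] for a categorical attribute.
#' @export
attr_categorical <- function(name, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  structure(list(name = name, kind = "categorical", taxonomy = tax),
            class = "srs_attr")
}

#' @export
print.srs_schema <- function(x, ...) {
  cat("SRS QID schema:\n")
  for (a in x$attrs) {
    if (a$kind == "numeric")
      cat("  ", a$name, ": numeric [", a$min, ", ", a$max, "]\n", sep = "")
    else
      cat("  ", a$name, ": categorical, taxonomy height ",
          a$taxonomy$height, "\n", sep = "")
  }
  invisible(x)
}

schema_check <- function(schema) {
  if (!inherits(schema, "srs_schema")) stop("'schema' must be an srs_schema")
  for (a in schema$attrs[schema$num])
    if (a$max - a$min <= 0) stop("zero-width global numeric range for ", a$name)
  invisible(schema)
}

# ---- compact matrix representation of QID columns ------------------------
#
# A set of records is carried as a "qmat": num_lo / num_hi numeric matrices
# (one column per numeric attribute) and cat integer matrix of taxonomy node
# ids (one column per categorical attribute).  Raw leaf rows have lo == hi
# and leaf nodes.

qid_cols <- function(schema) c(schema$num, schema$cat)

df_to_qmat <- function(df, schema) {
  n <- nrow(df)
  m_num <- length(schema$num); m_cat <- length(schema$cat)
  num_lo <- matrix(NA_real_, n, m_num, dimnames = list(NULL, schema$num))
  num_hi <- num_lo
  cat <- matrix(NA_integer_, n, m_cat, dimnames = list(NULL, schema$cat))
  for (a in schema$num) {
    if (!a %in% names(df)) stop("missing QID column: ", a)
    iv <- parse_interval(as.character(df[[a]]))
    num_lo[, a] <- iv$lo; num_hi[, a] <- iv$hi
  }
  for (a in schema$cat) {
    if (!a %in% names(df)) stop("missing QID column: ", a)
    cat[, a] <- tax_id(schema$attrs[[a]]$taxonomy, as.character(df[[a]]))
  }
  list(num_lo = num_lo, num_hi = num_hi, cat = cat, n = n)
}

qmat_to_df_cols <- function(qm, schema) {
  out <- list()
  for (a in schema$num)
    out[[a]] <- format_interval(qm$num_lo[, a], qm$num_hi[, a])
  for (a in schema$cat)
    out[[a]] <- schema$attrs[[a]]$taxonomy$labels[qm$cat[, a]]
  as.data.frame(out[qid_cols(schema)], optional = TRUE)
}

qmat_slice <- function(qm, i) {
  list(num_lo = qm$num_lo[i, , drop = FALSE],
       num_hi = qm$num_hi[i, , drop = FALSE],
       cat = qm$cat[i, , drop = FALSE], n = length(i))
}

# serialize closed intervals as "lo-hi" (a bare number when lo == hi);
# values must be non-negative so "-" is unambiguous
parse_interval <- function(x) {
  x <- trimws(x)
  has_dash <- grepl("-", x, fixed = TRUE)
  lo <- hi <- suppressWarnings(as.numeric(x))
  if (any(has_dash)) {
    parts <- strsplit(x[has_dash], "-", fixed = TRUE)
    bad <- vapply(parts, length, 0L) != 2L
    if (any(bad)) stop("malformed interval: ", x[has_dash][bad][1])
    lo[has_dash] <- as.numeric(vapply(parts, `[`, "", 1L))
    hi[has_dash] <- as.numeric(vapply(parts, `[`, "", 2L))
  }
  if (anyNA(lo) || anyNA(hi)) stop("non-numeric value in numeric QID column")
  if (any(lo > hi)) stop("interval with lo > hi")
  if (any(lo < 0)) stop("numeric QID values must be non-negative")
  list(lo = lo, hi = hi)
}

format_interval <- function(lo, hi) {
  ifelse(lo == hi, num_chr(lo), paste0(num_chr(lo), "-", num_chr(hi)))
}

num_chr <- function(x) {
  # compact, locale-independent numeric formatting for round-tripping
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 12)
  dot <- grepl(".", s, fixed = TRUE)
  s[dot] <- sub("\\.?0+$", "", s[dot])
  s
}
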