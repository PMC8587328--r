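#' Construct a (possibly generalized) QID value
#'
#' A QID value assigns, per schema attribute, either a closed numeric
#' interval `[lo, hi]` (a single number means the degenerate leaf interval)
#' or a taxonomy node label.  Raw records carry leaf values; anonymization
#' replaces them by more general ones.
#'
#' @param schema an [srs_schema].
#' @param ... one value per schema attribute, by name: numeric attributes
#'   take a number or a length-2 `c(lo, hi)`; categorical attributes take a
#'   node label of the attribute's taxonomy.
#' @return An object of class `qid_value` (a named list).
#' @examples
#' sch <- srs_schema(attr_categorical("Sex", sex_taxonomy()),
#'                   attr_numeric("Age", 0, 100))
#' qid_value(sch, Sex = "Female", Age = 32)
#' qid_value(sch, Sex = "ANY", Age = c(30, 40))
#' @export
qid_value <- function(schema, ...) {
  schema_check(schema)
  vals <- list(...)
  need <- qid_cols(schema)
  if (!setequal(names(vals), need))
    stop("QID value must name exactly the schema attributes: ",
         paste(need, collapse = ", "))
  out <- list()
  for (a in schema$num) {
    v <- vals[[a]]
    if (!is.numeric(v) || !length(v) %in% 1:2 || anyNA(v))
      stop("attribute '", a, "' needs a number or c(lo, hi)")
    if (length(v) == 1L) v <- c(v, v)
    if (v[1] > v[2]) stop("attribute '", a, "': lo > hi")
    out[[a]] <- unname(v)
  }
  for (a in schema$cat) {
    v <- vals[[a]]
    tax_id(schema$attrs[[a]]$taxonomy, as.character(v))  # validates
    out[[a]] <- as.character(v)
  }
  structure(out[need], class = "qid_value")
}

#' @export
print.qid_value <- function(x, ...) {
  parts <- vapply(names(x), function(a) {
    v <- x[[a]]
    if (is.numeric(v)) paste0(a, "=", format_interval(v[1], v[2]))
    else paste0(a, "=", v)
  }, "")
  cat("<", paste(parts, collapse = ", "), ">\n", sep = "")
  invisible(x)
}

qid_to_qmat <- function(q, schema) {
  df <- list()
  for (a in schema$num) df[[a]] <- format_interval(q[[a]][1], q[[a]][2])
  for (a in schema$cat) df[[a]] <- q[[a]]
  df_to_qmat(as.data.frame(df, optional = TRUE), schema)
}

as_qmat <- function(x, schema) {
  if (inherits(x, "qid_value")) return(qid_to_qmat(x, schema))
  if (is.data.frame(x)) return(df_to_qmat(x, schema))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "qid_value"))) {
    qms <- lapply(x, qid_to_qmat, schema = schema)
    return(list(
      num_lo = do.call(rbind, lapply(qms, `[[`, "num_lo")),
      num_hi = do.call(rbind, lapply(qms, `[[`, "num_hi")),
      cat = do.call(rbind, lapply(qms, `[[`, "cat")),
      n = length(qms)))
  }
  stop("expected a qid_value, a list of qid_value, or a data frame")
}

#' QID-cover relation
#'
#' `covers(q1, q2)` is `TRUE` when `q1` is equal to or more generalized than
#' `q2` on every attribute: numeric intervals of `q1` contain those of `q2`,
#' and each categorical node of `q1` is the node of `q2` or an ancestor of
#' it.  This is the partial order under which published generalized values
#' shield raw leaf values.
#'
#' @param q1,q2 [qid_value] objects on the same schema.
#' @param schema an [srs_schema].
#' @return Logical scalar.
#' @examples
#' sch <- srs_schema(attr_categorical("Sex", sex_taxonomy()),
#'                   attr_numeric("Age", 0, 100))
#' covers(qid_value(sch, Sex = "ANY", Age = c(30, 40)),
#'        qid_value(sch, Sex = "Female", Age = 32), sch)   # TRUE
#' covers(qid_value(sch, Sex = "Male", Age = c(35, 40)),
#'        qid_value(sch, Sex = "Female", Age = 32), sch)   # FALSE
#' @export
covers <- function(q1, q2, schema) {
  schema_check(schema)
  a <- as_qmat(q1, schema); b <- as_qmat(q2, schema)
  if (a$n != 1L || b$n != 1L) stop("covers() compares two single QID values")
  qmat_covers(a, 1L, b, 1L, schema)
}

# does row i of qmat a cover row j of qmat b?
qmat_covers <- function(a, i, b, j, schema) {
  for (k in seq_along(schema$num))
    if (a$num_lo[i, k] > b$num_lo[j, k] || a$num_hi[i, k] < b$num_hi[j, k])
      return(FALSE)
  for (k in seq_along(schema$cat)) {
    tx <- schema$attrs[[schema$cat[k]]]$taxonomy
    if (!tax_is_ancestor(tx, a$cat[i, k], b$cat[j, k])) return(FALSE)
  }
  TRUE
}

# vectorized: do rows `rows` of qmat a cover the single row j of qmat b?
# (a covers b on a categorical attribute when a's node is b's node or an
# ancestor of it)
qmat_covers_vec <- function(a, rows, b, j, schema) {
  ok <- rep(TRUE, length(rows))
  for (k in seq_along(schema$num))
    ok <- ok & a$num_lo[rows, k] <= b$num_lo[j, k] &
               a$num_hi[rows, k] >= b$num_hi[j, k]
  for (k in seq_along(schema$cat)) {
    tx <- schema$attrs[[schema$cat[k]]]$taxonomy
    avec <- a$cat[rows, k]
    bnode <- b$cat[j, k]
    da <- tx$depth[avec]
    ok <- ok & da <= tx$depth[bnode] & tx$anc[bnode, ][da + 1L] == avec
  }
  ok
}

#' Least common generalization of QID values
#'
#' Returns the least QID value covering every input: numeric attributes take
#' the interval hull `[min lo, max hi]`, categorical attributes take the
#' lowest common ancestor in the taxonomy.
#'
#' @param values a nonempty list of [qid_value] objects, or a data frame of
#'   QID columns.
#' @param schema an [srs_schema].
#' @return A [qid_value].
#' @examples
#' sch <- srs_schema(attr_categorical("Sex", sex_taxonomy()),
#'                   attr_numeric("Age", 0, 100))
#' qid_lub(list(qid_value(sch, Sex = "Male", Age = c(30, 35)),
#'              qid_value(sch, Sex = "Female", Age = c(35, 40))), sch)
#' # <Sex=ANY, Age=30-40>
#' @export
qid_lub <- function(values, schema) {
  schema_check(schema)
  qm <- as_qmat(values, schema)
  if (qm$n < 1L) stop("qid_lub() needs at least one value")
  out <- list()
  for (a in schema$num)
    out[[a]] <- c(min(qm$num_lo[, a]), max(qm$num_hi[, a]))
  for (k in seq_along(schema$cat)) {
    a <- schema$cat[k]
    tx <- schema$attrs[[a]]$taxonomy
    node <- qm$cat[1L, k]
    if (qm$n > 1L) for (i in 2:qm$n) node <- tax_lca(tx, node, qm$cat[i, k])
    out[[a]] <- tx$labels[node]
  }
  structure(out[qid_cols(schema)], class = "qid_value")
}

#' Information loss of a QID group
#'
#' The clustering information loss of a group `g` of records is
#' \deqn{IL(g) = |g| \times \Big[\sum_i \frac{\max(N_i,g)-\min(N_i,g)}
#'   {\max(N_i)-\min(N_i)} + \sum_j \frac{h(C_j,g)}{h(C_j)}\Big]}
#' summing over numeric attributes \eqn{N_i} (group range over global range)
#' and categorical attributes \eqn{C_j} (height of the group's generalized
#' taxonomy node over the tree height, heights measured from the leaf
#' level).  A group of identical leaf records loses nothing; a group
#' generalized to the root on every attribute loses `|g| * |QID|`.
#'
#' @param g group members: a data frame of QID columns or a list of
#'   [qid_value] objects.
#' @param schema an [srs_schema].
#' @return Nonnegative number in `[0, |g| * |QID|]`.
#' @export
group_il <- function(g, schema) {
  schema_check(schema)
  qm <- as_qmat(g, schema)
  if (qm$n < 1L) stop("group_il() needs at least one record")
  qm$n * il_per_record(qm, schema)
}

# per-record IL of the group spanned by all rows of qm
il_per_record <- function(qm, schema) {
  tot <- 0
  for (a in schema$num) {
    at <- schema$attrs[[a]]
    tot <- tot + (max(qm$num_hi[, a]) - min(qm$num_lo[, a])) / (at$max - at$min)
  }
  for (k in seq_along(schema$cat)) {
    tx <- schema$attrs[[schema$cat[k]]]$taxonomy
    node <- qm$cat[1L, k]
    if (qm$n > 1L) for (i in 2:qm$n) node <- tax_lca(tx, node, qm$cat[i, k])
    tot <- tot + tx$node_height[node] / tx$height
  }
  unname(tot)
}

#' Information-loss increase of adding a record to a group
#'
#' `delta_il(g, r)` is the information loss attributable to widening the
#' group's generalization to absorb record `r`: the grown group's size times
#' the increase in per-record loss.  It is always nonnegative and is zero
#' exactly when the group's generalized value already covers `r` — the
#' property that makes zero-cost placements of pre-generalized old cases
#' visible to the greedy, and the reason mixing old cases into group
#' formation blunts the criterion's discrimination.
#'
#' @param g group members (as in [group_il()]).
#' @param r a single [qid_value] (or one-row data frame) to add.
#' @param schema an [srs_schema].
#' @return Nonnegative number.
#' @export
delta_il <- function(g, r, schema) {
  schema_check(schema)
  qm_g <- as_qmat(g, schema)
  qm_r <- as_qmat(r, schema)
  if (qm_r$n != 1L) stop("'r' must be a single record")
  both <- list(num_lo = rbind(qm_g$num_lo, qm_r$num_lo),
               num_hi = rbind(qm_g$num_hi, qm_r$num_hi),
               cat = rbind(qm_g$cat, qm_r$cat), n = qm_g$n + 1L)
  both$n * (il_per_record(both, schema) - il_per_record(qm_g, schema))
}
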