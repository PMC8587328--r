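# Anonymization-quality metrics evaluated on published releases.

#' Normalized information loss of a release
#'
#' \eqn{NIL(R) = \sum_g IL(g) / (|QID| \times |R|)}: the total group
#' information loss averaged over each attribute of each record, ranging in
#' `[0, 1]` (0 = all records published at leaf level, 1 = everything
#' generalized to the root).  Groups are recovered as maximal sets of
#' records sharing an identical generalized QID value — all a release
#' exposes.
#'
#' @param release published data frame.
#' @param schema an [srs_schema].
#' @return Number in `[0, 1]`.
#' @export
metric_nil <- function(release, schema) {
  schema_check(schema)
  if (is.null(release) || nrow(release) == 0L)
    stop("NIL is undefined for an empty release")
  grp <- release_groups(release, schema)
  qm <- df_to_qmat(release, schema)
  total <- 0
  for (g in unique(grp)) {
    rows <- which(grp == g)
    total <- total + length(rows) * il_row_per(qm, rows[1], schema)
  }
  total / (length(qid_cols(schema)) * nrow(release))
}

# per-record IL of a published group: all members share the group value, so
# one row suffices
il_row_per <- function(qm, i, schema) {
  per <- 0
  for (j in seq_along(schema$num)) {
    a <- schema$attrs[[schema$num[j]]]
    per <- per + (qm$num_hi[i, j] - qm$num_lo[i, j]) / (a$max - a$min)
  }
  for (j in seq_along(schema$cat)) {
    tx <- schema$attrs[[schema$cat[j]]]$taxonomy
    per <- per + tx$node_height[qm$cat[i, j]] / tx$height
  }
  unname(per)
}

#' Dangerous identity ratio of a release after BFL audit
#'
#' \eqn{DIR(R) = DIGNum(R) / GroupNum(R)}: the fraction of QID groups
#' containing at least one audited target whose candidate set, after
#' removing everything the B-, F- and L-attacks exclude, holds fewer than
#' `k` cases.
#'
#' @param findings rows of [audit_series()] output for **one** release.
#' @param k the anonymity parameter.
#' @return Number in `[0, 1]`.
#' @export
metric_dir <- function(findings, k) {
  if (!nrow(findings)) stop("no audit findings supplied")
  if (length(unique(findings$release)) != 1L)
    stop("supply findings of a single release")
  danger <- tapply(findings$eff_size < k, findings$group, any)
  sum(danger) / length(danger)
}

#' Dangerous sensitivity ratio of a release after BFL audit
#'
#' \eqn{DSR(R) = DSGNum(R) / GroupNum(R)}: the fraction of QID groups in
#' which some target's post-exclusion confidence for some sensitive term
#' exceeds that term's threshold.
#'
#' @param findings rows of [audit_series()] output for one release (the
#'   `sens_danger` flag already encodes the threshold comparison).
#' @return Number in `[0, 1]`.
#' @export
metric_dsr <- function(findings) {
  if (!nrow(findings)) stop("no audit findings supplied")
  if (length(unique(findings$release)) != 1L)
    stop("supply findings of a single release")
  danger <- tapply(findings$sens_danger, findings$group, any)
  sum(danger) / length(danger)
}

#' Per-release quality report for an anonymized series
#'
#' Audits the series and tabulates NIL, DIR and DSR for every release.
#'
#' @param series a `release_series` with raw leaf quarters.
#' @param params a [privacy_params].
#' @param findings optional precomputed [audit_series()] output.
#' @return Data frame with one row per release: `release`, `n_records`,
#'   `group_num`, `dig_num`, `dsg_num`, `nil`, `dir`, `dsr`.
#' @export
metrics_report <- function(series, params, findings = NULL) {
  if (is.null(findings)) findings <- audit_series(series, params)
  out <- lapply(sort(unique(findings$release)), function(i) {
    fi <- findings[findings$release == i, , drop = FALSE]
    dig <- tapply(fi$eff_size < params$k, fi$group, any)
    dsg <- tapply(fi$sens_danger, fi$group, any)
    data.frame(release = i,
               n_records = nrow(series$released[[i]]),
               group_num = length(dig),
               dig_num = sum(dig), dsg_num = sum(dsg),
               nil = metric_nil(series$released[[i]], series$schema),
               dir = sum(dig) / length(dig),
               dsr = sum(dsg) / length(dsg))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a metrics report
#'
#' Serializes a [metrics_report()] both as tab-separated text and, with a
#' `.json` path, as a machine-readable key-value file.
#'
#' @param report data frame from [metrics_report()].
#' @param path output path; the extension decides the format.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
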