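# Adverse-drug-reaction signal utility: does anonymization preserve the
# disproportionality signals a pharmacovigilance analyst would compute?

#' Define a demographic-conditioned ADR rule
#'
#' A rule pairs a drug with a suspected reaction inside a demographic
#' subpopulation, e.g. "Avandia, Age > 18 -> Myocardial infarction".
#'
#' @param drug drug name.
#' @param reaction reaction (sensitive) term.
#' @param attribute the single QID attribute the condition constrains.
#' @param op comparison operator: one of `">"`, `">="`, `"<"`, `"<="`,
#'   `"=="`.
#' @param value numeric threshold (numeric attribute) or category label.
#' @return An object of class `adr_rule`.
#' @export
adr_rule <- function(drug, reaction, attribute, op, value) {
  op <- match.arg(op, c(">", ">=", "<", "<=", "=="))
  structure(list(drug = drug, reaction = reaction, attribute = attribute,
                 op = op, value = value),
            class = "adr_rule")
}

#' @export
print.adr_rule <- function(x, ...) {
  cat(x$drug, ", ", x$attribute, " ", x$op, " ", x$value, " -> ",
      x$reaction, "\n", sep = "")
  invisible(x)
}

#' Does a (generalized) QID value entail a rule condition?
#'
#' Entailment, not overlap: the condition must hold for *every* leaf value
#' consistent with the published generalization.  A report whose age was
#' published as `[15-25]` does not entail `Age > 18`; a report whose sex was
#' generalized to `ANY` does not entail `Sex == Female` and so drops out of
#' the rule's counts — the mechanism by which generalization erodes signal
#' counts.
#'
#' @param qid a [qid_value] (or one-row data frame of QID columns).
#' @param rule an [adr_rule] (only its condition is used).
#' @param schema an [srs_schema].
#' @return Logical scalar.
#' @export
condition_entails <- function(qid, rule, schema) {
  qm <- as_qmat(qid, schema)
  if (qm$n != 1L) stop("supply a single QID value")
  entails_rows(qm, rule, schema)[1]
}

# vectorized entailment over all rows of a qmat
entails_rows <- function(qm, rule, schema) {
  a <- rule$attribute
  if (a %in% schema$num) {
    lo <- qm$num_lo[, a]; hi <- qm$num_hi[, a]
    v <- as.numeric(rule$value)
    switch(rule$op,
           ">"  = lo > v,
           ">=" = lo >= v,
           "<"  = hi < v,
           "<=" = hi <= v,
           "==" = lo == v & hi == v)
  } else if (a %in% schema$cat) {
    if (rule$op != "==")
      stop("categorical conditions support '==' only")
    tx <- schema$attrs[[a]]$taxonomy
    # every leaf below the published node must equal the condition value
    ok_nodes <- which(vapply(tx$leaves_under, function(lv)
      length(lv) > 0 && all(lv == rule$value), TRUE))
    qm$cat[, a] %in% ok_nodes
  } else stop("condition attribute not in schema: ", a)
}

#' Proportional reporting ratio
#'
#' \eqn{PRR = \frac{a/(a+b)}{c/(c+d)}} on the 2x2 drug-by-reaction table of
#' the condition-satisfying subpopulation.  Following the usual signal
#' criterion for newly marketed drugs (a signal needs `a >= 3` and
#' `PRR > 2`), the PRR is forced to 0 when `a < 3`, so that losing even one
#' report of a rare rule visibly invalidates it.
#'
#' @param a reports with the drug and the reaction.
#' @param b reports with the drug, without the reaction.
#' @param c reports with the reaction, without the drug.
#' @param d reports with neither.
#' @return Nonnegative number (`Inf` when `a >= 3` and no comparator report
#'   has the reaction).
#' @examples
#' prr(4, 6, 16, 74)  # 2.25
#' @export
prr <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0) stop("cell counts must be nonnegative")
  if (a < 3) return(0)
  if (a + b == 0 || c + d == 0)
    stop("PRR undefined: empty margin in the 2x2 table")
  if (c == 0) return(Inf)
  (a / (a + b)) / (c / (c + d))
}

#' Evaluate an ADR rule on a quarterly table
#'
#' Restricts to reports whose (possibly generalized) QID entails the rule's
#' demographic condition, collapses same-CaseID rows to one case (drug and
#' reaction sets united, QID values merged), cross-tabulates drug presence
#' against reaction presence, and computes the PRR.  Drug and reaction
#' matching is by case-insensitive exact name.
#'
#' @param dataset data frame with `case_id`, QID columns, `drugs` and
#'   `sensitive` (semicolon-joined).
#' @param rule an [adr_rule].
#' @param schema an [srs_schema].
#' @return List of class `signal_result`: cells `a`, `b`, `c`, `d`, `n`
#'   (condition-entailing subpopulation size), `prr`, `valid`
#'   (`a >= 3 & prr > 2`).
#' @export
evaluate_rule <- function(dataset, rule, schema) {
  schema_check(schema)
  cases <- combine_super_records(dataset, schema)
  qm <- df_to_qmat(cases, schema)
  sub <- which(entails_rows(qm, rule, schema))
  if (!length(sub))
    stop("no report entails the rule condition")
  has_drug <- vapply(split_terms(cases$drugs[sub]), function(x)
    any(tolower(x) == tolower(rule$drug)), TRUE)
  has_reac <- vapply(split_terms(cases$sensitive[sub]), function(x)
    any(tolower(x) == tolower(rule$reaction)), TRUE)
  a <- sum(has_drug & has_reac); b <- sum(has_drug & !has_reac)
  cc <- sum(!has_drug & has_reac); d <- sum(!has_drug & !has_reac)
  p <- prr(a, b, cc, d)
  structure(list(a = a, b = b, c = cc, d = d, n = length(sub),
                 prr = p, valid = a >= 3 && p > 2),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("2x2: a=%d b=%d c=%d d=%d (n=%d)  PRR=%.3f  %s\n",
              x$a, x$b, x$c, x$d, x$n, x$prr,
              if (x$valid) "signal" else "no signal"))
  invisible(x)
}

#' Signal bias introduced by anonymization
#'
#' Evaluates a rule on the raw and the anonymized version of the same
#' quarter and reports the differences (anonymized minus raw) in the `a`
#' count and in the PRR.  Generalization can only shrink `a` (entailment is
#' monotone), and a rare rule whose raw `a` is exactly 3 is invalidated by a
#' single missing count, dropping its PRR to 0.
#'
#' @param raw,anonymized data frames for the same quarter.
#' @param rule an [adr_rule].
#' @param schema an [srs_schema].
#' @return List with `raw`, `anonymized` (both `signal_result`),
#'   `count_delta` and `prr_delta`.
#' @export
signal_bias <- function(raw, anonymized, rule, schema) {
  r0 <- evaluate_rule(raw, rule, schema)
  r1 <- evaluate_rule(anonymized, rule, schema)
  list(raw = r0, anonymized = r1,
       count_delta = r1$a - r0$a,
       prr_delta = r1$prr - r0$prr)
}

#' Read / write ADR rule files
#'
#' Rules are stored as tab-separated text with columns `drug`, `reaction`,
#' `attribute`, `op`, `value`.
#'
#' @param path file path.
#' @param rules a list of [adr_rule] objects.
#' @return `read_rules()` returns a list of [adr_rule].
#' @export
read_rules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  lapply(seq_len(nrow(df)), function(i)
    adr_rule(df$drug[i], df$reaction[i], df$attribute[i], df$op[i],
             df$value[i]))
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  df <- do.call(rbind, lapply(rules, function(r)
    data.frame(drug = r$drug, reaction = r$reaction, attribute = r$attribute,
               op = r$op, value = as.character(r$value))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
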