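#' Built-in three-quarter demonstration series
#'
#' A miniature SRS publishing scenario of three consecutive quarters over
#' QID attributes Sex and Age and a single-term sensitive attribute
#' (Disease), used throughout the documentation and tests to demonstrate
#' cross-release linkage.
#'
#' `example_series_vulnerable()` returns a series in which every quarter is
#' 3-anonymous on its own, yet follow-up CaseIDs let an adversary break it:
#' a target with leaf QID \{Female, 32\} in quarter 2 sits in the group with
#' CaseIDs \{1, 4, 7\}; linking CaseID 1 to quarter 1 (where it is published
#' as Male) excludes it (B-attack), linking CaseID 7 to quarter 3 (Male)
#' excludes it too (F-attack), leaving the single candidate 4 with certainty
#' of its HIV diagnosis.  A target \{Male, 33\} first reported in quarter 3
#' is exposed by the L-attack: candidates 7 and 8 already appear in quarter
#' 2, leaving candidate 18.
#'
#' `example_series_protected()` returns the same raw quarters anonymized
#' with new-case bounding and QID-covering (k = 3): every target retains at
#' least 3 candidates under the full BFL audit.
#'
#' The published values are fixed; the accompanying raw leaf QIDs are
#' synthetic (chosen inside each published generalization, with the two
#' named targets at Female/32 and Male/33) so that the series can be
#' audited.
#'
#' @return A `release_series` object: a list with `schema`, `raw` (leaf-level
#'   quarters `D_i`), `released` (published quarters `R_i`) and `suppressed`.
#' @examples
#' ser <- example_series_vulnerable()
#' ser$released[[2]]
#' @export
example_series_vulnerable <- function() {
  sch <- example_schema()
  leaf <- example_leaf_table()
  rel <- list(
    ex_quarter(1, c(1, 2, 3),     "Male",   35, 40,
               c("Flu", "Flu", "Fever")),
    ex_quarter(1, c(4, 5, 6),     "Female", 30, 35,
               c("HIV", "Flu", "Diabetes")),
    ex_quarter(2, c(1, 4, 7),     "ANY",    30, 40,
               c("Flu", "HIV", "Diabetes")),
    ex_quarter(2, c(8, 9, 10, 11, 12), "Male", 30, 35,
               c("Fever", "Flu", "Diabetes", "HIV", "Flu")),
    ex_quarter(3, c(13, 14, 15, 16, 17), "Female", 30, 35,
               c("Flu", "Diabetes", "Fever", "Flu", "Fever")),
    ex_quarter(3, c(7, 8, 18),    "Male",   30, 35,
               c("Diabetes", "Fever", "HIV")))
  released <- lapply(1:3, function(q)
    do.call(rbind, rel[vapply(rel, function(x) x$quarter[1], 0) == q]))
  new_release_series(sch, raw = split(leaf, leaf$quarter),
                     released = released)
}

#' @rdname example_series_vulnerable
#' @export
example_series_protected <- function() {
  sch <- example_schema()
  leaf <- example_leaf_table()
  rel <- list(
    ex_quarter(1, c(1, 2, 3),     "Male",   35, 40,
               c("Flu", "Flu", "Fever")),
    ex_quarter(1, c(4, 5, 6),     "Female", 30, 35,
               c("HIV", "Flu", "Diabetes")),
    ex_quarter(2, c(1, 4, 7, 8, 9), "ANY",  30, 40,
               c("Flu", "HIV", "Diabetes", "Fever", "Flu")),
    ex_quarter(2, c(10, 11, 12),  "Male",   30, 35,
               c("Diabetes", "HIV", "Flu")),
    ex_quarter(3, c(13, 14, 15),  "Female", 30, 35,
               c("Flu", "Diabetes", "Fever")),
    ex_quarter(3, c(16, 17, 7, 8, 18), "ANY", 30, 40,
               c("Flu", "Fever", "Diabetes", "Fever", "HIV")))
  released <- lapply(1:3, function(q)
    do.call(rbind, rel[vapply(rel, function(x) x$quarter[1], 0) == q]))
  new_release_series(sch, raw = split(leaf, leaf$quarter),
                     released = released)
}

#' @rdname example_series_vulnerable
#' @export
example_schema <- function() {
  srs_schema(attr_categorical("Sex", sex_taxonomy()),
             attr_numeric("Age", 0, 100))
}

# raw leaf quarters consistent with both example series; ages are synthetic
# but lie inside every generalization the series publish for that case
example_leaf_table <- function() {
  sex <- c(`1` = "Male", `2` = "Male", `3` = "Male", `4` = "Female",
           `5` = "Female", `6` = "Female", `7` = "Male", `8` = "Male",
           `9` = "Male", `10` = "Male", `11` = "Male", `12` = "Male",
           `13` = "Female", `14` = "Female", `15` = "Female",
           `16` = "Female", `17` = "Female", `18` = "Male")
  age <- c(`1` = 36, `2` = 37, `3` = 38, `4` = 32, `5` = 31, `6` = 33,
           `7` = 31, `8` = 34, `9` = 33, `10` = 32, `11` = 30, `12` = 35,
           `13` = 30, `14` = 31, `15` = 32, `16` = 33, `17` = 34, `18` = 33)
  dis <- list(
    q1 = c(`1` = "Flu", `2` = "Flu", `3` = "Fever", `4` = "HIV",
           `5` = "Flu", `6` = "Diabetes"),
    q2 = c(`1` = "Flu", `4` = "HIV", `7` = "Diabetes", `8` = "Fever",
           `9` = "Flu", `10` = "Diabetes", `11` = "HIV", `12` = "Flu"),
    q3 = c(`13` = "Flu", `14` = "Diabetes", `15` = "Fever", `16` = "Flu",
           `17` = "Fever", `7` = "Diabetes", `8` = "Fever", `18` = "HIV"))
  rows <- do.call(rbind, lapply(1:3, function(q) {
    ids <- as.integer(names(dis[[q]]))
    data.frame(case_id = ids, quarter = q,
               Sex = unname(sex[as.character(ids)]),
               Age = unname(age[as.character(ids)]),
               drugs = "", sensitive = unname(dis[[q]]),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

ex_quarter <- function(quarter, ids, sex, lo, hi, disease) {
  data.frame(case_id = as.integer(ids), quarter = as.integer(quarter),
             Sex = sex, Age = format_interval(rep(lo, length(ids)),
                                              rep(hi, length(ids))),
             drugs = "", sensitive = disease, stringsAsFactors = FALSE)
}

new_release_series <- function(schema, raw, released, suppressed = NULL,
                               variant = NA_character_) {
  raw <- unname(raw); released <- unname(released)
  if (is.null(suppressed))
    suppressed <- lapply(seq_along(released), function(i)
      data.frame(case_id = integer(0), quarter = integer(0),
                 reason = character(0)))
  structure(list(schema = schema, raw = raw, released = released,
                 suppressed = suppressed, variant = variant,
                 n_releases = length(released)),
            class = "release_series")
}

#' @export
print.release_series <- function(x, ...) {
  cat("SRS release series: ", x$n_releases, " quarters",
      if (!is.na(x$variant)) paste0(" (", x$variant, ")"), "\n", sep = "")
  for (i in seq_len(x$n_releases))
    cat(sprintf("  R%d: %d records published, %d suppressed\n", i,
                nrow(x$released[[i]]), nrow(x$suppressed[[i]])))
  invisible(x)
}
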