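#' Per-term confidence thresholds
#'
#' A threshold map assigns each sensitive term \eqn{s_j} a probability bound
#' \eqn{\theta_j \in [0,1]}: after anonymization (and after any cross-release
#' exclusions) an adversary's confidence that a target has \eqn{s_j} must not
#' exceed \eqn{\theta_j}.  Terms absent from the map fall back on `default`.
#'
#' @param theta named numeric vector of per-term thresholds in `[0, 1]`.
#' @param default threshold for terms not named in `theta`.
#' @return An object of class `threshold_map`.
#' @seealso [set_thresholds()] for the uniform / frequency-based / level-wise
#'   setting schemes.
#' @export
threshold_map <- function(theta = numeric(0), default = 1) {
  theta <- unlist(theta)
  if (length(theta) && (is.null(names(theta)) || any(names(theta) == "")))
    stop("'theta' must be a named vector term -> threshold")
  if (any(theta < 0 | theta > 1) || default < 0 || default > 1)
    stop("thresholds must lie in [0, 1]")
  structure(list(theta = theta, default = default), class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat("Threshold map: ", length(x$theta), " term-specific thresholds, ",
      "default ", x$default, "\n", sep = "")
  invisible(x)
}

theta_of <- function(tm, terms) {
  stopifnot(inherits(tm, "threshold_map"))
  out <- rep(tm$default, length(terms))
  hit <- match(terms, names(tm$theta))
  out[!is.na(hit)] <- tm$theta[hit[!is.na(hit)]]
  out
}

#' Privacy parameters for PPMS(k, theta*)-bounding
#'
#' @param k minimum number of new-CaseID records per QID group (`k >= 2`).
#' @param thresholds a [threshold_map].
#' @param lifespan_x follow-up life span in quarters: a CaseID reappearing
#'   more than `lifespan_x` releases after its last publication is treated as
#'   new by the anonymizer.
#' @param seed integer seed driving every random choice of the anonymizer.
#' @return An object of class `privacy_params`.
#' @export
privacy_params <- function(k, thresholds = threshold_map(),
                           lifespan_x = 8L, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (lifespan_x < 1) stop("lifespan_x must be at least 1")
  stopifnot(inherits(thresholds, "threshold_map"))
  structure(list(k = as.integer(k), thresholds = thresholds,
                 lifespan_x = as.integer(lifespan_x),
                 seed = as.integer(seed)),
            class = "privacy_params")
}

#' Build a QID group from records
#'
#' Groups are evaluated at the case level: all records sharing a CaseID count
#' as one case, and a case "contains" a sensitive term when any of its
#' records does.
#'
#' @param records data frame with at least `case_id` and `sensitive`
#'   (semicolon-joined term list) columns; QID columns may be present and are
#'   kept for information-loss computations.
#' @param new_case_ids CaseIDs considered new in this release; defaults to
#'   all of them (a first release).
#' @return An object of class `qid_group` with components `records`,
#'   `case_ids`, `size` (number of cases), `nc_count` (number of new cases),
#'   and `sigma` (named per-term case counts).
#' @export
qid_group <- function(records, new_case_ids = NULL) {
  if (!all(c("case_id", "sensitive") %in% names(records)))
    stop("records need 'case_id' and 'sensitive' columns")
  if (nrow(records) == 0L) stop("a QID group cannot be empty")
  case_ids <- unique(records$case_id)
  if (is.null(new_case_ids)) new_case_ids <- case_ids
  terms_by_case <- lapply(split(records$sensitive, factor(records$case_id,
                                                          levels = case_ids)),
                          function(x) unique(unlist(split_terms(x))))
  sigma <- table(unlist(terms_by_case))
  sigma <- stats::setNames(as.integer(sigma), names(sigma))
  structure(list(records = records, case_ids = case_ids,
                 size = length(case_ids),
                 new = case_ids %in% new_case_ids,
                 nc_count = sum(case_ids %in% new_case_ids),
                 terms_by_case = terms_by_case, sigma = sigma),
            class = "qid_group")
}

split_terms <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

join_terms <- function(lst) vapply(lst, paste, "", collapse = ";")

#' Confidence of inferring a sensitive term within a group
#'
#' `conf(v -> s) = sigma_s(g) / |g|`: the fraction of cases in the target's
#' QID group that contain term `s`.
#'
#' @param g a [qid_group].
#' @param s a sensitive term.
#' @return Number in `[0, 1]`.
#' @export
confidence <- function(g, s) {
  stopifnot(inherits(g, "qid_group"))
  sig <- g$sigma[s]
  if (is.na(sig)) sig <- 0L
  unname(sig) / g$size
}

#' Maximum admissible occurrence of a sensitive term in a group
#'
#' In the worst case an adversary excludes every old case from a QID group,
#' shrinking it to its new cases.  Keeping the confidence for term `s` below
#' `theta_s` even then requires
#' \eqn{\sigma_s(g) \le \eta_s(g) = \lfloor \theta_s |NC(g)| \rfloor},
#' where `|NC(g)|` is the number of new CaseIDs in the group.
#'
#' @param theta_s threshold for the term, in `[0, 1]`.
#' @param nc_count number of new CaseIDs in the group.
#' @return Integer bound `eta_s(g)`.
#' @examples
#' eta_bound(0.2, 18462)  # 3692: a count of 3877 would be infeasible
#' @export
eta_bound <- function(theta_s, nc_count) {
  if (any(theta_s < 0 | theta_s > 1)) stop("theta_s must lie in [0, 1]")
  if (any(nc_count < 0)) stop("nc_count must be nonnegative")
  as.integer(floor(theta_s * nc_count + 1e-9))
}

#' Privacy risk of adding a record to a group
#'
#' \deqn{PR(g, r) = 1 + \sum_{s \in S_r} \frac{\sigma_s(g \cup r)}
#'   {\eta_s(g \cup r) - \sigma_s(g \cup r) + 1}}
#' summing over the sensitive terms of `r`.  The ratio grows as a term
#' approaches its admissible bound, steering the greedy grouping towards
#' records whose terms are still rare in `g`; it becomes `+Inf` as soon as
#' any term would exceed its bound, so such a record is never chosen.  The
#' leading 1 keeps the risk positive even when every term of `r` is new to
#' the group.
#'
#' @param g a [qid_group].
#' @param r_terms sensitive terms of the candidate record (character vector).
#' @param thresholds a [threshold_map].
#' @param r_new is the candidate a new case?  (Old cases do not raise the
#'   admissible bounds.)
#' @return Number `>= 1`, possibly `Inf`.
#' @export
privacy_risk <- function(g, r_terms, thresholds, r_new = TRUE) {
  stopifnot(inherits(g, "qid_group"))
  r_terms <- unique(as.character(r_terms))
  nc_new <- g$nc_count + as.integer(r_new)
  pr <- 1
  for (s in r_terms) {
    sig <- g$sigma[s]
    sig <- if (is.na(sig)) 1L else sig + 1L
    eta <- eta_bound(theta_of(thresholds, s), nc_new)
    if (sig > eta) return(Inf)
    pr <- pr + sig / (eta - sig + 1)
  }
  unname(pr)
}

#' Privacy-risk-weighted information-loss increase
#'
#' \eqn{\Delta IL'(g, r) = \Delta IL(g, r) \times PR(g, r)}: the greedy
#' grouping criterion.  An infeasible candidate (`PR = Inf`) yields `Inf`
#' regardless of its information loss, so it is never selected; a candidate
#' already covered by the group's generalization yields 0 whenever it is
#' feasible.
#'
#' @param g a [qid_group] whose `records` carry QID columns.
#' @param r a one-row data frame with QID columns and a `sensitive` column.
#' @param thresholds a [threshold_map].
#' @param schema an [srs_schema].
#' @param r_new is the candidate a new case?
#' @return Nonnegative number, possibly `Inf`.
#' @export
delta_il_prime <- function(g, r, thresholds, schema, r_new = TRUE) {
  pr <- privacy_risk(g, split_terms(r$sensitive)[[1]], thresholds, r_new)
  if (is.infinite(pr)) return(Inf)
  delta_il(g$records, r, schema) * pr
}

#' Set confidence thresholds for sensitive terms
#'
#' Three schemes are supported.  `uniform` gives every term the same
#' threshold.  `frequency` follows the rule "the more frequent, the less
#' sensitive": with `m` the mean and `SD` the population standard deviation
#' of the per-term occurrence counts, terms with counts below `m - SD` get
#' 0.2, within `[m - SD, m + SD]` get 0.6, and above `m + SD` get 1.0.
#' `levelwise` maps user-supplied sensitivity labels `high`/`low`/`non` to
#' 0.2 / 0.4 / 1.0.
#'
#' @param counts named integer vector of per-term occurrence counts (cases
#'   containing the term), typically per quarter.
#' @param mode one of `"uniform"`, `"frequency"`, `"levelwise"`.
#' @param theta the single threshold used by `uniform` mode.
#' @param levels named character vector term -> `"high"`/`"low"`/`"non"`
#'   for `levelwise` mode; unlabelled terms count as `"low"`.
#' @return A [threshold_map].  Unseen terms default to 0.2 under `frequency`
#'   (an unseen term is rarer than any seen one) and to the scheme's value
#'   for unlabelled terms otherwise.
#' @export
set_thresholds <- function(counts, mode = c("uniform", "frequency",
                                            "levelwise"),
                           theta = 0.2, levels = NULL) {
  mode <- match.arg(mode)
  if (mode == "uniform")
    return(threshold_map(default = theta))
  if (!length(counts) || is.null(names(counts)))
    stop("'counts' must be a nonempty named vector")
  if (mode == "frequency") {
    m <- mean(counts)
    sd_pop <- sqrt(mean((counts - m)^2))
    th <- ifelse(counts < m - sd_pop, 0.2,
                 ifelse(counts > m + sd_pop, 1.0, 0.6))
    return(threshold_map(stats::setNames(th, names(counts)), default = 0.2))
  }
  # levelwise
  if (is.null(levels)) stop("levelwise mode needs 'levels'")
  bad <- setdiff(unique(levels), c("high", "low", "non"))
  if (length(bad)) stop("unknown sensitivity level(s): ",
                        paste(bad, collapse = ", "))
  lv <- c(high = 0.2, low = 0.4, non = 1.0)
  threshold_map(stats::setNames(unname(lv[levels]), names(levels)),
                default = 0.4)
}

#' Global feasibility diagnosis for a quarter
#'
#' A term `s` makes a whole quarter infeasible when even a single all-new
#' group over the quarter could not absorb it: `sigma_s(D) / |NC(D)| >
#' theta_s`.  The report gives, per term, its share of all cases, its ratio
#' over new cases, and the feasibility verdict — the diagnosis a publisher
#' needs when a release cannot meet its privacy requirement.
#'
#' @param term_counts named vector: cases containing each term.
#' @param n_cases total number of cases in the quarter.
#' @param n_new_cases number of new cases in the quarter.
#' @param thresholds a [threshold_map].
#' @return Data frame with columns `term`, `count`, `share_pct`
#'   (percentage of all cases), `new_case_pct` (percentage of new cases),
#'   `theta`, `feasible`, sorted by decreasing count.
#' @examples
#' # a quarter of 20467 cases (18462 new) where one symptom occurs 3877 times
#' infeasibility_report(c(`Diabetes Mellitus Non-Insulin-Dependent` = 3877),
#'                      20467, 18462, threshold_map(default = 0.2))
#' @export
infeasibility_report <- function(term_counts, n_cases, n_new_cases,
                                 thresholds) {
  if (!length(term_counts) || is.null(names(term_counts)))
    stop("'term_counts' must be a nonempty named vector")
  th <- theta_of(thresholds, names(term_counts))
  out <- data.frame(
    term = names(term_counts),
    count = as.integer(term_counts),
    share_pct = 100 * term_counts / n_cases,
    new_case_pct = 100 * term_counts / n_new_cases,
    theta = th,
    feasible = term_counts <= eta_bound(th, n_new_cases),
    row.names = NULL)
  out[order(-out$count), , drop = FALSE]
}

#' Read / write a threshold map
#'
#' Two-column tab-separated text (`term<TAB>theta`), with the default
#' threshold stored under the pseudo-term `.default`.
#'
#' @param path file path.
#' @param tm a [threshold_map].
#' @export
write_thresholds <- function(tm, path) {
  stopifnot(inherits(tm, "threshold_map"))
  df <- data.frame(term = c(names(tm$theta), ".default"),
                   theta = c(unname(tm$theta), tm$default))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"),
                          quote = "", comment.char = "")
  is_def <- df$term == ".default"
  threshold_map(stats::setNames(df$theta[!is_def], df$term[!is_def]),
                default = if (any(is_def)) df$theta[is_def][1] else 1)
}
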