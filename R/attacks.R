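# BFL-attack simulation against a series of anonymized releases.
#
# The auditor plays the strongest adversary consistent with the attack
# definitions: it knows every target's true leaf QID and, for new cases, the
# release in which the case first appears.

# ---- shared internals ----------------------------------------------------

# stack all published rows of a series into one qmat + release/case vectors
pub_index <- function(series) {
  sch <- series$schema
  qms <- lapply(series$released, df_to_qmat, schema = sch)
  list(num_lo = do.call(rbind, lapply(qms, `[[`, "num_lo")),
       num_hi = do.call(rbind, lapply(qms, `[[`, "num_hi")),
       cat = do.call(rbind, lapply(qms, `[[`, "cat")),
       release = rep(seq_along(series$released),
                     vapply(series$released, nrow, 0L)),
       case_id = unlist(lapply(series$released, `[[`, "case_id"),
                        use.names = FALSE))
}

# case-level leaf QIDs for release i: one qmat row per case (interval hull /
# lub over the case's raw rows, i.e. the super-record leaf)
leaf_cases <- function(series, i) {
  sch <- series$schema
  raw <- series$raw[[i]]
  if (is.null(raw)) stop("audit needs raw leaf QIDs for release ", i)
  qm <- df_to_qmat(raw, sch)
  ids <- unique(raw$case_id)
  pos <- split(seq_len(nrow(raw)), factor(raw$case_id, levels = ids))
  num_lo <- do.call(rbind, lapply(pos, function(p)
    apply(qm$num_lo[p, , drop = FALSE], 2, min)))
  num_hi <- do.call(rbind, lapply(pos, function(p)
    apply(qm$num_hi[p, , drop = FALSE], 2, max)))
  cat <- do.call(rbind, lapply(pos, function(p) {
    vapply(seq_along(sch$cat), function(k) {
      tx <- sch$attrs[[sch$cat[k]]]$taxonomy
      node <- qm$cat[p[1], k]
      for (q in p[-1]) node <- tax_lca(tx, node, qm$cat[q, k])
      node
    }, 0L)
  }))
  if (length(sch$num) == 0L) num_lo <- num_hi <-
      matrix(0, length(ids), 0)
  if (length(sch$cat) == 0L) cat <- matrix(0L, length(ids), 0)
  list(num_lo = num_lo, num_hi = num_hi,
       cat = cat, n = length(ids), case_id = ids,
       terms = lapply(pos, function(p)
         unique(unlist(split_terms(raw$sensitive[p])))))
}

# groups of a published release: maximal sets of rows sharing an identical
# generalized QID value (all a release exposes)
release_groups <- function(df, schema) {
  key <- do.call(paste, c(df[qid_cols(schema)], sep = "\r"))
  match(key, unique(key))
}

# case ids present in releases 1..(i-1)
cases_before <- function(series, i) {
  if (i <= 1L) return(integer(0))
  unique(unlist(lapply(series$released[seq_len(i - 1L)], `[[`, "case_id"),
                use.names = FALSE))
}

# resolve a target to (leaf qmat row, CI) in release i
resolve_target <- function(series, i, case_id) {
  rel <- series$released[[i]]
  if (!case_id %in% rel$case_id)
    stop("case ", case_id, " is not published in release ", i)
  grp <- release_groups(rel, series$schema)
  g <- grp[match(case_id, rel$case_id)]
  ci <- unique(rel$case_id[grp == g])
  lf <- leaf_cases(series, i)
  v <- match(case_id, lf$case_id)
  if (is.na(v)) stop("case ", case_id, " has no raw record in quarter ", i)
  list(ci = ci, leaf = lf, v = v)
}

# excludable candidates by cover failure in releases `rel_set`
exclude_by_cover <- function(series, pub, ci, leaf, v, rel_set) {
  if (!length(rel_set)) return(integer(0))
  rows <- which(pub$release %in% rel_set & pub$case_id %in% ci)
  if (!length(rows)) return(integer(0))
  cov <- qmat_covers_vec(pub, rows, leaf, v, series$schema)
  sort(unique(pub$case_id[rows[!cov]]))
}

# ---- single-target operations -------------------------------------------

#' Simulate B-, F- and L-attacks on a single target
#'
#' Given a target case published in release `i` of an anonymized series,
#' these return the subset of its candidate CaseID set (the CaseIDs of its
#' QID group) that the attack can exclude:
#' * `b_attack()`: candidates some of whose records in an *earlier* release
#'   carry a published QID that does not cover the target's true leaf QID;
#' * `f_attack()`: the mirror image over *later* releases;
#' * `l_attack()`: when the attacker knows the target's CaseID first appears
#'   in release `i`, every candidate already published earlier.
#'
#' @param series a `release_series` (raw leaf quarters must be present; the
#'   target's leaf QID is taken from them).
#' @param i release index of the target.
#' @param case_id the target's CaseID.
#' @return Sorted integer vector of excludable CaseIDs (possibly empty).
#' @seealso [audit_series()] to run all three attacks on every target.
#' @examples
#' ser <- example_series_vulnerable()
#' b_attack(ser, 2, 4)  # CaseID 1 excluded via quarter 1
#' f_attack(ser, 2, 4)  # CaseID 7 excluded via quarter 3
#' l_attack(ser, 3, 18) # CaseIDs 7, 8 seen before quarter 3
#' @export
b_attack <- function(series, i, case_id) {
  tg <- resolve_target(series, i, case_id)
  exclude_by_cover(series, pub_index(series), tg$ci, tg$leaf, tg$v,
                   seq_len(i - 1L))
}

#' @rdname b_attack
#' @export
f_attack <- function(series, i, case_id) {
  tg <- resolve_target(series, i, case_id)
  rel_set <- if (i < series$n_releases) (i + 1L):series$n_releases
             else integer(0)
  exclude_by_cover(series, pub_index(series), tg$ci, tg$leaf, tg$v, rel_set)
}

#' @rdname b_attack
#' @export
l_attack <- function(series, i, case_id) {
  tg <- resolve_target(series, i, case_id)
  before <- cases_before(series, i)
  if (case_id %in% before) return(integer(0))  # premise: target is new here
  sort(intersect(tg$ci, before))
}

#' Audit a release series with the full BFL attack suite
#'
#' Runs the B-, F- and L-attacks against every published case of every
#' release, and reports each target's candidate set before and after
#' exclusion together with its post-exclusion confidences.  The L-attack is
#' evaluated only for targets whose CaseID is genuinely new in their
#' release, matching the attack's premise.
#'
#' @param series a `release_series` with raw leaf quarters.
#' @param params a [privacy_params]; its `k` and thresholds decide which
#'   findings count as dangerous.
#' @return A data frame with one row per (release, case): columns `release`,
#'   `case_id`, `group` (within-release group index), `ci_size`, `n_b`,
#'   `n_f`, `n_l`, `eff_size` (candidates surviving all exclusions),
#'   `new_case`, `max_conf` and `max_conf_term` (largest post-exclusion
#'   confidence and the term attaining it), `id_danger` (`eff_size < k`) and
#'   `sens_danger` (some term's post-exclusion confidence exceeds its
#'   threshold).
#' @export
audit_series <- function(series, params) {
  stopifnot(inherits(series, "release_series"),
            inherits(params, "privacy_params"))
  sch <- series$schema
  pub <- pub_index(series)
  rows_by_case <- split(seq_along(pub$case_id), pub$case_id)
  out <- vector("list", series$n_releases)
  for (i in seq_len(series$n_releases)) {
    rel <- series$released[[i]]
    if (is.null(rel) || nrow(rel) == 0L) next
    grp <- release_groups(rel, sch)
    lf <- leaf_cases(series, i)
    before <- cases_before(series, i)
    n_t <- length(unique(rel$case_id))
    acc <- list(case_id = integer(n_t), group = integer(n_t),
                ci_size = integer(n_t), n_b = integer(n_t),
                n_f = integer(n_t), n_l = integer(n_t),
                eff_size = integer(n_t), new_case = logical(n_t),
                max_conf = numeric(n_t), max_conf_term = character(n_t),
                id_danger = logical(n_t), sens_danger = logical(n_t))
    at <- 0L
    for (g in seq_len(max(grp))) {
      ci <- unique(rel$case_id[grp == g])
      vpos <- match(ci, lf$case_id)
      other <- unlist(rows_by_case[as.character(ci)], use.names = FALSE)
      prev_rows <- other[pub$release[other] < i]
      next_rows <- other[pub$release[other] > i]
      terms_ci <- lf$terms[vpos]
      for (t in seq_along(ci)) {
        v <- vpos[t]
        b <- if (length(prev_rows)) {
          cov <- qmat_covers_vec(pub, prev_rows, lf, v, sch)
          unique(pub$case_id[prev_rows[!cov]])
        } else integer(0)
        f <- if (length(next_rows)) {
          cov <- qmat_covers_vec(pub, next_rows, lf, v, sch)
          unique(pub$case_id[next_rows[!cov]])
        } else integer(0)
        new_case <- !(ci[t] %in% before)
        l <- if (new_case) intersect(ci, before) else integer(0)
        keep <- setdiff(ci, union(union(b, f), l))
        conf <- table(unlist(terms_ci[match(keep, ci)]))
        conf <- conf / length(keep)
        th <- theta_of(params$thresholds, names(conf))
        best <- if (length(conf)) which.max(conf) else integer(0)
        at <- at + 1L
        acc$case_id[at] <- ci[t]; acc$group[at] <- g
        acc$ci_size[at] <- length(ci)
        acc$n_b[at] <- length(b); acc$n_f[at] <- length(f)
        acc$n_l[at] <- length(l); acc$eff_size[at] <- length(keep)
        acc$new_case[at] <- new_case
        acc$max_conf[at] <- if (length(best)) as.numeric(conf[best]) else 0
        acc$max_conf_term[at] <- if (length(best)) names(conf)[best]
                                 else NA_character_
        acc$id_danger[at] <- length(keep) < params$k
        acc$sens_danger[at] <- any(as.numeric(conf) > th + 1e-12)
      }
    }
    out[[i]] <- cbind(data.frame(release = rep(i, at)),
                      as.data.frame(acc, stringsAsFactors = FALSE))
  }
  found <- do.call(rbind, out)
  rownames(found) <- NULL
  found
}

#' Write an audit report
#'
#' Serializes the findings of [audit_series()] as tab-separated text.
#'
#' @param findings data frame from [audit_series()].
#' @param path file path.
#' @export
write_audit_report <- function(findings, path) {
  utils::write.table(findings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
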