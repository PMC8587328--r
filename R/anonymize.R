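# PPMS-Anonymization and variants.
#
# Per quarter, the pipeline has three stages:
#   1. same-CaseID rows are merged into super records; old cases get their
#      QID pre-generalized to cover a designated earlier publication
#      (QID-covering, defeating the F-attack),
#   2. greedy clustering forms QID groups holding at least k new CaseIDs
#      (NC-bounding) and respecting every term's occurrence bound,
#   3. ungrouped records are assigned to the group with the least
#      privacy-risk-weighted information loss, super records are split back,
#      and each group is generalized to a common QID value.

#' Anonymize a series of raw quarterly SRS tables
#'
#' Runs the selected variant of the anonymization algorithm over the
#' quarters in order, each release taking the previously emitted releases as
#' its history.
#'
#' Variants: `"ppms"` covers each old case's most recent prior publication
#' and groups old and new cases together; `"ppms+"` covers only the earliest
#' prior publication (later publications are excludable by B/L-attacks
#' anyway, so covering them only accumulates generalization); `"ppms++"`
#' additionally keeps old cases out of group formation, assigning them
#' afterwards; `"ms"` is a single-release baseline (no covering, group size
#' counted over all cases) that is *not* safe against cross-release attacks
#' and serves as a comparison point.
#'
#' @param quarters list of raw quarterly data frames (columns `case_id`,
#'   `quarter`, the schema's QID columns at leaf level, `drugs`,
#'   `sensitive`).  Rows with missing QID or sensitive values are dropped.
#' @param schema an [srs_schema].
#' @param params a [privacy_params].
#' @param variant one of `"ppms"`, `"ppms+"`, `"ppms++"`, `"ms"`.
#' @return A `release_series` whose `released` quarters satisfy
#'   PPMS(k, theta*)-bounding whenever each quarter is globally feasible
#'   (see [infeasibility_report()]); infeasible records are suppressed and
#'   listed in `suppressed`.  The component `infeasible_terms` names, per
#'   quarter, any term whose global frequency makes the requirement
#'   unsatisfiable.
#' @examples
#' ser <- generate_series(synth_config(n_quarters = 2, cases_per_quarter = 60,
#'                                     seed = 7))
#' anon <- anonymize_series(ser$quarters, ser$schema,
#'                          privacy_params(k = 3, threshold_map(default = 0.5),
#'                                         seed = 7),
#'                          variant = "ppms++")
#' @export
anonymize_series <- function(quarters, schema, params,
                             variant = c("ppms", "ppms+", "ppms++", "ms")) {
  variant <- match.arg(variant)
  schema_check(schema)
  stopifnot(inherits(params, "privacy_params"))
  set.seed(params$seed)
  released <- list()
  suppressed <- list()
  infeasible <- list()
  for (i in seq_along(quarters)) {
    hist_idx <- seq_len(i - 1L)
    hist_idx <- hist_idx[hist_idx > i - 1L - params$lifespan_x]
    res <- anonymize_quarter(quarters[[i]], released[hist_idx], schema,
                             params, variant)
    released[[i]] <- res$release
    suppressed[[i]] <- res$suppressed
    infeasible[[i]] <- res$infeasible_terms
  }
  out <- new_release_series(schema, raw = lapply(quarters, drop_missing,
                                                 schema = schema),
                            released = released, suppressed = suppressed,
                            variant = variant)
  out$infeasible_terms <- infeasible
  out
}

#' Anonymize one raw quarter against its published history
#'
#' The single-quarter step of [anonymize_series()]; exposed for callers that
#' manage the release history themselves.
#'
#' @param quarter raw quarterly data frame.
#' @param history list of previously emitted releases inside the follow-up
#'   life-span window, oldest first (empty for a first release).
#' @param schema an [srs_schema].
#' @param params a [privacy_params].
#' @param variant algorithm variant, as in [anonymize_series()].
#' @return List with `release` (published data frame), `suppressed`
#'   (case_id, quarter, reason), `infeasible_terms`, and `groups` (the
#'   final generalized QID value of each group, as a data frame).
#' @export
anonymize_quarter <- function(quarter, history, schema, params,
                              variant = c("ppms", "ppms+", "ppms++", "ms")) {
  variant <- match.arg(variant)
  quarter <- drop_missing(quarter, schema)
  qtr_no <- if (nrow(quarter)) quarter$quarter[1] else NA_integer_
  empty_rel <- quarter[0, , drop = FALSE]
  empty_sup <- data.frame(case_id = integer(0), quarter = integer(0),
                          reason = character(0))
  if (nrow(quarter) == 0L)
    return(list(release = empty_rel, suppressed = empty_sup,
                infeasible_terms = character(0),
                groups = empty_rel[qid_cols(schema)]))

  S <- build_engine(quarter, history, schema, params, variant)

  # global feasibility diagnosis (does not abort: infeasible records are
  # suppressed record by record below)
  counts <- tabulate(S$flat_term, nbins = S$n_terms)
  names(counts) <- S$term_universe
  eta_glob <- floor(S$theta * sum(S$is_new) + 1e-9)
  infeasible_terms <- S$term_universe[counts > eta_glob]

  gr <- run_grouping(S, params)
  fin <- run_generalization(S, params, gr)

  # split super records back: every raw row of a grouped case takes its
  # group's generalized QID value
  assign <- fin$assign                  # group id per super record, NA = suppressed
  keep_sr <- which(!is.na(assign))
  rows <- unlist(S$member_rows[keep_sr], use.names = FALSE)
  grp_of_row <- rep(assign[keep_sr],
                    vapply(S$member_rows[keep_sr], length, 0L))
  rel <- quarter[rows, , drop = FALSE]
  gq <- fin$group_qids                  # list of per-group qid (lo, hi, cat)
  for (j in seq_along(schema$num)) {
    a <- schema$num[j]
    glab <- format_interval(vapply(gq, function(g) g$lo[j], 0),
                            vapply(gq, function(g) g$hi[j], 0))
    rel[[a]] <- glab[grp_of_row]
  }
  for (j in seq_along(schema$cat)) {
    a <- schema$cat[j]
    tx <- schema$attrs[[a]]$taxonomy
    glab <- tx$labels[vapply(gq, function(g) g$cat[j], 0L)]
    rel[[a]] <- glab[grp_of_row]
  }
  ord <- order(grp_of_row, rel$case_id)
  rel <- rel[ord, , drop = FALSE]
  rownames(rel) <- NULL

  sup_sr <- which(is.na(assign))
  suppressed <- if (length(sup_sr))
    data.frame(case_id = S$case_id[sup_sr], quarter = qtr_no,
               reason = fin$reason[sup_sr])
  else empty_sup

  if (!length(gq))
    return(list(release = empty_rel, suppressed = suppressed,
                infeasible_terms = infeasible_terms,
                groups = empty_rel[qid_cols(schema)]))
  groups_df <- do.call(rbind, lapply(gq, function(g) {
    qm <- list(num_lo = matrix(g$lo, 1), num_hi = matrix(g$hi, 1),
               cat = matrix(g$cat, 1), n = 1L)
    colnames(qm$num_lo) <- colnames(qm$num_hi) <- schema$num
    colnames(qm$cat) <- schema$cat
    qmat_to_df_cols(qm, schema)
  }))

  list(release = rel, suppressed = suppressed,
       infeasible_terms = infeasible_terms, groups = groups_df)
}

#' Merge same-CaseID rows of a quarter into super records
#'
#' All rows sharing a CaseID describe one event and must be anonymized as a
#' unit: the super record carries the least-common generalization of the
#' member QIDs and the union of their drugs and sensitive terms.
#'
#' @param quarter raw quarterly data frame.
#' @param schema an [srs_schema].
#' @return Data frame with one row per CaseID (columns as the input plus
#'   `n_members`).
#' @export
combine_super_records <- function(quarter, schema) {
  schema_check(schema)
  quarter <- drop_missing(quarter, schema)
  if (nrow(quarter) == 0L)
    return(cbind(quarter, n_members = integer(0)))
  qm <- df_to_qmat(quarter, schema)
  ids <- unique(quarter$case_id)
  pos <- split(seq_len(nrow(quarter)), factor(quarter$case_id, levels = ids))
  out <- data.frame(case_id = ids,
                    quarter = quarter$quarter[match(ids, quarter$case_id)])
  for (j in seq_along(schema$num)) {
    a <- schema$num[j]
    out[[a]] <- format_interval(
      vapply(pos, function(p) min(qm$num_lo[p, j]), 0),
      vapply(pos, function(p) max(qm$num_hi[p, j]), 0))
  }
  for (j in seq_along(schema$cat)) {
    a <- schema$cat[j]
    tx <- schema$attrs[[a]]$taxonomy
    out[[a]] <- tx$labels[vapply(pos, function(p) {
      node <- qm$cat[p[1], j]
      for (q in p[-1]) node <- tax_lca(tx, node, qm$cat[q, j])
      node
    }, 0L)]
  }
  out$drugs <- vapply(pos, function(p)
    paste(unique(unlist(split_terms(quarter$drugs[p]))), collapse = ";"), "")
  out$sensitive <- vapply(pos, function(p)
    paste(unique(unlist(split_terms(quarter$sensitive[p]))), collapse = ";"),
    "")
  out$n_members <- vapply(pos, length, 0L)
  rownames(out) <- NULL
  out
}

#' Pre-generalize old cases to cover a prior publication
#'
#' For every record whose CaseID already appears in the history, widens its
#' QID to cover the designated prior published value: the most recent prior
#' occurrence for `"ppms"` (transitivity then chains back through all older
#' ones), the earliest prior occurrence for `"ppms+"` / `"ppms++"` (later
#' publications are excludable by B/L-attacks regardless, so covering them
#' buys nothing).
#'
#' @param supers super-record data frame (see [combine_super_records()]).
#' @param history list of prior releases within the life-span window,
#'   oldest first.
#' @param schema an [srs_schema].
#' @param variant algorithm variant.
#' @return `supers` with generalized QID columns and a logical `new_case`
#'   column (`TRUE` when the CaseID is absent from the history).
#' @export
cover_old_cases <- function(supers, history, schema,
                            variant = c("ppms", "ppms+", "ppms++", "ms")) {
  variant <- match.arg(variant)
  hist_ids <- lapply(history, `[[`, "case_id")
  seen <- unique(unlist(hist_ids, use.names = FALSE))
  supers$new_case <- !(supers$case_id %in% seen)
  if (variant == "ms" || !length(history) || all(supers$new_case))
    return(supers)
  qm <- df_to_qmat(supers, schema)
  scan <- if (variant == "ppms") rev(seq_along(history))
          else seq_along(history)
  for (r in which(!supers$new_case)) {
    cid <- supers$case_id[r]
    for (h in scan) {
      hit <- which(hist_ids[[h]] == cid)
      if (!length(hit)) next
      hqm <- df_to_qmat(history[[h]][hit, , drop = FALSE], schema)
      for (j in seq_along(schema$num)) {
        qm$num_lo[r, j] <- min(qm$num_lo[r, j], hqm$num_lo[, j])
        qm$num_hi[r, j] <- max(qm$num_hi[r, j], hqm$num_hi[, j])
      }
      for (j in seq_along(schema$cat)) {
        tx <- schema$attrs[[schema$cat[j]]]$taxonomy
        node <- qm$cat[r, j]
        for (q in seq_len(hqm$n)) node <- tax_lca(tx, node, hqm$cat[q, j])
        qm$cat[r, j] <- node
      }
      break  # one designated occurrence suffices (covering transitivity)
    }
  }
  cols <- qmat_to_df_cols(qm, schema)
  for (a in qid_cols(schema)) supers[[a]] <- cols[[a]]
  supers
}

# ---- internal engine -----------------------------------------------------

drop_missing <- function(df, schema) {
  need <- c(qid_cols(schema), "sensitive")
  ok <- rep(TRUE, nrow(df))
  for (a in need) {
    v <- df[[a]]
    if (is.null(v)) stop("missing column: ", a)
    ok <- ok & !is.na(v) & trimws(as.character(v)) != ""
  }
  df[ok, , drop = FALSE]
}

build_engine <- function(quarter, history, schema, params, variant) {
  sup <- combine_super_records(quarter, schema)
  sup <- cover_old_cases(sup, history, schema, variant)
  if (variant == "ms") sup$new_case <- TRUE     # size-based k, no NC notion
  qm <- df_to_qmat(sup, schema)
  ids <- unique(quarter$case_id)
  member_rows <- split(seq_len(nrow(quarter)),
                       factor(quarter$case_id, levels = ids))
  dimnames(qm$num_lo) <- dimnames(qm$num_hi) <- dimnames(qm$cat) <- NULL
  terms_chr <- split_terms(sup$sensitive)
  term_universe <- sort(unique(unlist(terms_chr, use.names = FALSE)))
  terms <- lapply(terms_chr, function(x)
    match(unique(x), term_universe))
  flat_rec <- rep(seq_along(terms), vapply(terms, length, 0L))
  flat_term <- unlist(terms, use.names = FALSE)
  num_rng <- vapply(schema$attrs[schema$num],
                    function(a) a$max - a$min, 0)
  cat_tax <- lapply(schema$attrs[schema$cat], `[[`, "taxonomy")
  eta_k <- floor(theta_of(params$thresholds, term_universe) *
                 params$k + 1e-9)
  list(n = nrow(sup), case_id = sup$case_id, is_new = sup$new_case,
       qm = qm, member_rows = unname(member_rows),
       terms = terms, term_universe = term_universe,
       n_terms = length(term_universe),
       theta = theta_of(params$thresholds, term_universe),
       flat_rec = flat_rec, flat_term = flat_term,
       num_rng = num_rng, cat_tax = unname(cat_tax),
       m_num = length(schema$num), m_cat = length(schema$cat),
       k = params$k,
       # per-term record index and the risk contribution of a record whose
       # terms are all new to a group still below k new cases (eta then
       # equals its floor(theta * k) projection) -- the common case the
       # fast scoring path corrects from
       recs_by_term = lapply(seq_along(term_universe), function(t)
         flat_rec[flat_term == t]),
       eta_k = eta_k,
       base_k = as.vector(rowsum(1 / eta_k[flat_term], flat_rec)),
       # ppms++ forms groups from new cases only; old cases are assigned
       # during the generalization stage
       pool = if (variant == "ppms++") sup$new_case else rep(TRUE, nrow(sup)))
}

# per-record IL contribution of a candidate merge, vectorized over cand:
# returns IL(g + cand) - IL(g) for each candidate
engine_delta_il <- function(S, g, cand) {
  per <- numeric(length(cand))
  for (j in seq_len(S$m_num)) {
    hi <- S$qm$num_hi[cand, j]; lo <- S$qm$num_lo[cand, j]
    hi[hi < g$hi[j]] <- g$hi[j]
    lo[lo > g$lo[j]] <- g$lo[j]
    per <- per + (hi - lo) / S$num_rng[j]
  }
  for (j in seq_len(S$m_cat)) {
    tx <- S$cat_tax[[j]]
    b <- S$qm$cat[cand, j]
    dmax <- min(tx$depth[g$cat[j]], tx$height)
    lca_depth <- integer(length(b))
    if (dmax >= 1L) for (d in seq_len(dmax)) {
      eq <- tx$anc[b, d + 1L] == tx$anc[g$cat[j], d + 1L] &
            tx$anc[b, d + 1L] != 0L
      lca_depth <- lca_depth + (eq & lca_depth == (d - 1L))
    }
    per <- per + (tx$height - lca_depth) / tx$height
  }
  (g$size + 1) * (per - g$il_per)
}

# privacy risk of adding each record to group g (full-length vector; only
# entries for candidate rows are meaningful).  While a group is still
# growing towards its k new cases, the occurrence bound is projected to the
# new-case count the group is required to reach (eta is monotone in |NC|,
# so any record admissible under the projection is admissible in the
# finished group); the final feasibility check uses the actual count.
engine_pr <- function(S, g) {
  if (g$nc + 1L <= S$k) {
    # projection regime: eta = floor(theta * k) for every candidate, so the
    # all-terms-new baseline is precomputable; correct only the few terms
    # already present in g
    if (is.null(S$base_k)) stop("engine not initialised")  # defensive
    pr <- 1 + S$base_k
    for (s in which(g$sigma > 0L)) {
      idx <- S$recs_by_term[[s]]
      sig_new <- g$sigma[s] + 1L
      eta <- S$eta_k[s]
      pr[idx] <- if (sig_new > eta) Inf
                 else pr[idx] - 1 / eta + sig_new / (eta - sig_new + 1)
    }
    return(pr)
  }
  sig_new <- g$sigma[S$flat_term] + 1L
  nc_new <- pmax(g$nc + as.integer(S$is_new[S$flat_rec]), S$k)
  eta <- floor(S$theta[S$flat_term] * nc_new + 1e-9)
  pr_term <- ifelse(sig_new <= eta, sig_new / (eta - sig_new + 1), Inf)
  1 + as.vector(rowsum(pr_term, S$flat_rec))
}

new_group <- function(S, r) {
  g <- list(members = r,
            lo = S$qm$num_lo[r, ], hi = S$qm$num_hi[r, ],
            cat = S$qm$cat[r, ], size = 1L,
            nc = as.integer(S$is_new[r]),
            sigma = integer(S$n_terms))
  g$sigma[S$terms[[r]]] <- 1L
  g$il_per <- group_il_per(S, g)
  g
}

group_il_per <- function(S, g) {
  per <- 0
  for (j in seq_len(S$m_num)) per <- per + (g$hi[j] - g$lo[j]) / S$num_rng[j]
  for (j in seq_len(S$m_cat)) {
    tx <- S$cat_tax[[j]]
    per <- per + tx$node_height[g$cat[j]] / tx$height
  }
  per
}

group_add <- function(S, g, r) {
  for (j in seq_len(S$m_num)) {
    g$lo[j] <- min(g$lo[j], S$qm$num_lo[r, j])
    g$hi[j] <- max(g$hi[j], S$qm$num_hi[r, j])
  }
  for (j in seq_len(S$m_cat))
    g$cat[j] <- tax_lca(S$cat_tax[[j]], g$cat[j], S$qm$cat[r, j])
  g$members <- c(g$members, r)
  g$size <- g$size + 1L
  g$nc <- g$nc + as.integer(S$is_new[r])
  g$sigma[S$terms[[r]]] <- g$sigma[S$terms[[r]]] + 1L
  g$il_per <- group_il_per(S, g)
  g
}

group_feasible <- function(S, g) {
  all(g$sigma <= floor(S$theta * g$nc + 1e-9))
}

# can the remaining pool still form a group?  (prose stopping predicate:
# fewer than k new cases left, or some term too frequent among them)
pool_exhausted <- function(S, avail, k) {
  nc_rem <- sum(S$is_new & avail)
  if (nc_rem < k) return(TRUE)
  sel <- avail[S$flat_rec]
  cnt <- tabulate(S$flat_term[sel], nbins = S$n_terms)
  any(cnt > floor(S$theta * nc_rem + 1e-9))
}

# argmin with ties broken by smallest case_id then input order
pick_min <- function(values, case_ids) {
  fin <- is.finite(values)
  if (!any(fin)) return(NA_integer_)
  i <- which(fin)
  i[order(values[fin], case_ids[fin])[1]]
}

run_grouping <- function(S, params) {
  k <- params$k
  avail <- S$pool
  groups <- list()
  leftover <- integer(0)
  last_added <- NA_integer_
  repeat {
    if (pool_exhausted(S, avail, k)) break
    idx <- which(avail)
    if (is.na(last_added)) {
      seed <- idx[sample.int(length(idx), 1L)]
    } else {
      # next seed: the available record most distinguished (largest pairwise
      # information-loss increase) from the one just added
      gseed <- new_group(S, last_added)
      dil <- engine_delta_il(S, gseed, idx)
      seed <- idx[order(-dil, S$case_id[idx])[1]]
    }
    g <- new_group(S, seed)
    avail[seed] <- FALSE
    ok <- FALSE
    repeat {
      if (g$nc >= k && group_feasible(S, g)) { ok <- TRUE; break }
      cand <- which(avail)
      if (!length(cand)) break
      dil <- engine_delta_il(S, g, cand)
      pr <- engine_pr(S, g)[cand]
      dilp <- ifelse(is.infinite(pr), Inf, dil * pr)
      best <- pick_min(dilp, S$case_id[cand])
      if (is.na(best)) break
      r <- cand[best]
      g <- group_add(S, g, r)
      avail[r] <- FALSE
      last_added <- r
    }
    if (ok) {
      groups[[length(groups) + 1L]] <- g
    } else {
      # stalled before reaching k feasible new cases: dissolve to leftovers
      leftover <- c(leftover, g$members)
      last_added <- NA_integer_
    }
  }
  leftover <- c(leftover, which(avail))
  list(groups = groups, leftover = leftover)
}

run_generalization <- function(S, params, gr) {
  groups <- gr$groups
  assign <- rep(NA_integer_, S$n)
  reason <- rep(NA_character_, S$n)
  for (gi in seq_along(groups))
    assign[groups[[gi]]$members] <- gi
  to_place <- which(is.na(assign))   # leftovers + records kept out of the pool
  to_place <- to_place[order(S$case_id[to_place])]
  if (!length(groups)) {
    reason[to_place] <- "no feasible group in quarter"
    return(list(assign = assign, reason = reason, group_qids = list()))
  }
  # group state as matrices so each placement scores all groups at once
  G <- length(groups)
  glo <- do.call(rbind, lapply(groups, `[[`, "lo"))
  ghi <- do.call(rbind, lapply(groups, `[[`, "hi"))
  gcat <- do.call(rbind, lapply(groups, `[[`, "cat"))
  if (S$m_num == 0L) glo <- ghi <- matrix(0, G, 0)
  if (S$m_cat == 0L) gcat <- matrix(0L, G, 0)
  gsize <- vapply(groups, `[[`, 0L, "size")
  gnc <- vapply(groups, `[[`, 0L, "nc")
  gilper <- vapply(groups, `[[`, 0, "il_per")
  gsigma <- do.call(rbind, lapply(groups, `[[`, "sigma"))
  for (r in to_place) {
    per <- numeric(G)
    for (j in seq_len(S$m_num)) {
      hi <- ghi[, j]; lo <- glo[, j]
      hi[hi < S$qm$num_hi[r, j]] <- S$qm$num_hi[r, j]
      lo[lo > S$qm$num_lo[r, j]] <- S$qm$num_lo[r, j]
      per <- per + (hi - lo) / S$num_rng[j]
    }
    for (j in seq_len(S$m_cat)) {
      tx <- S$cat_tax[[j]]
      b <- S$qm$cat[r, j]
      dmax <- min(tx$depth[b], tx$height)
      lca_depth <- integer(G)
      if (dmax >= 1L) for (d in seq_len(dmax)) {
        eq <- tx$anc[gcat[, j], d + 1L] == tx$anc[b, d + 1L] &
              tx$anc[b, d + 1L] != 0L
        lca_depth <- lca_depth + (eq & lca_depth == (d - 1L))
      }
      per <- per + (tx$height - lca_depth) / tx$height
    }
    dil <- (gsize + 1) * (per - gilper)
    pr <- rep(1, G)
    nc_new <- gnc + as.integer(S$is_new[r])
    for (s in S$terms[[r]]) {
      sig <- gsigma[, s] + 1L
      eta <- floor(S$theta[s] * nc_new + 1e-9)
      contrib <- ifelse(sig <= eta, sig / (eta - sig + 1), Inf)
      pr <- pr + contrib
    }
    dilp <- ifelse(is.infinite(pr), Inf, dil * pr)
    best <- which(is.finite(dilp))
    if (!length(best)) {
      reason[r] <- "every placement exceeds a sensitive-term bound"
      next
    }
    gi <- best[which.min(dilp[best])]
    assign[r] <- gi
    for (j in seq_len(S$m_num)) {
      glo[gi, j] <- min(glo[gi, j], S$qm$num_lo[r, j])
      ghi[gi, j] <- max(ghi[gi, j], S$qm$num_hi[r, j])
    }
    for (j in seq_len(S$m_cat))
      gcat[gi, j] <- tax_lca(S$cat_tax[[j]], gcat[gi, j], S$qm$cat[r, j])
    gsize[gi] <- gsize[gi] + 1L
    gnc[gi] <- gnc[gi] + as.integer(S$is_new[r])
    gsigma[gi, S$terms[[r]]] <- gsigma[gi, S$terms[[r]]] + 1L
    gtmp <- list(lo = glo[gi, ], hi = ghi[gi, ], cat = gcat[gi, ])
    gilper[gi] <- group_il_per(S, gtmp)
  }
  list(assign = assign, reason = reason,
       group_qids = lapply(seq_len(G), function(gi)
         list(lo = glo[gi, ], hi = ghi[gi, ], cat = gcat[gi, ])))
}
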