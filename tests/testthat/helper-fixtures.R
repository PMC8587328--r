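# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately re-derive everything from first principles with
# naive loops (their own cover test, their own tree walks) so that they stay
# independent of the implementation paths they check.

two_cat_schema <- function() {
  srs_schema(attr_categorical("Sex", sex_taxonomy()),
             attr_categorical("Age", toy_age_taxonomy()))
}

mixed_schema <- function() {
  srs_schema(attr_categorical("Sex", sex_taxonomy()),
             attr_numeric("Age", 0, 100))
}

# ---- independent cover test ---------------------------------------------

# walk the parent chain of a label (edge list form, no taxonomy object)
oracle_ancestors <- function(parent_edges, label) {
  out <- label
  while (!is.null(parent_edges[[label]])) {
    label <- parent_edges[[label]]
    out <- c(out, label)
  }
  out
}

SEX_EDGES <- list(Male = "ANY", Female = "ANY")
AGE_EDGES <- list(Nonadult = "ANY", Adult = "ANY", Newborn = "Nonadult",
                  Infant = "Nonadult", Preschool = "Nonadult",
                  Child = "Nonadult", Adolescent = "Nonadult",
                  YoungAdult = "Adult", MiddleAged = "Adult", Aged = "Adult")

# q1, q2: list(Sex = label, Age = c(lo, hi)) on mixed_schema()
oracle_covers <- function(q1, q2) {
  sex_ok <- q1$Sex %in% oracle_ancestors(SEX_EDGES, q2$Sex)
  age_ok <- q1$Age[1] <= q2$Age[1] && q1$Age[2] >= q2$Age[2]
  sex_ok && age_ok
}

parse_age <- function(x) {
  p <- as.numeric(strsplit(as.character(x), "-", fixed = TRUE)[[1]])
  if (length(p) == 1) c(p, p) else p
}

row_qid <- function(df, i) list(Sex = df$Sex[i], Age = parse_age(df$Age[i]))

# ---- brute-force BFL audit oracle ---------------------------------------

# direct nested-loop enumeration of the attack definitions on a series over
# mixed_schema(); returns per (release, case): eff size and B/F/L counts
oracle_audit <- function(series) {
  n <- length(series$released)
  res <- list()
  for (i in seq_len(n)) {
    rel <- series$released[[i]]
    raw <- series$raw[[i]]
    key <- paste(rel$Sex, rel$Age)
    for (cid in unique(rel$case_id)) {
      g_key <- key[match(cid, rel$case_id)]
      ci <- unique(rel$case_id[key == g_key])
      # leaf of the target: hull over its raw rows this quarter
      rrows <- which(raw$case_id == cid)
      ages <- do.call(rbind, lapply(rrows, function(r) parse_age(raw$Age[r])))
      sexes <- unique(raw$Sex[rrows])
      leaf <- list(Sex = if (length(sexes) == 1) sexes else "ANY",
                   Age = c(min(ages[, 1]), max(ages[, 2])))
      b <- f <- l <- integer(0)
      for (c2 in ci) {
        for (j in seq_len(n)) {
          if (j == i) next
          relj <- series$released[[j]]
          for (r in which(relj$case_id == c2)) {
            q_r <- row_qid(relj, r)
            if (!oracle_covers(q_r, leaf)) {
              if (j < i) b <- union(b, c2) else f <- union(f, c2)
            }
          }
        }
      }
      appears_before <- function(c2) {
        any(vapply(seq_len(i - 1), function(j)
          c2 %in% series$released[[j]]$case_id, TRUE))
      }
      if (i > 1 && !appears_before(cid))
        l <- ci[vapply(ci, appears_before, TRUE)]
      eff <- setdiff(ci, union(union(b, f), l))
      res[[length(res) + 1]] <- data.frame(
        release = i, case_id = cid, ci_size = length(ci),
        n_b = length(b), n_f = length(f), n_l = length(l),
        eff_size = length(eff))
    }
  }
  do.call(rbind, res)
}

# random small series (published values arbitrary, leaves fixed per case)
random_series <- function(seed) {
  set.seed(seed)
  sch <- mixed_schema()
  pool <- 1:12
  leaf_sex <- sample(c("Male", "Female"), length(pool), replace = TRUE)
  leaf_age <- sample(30:40, length(pool), replace = TRUE)
  n_rel <- sample(2:3, 1)
  raw <- list(); released <- list()
  for (i in seq_len(n_rel)) {
    ids <- sort(sample(pool, sample(4:9, 1)))
    raw[[i]] <- data.frame(case_id = ids, quarter = i,
                           Sex = leaf_sex[ids], Age = as.character(leaf_age[ids]),
                           drugs = "", sensitive = sample(c("Flu", "HIV", "Fever"),
                                                          length(ids), TRUE),
                           stringsAsFactors = FALSE)
    # published: random coarsening, a handful of distinct group values
    n_g <- sample(1:3, 1)
    gq <- lapply(seq_len(n_g), function(.) {
      lo <- sample(30:38, 1); hi <- lo + sample(0:4, 1)
      list(Sex = sample(c("Male", "Female", "ANY"), 1),
           Age = if (lo == hi) as.character(lo) else paste0(lo, "-", hi))
    })
    pick <- sample(n_g, length(ids), replace = TRUE)
    released[[i]] <- data.frame(
      case_id = ids, quarter = i,
      Sex = vapply(gq[pick], `[[`, "", "Sex"),
      Age = vapply(gq[pick], `[[`, "", "Age"),
      drugs = "", sensitive = raw[[i]]$sensitive,
      stringsAsFactors = FALSE)
  }
  ppmsanon:::new_release_series(sch, raw = raw, released = released)
}

# ---- signal tabulation oracle -------------------------------------------

# one case = one unit; condition tested on the case's merged value
oracle_rule_counts <- function(df, drug, reaction, cond_fun) {
  ids <- unique(df$case_id)
  a <- b <- cc <- d <- 0L
  n <- 0L
  for (cid in ids) {
    rows <- which(df$case_id == cid)
    ages <- do.call(rbind, lapply(rows, function(r) parse_age(df$Age[r])))
    sexes <- unique(df$Sex[rows])
    if (!cond_fun(list(Sex = if (length(sexes) == 1) sexes else "ANY",
                       Age = c(min(ages[, 1]), max(ages[, 2])))))
      next
    n <- n + 1L
    dr <- unique(unlist(strsplit(df$drugs[rows], ";")))
    re <- unique(unlist(strsplit(df$sensitive[rows], ";")))
    hd <- drug %in% dr
    hr <- reaction %in% re
    if (hd && hr) a <- a + 1L else if (hd) b <- b + 1L
    else if (hr) cc <- cc + 1L else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d, n = n)
}

# small synthetic configuration used across tests (kept quick)
quick_synth <- function(seed, ...) {
  defaults <- list(n_quarters = 3, cases_per_quarter = 120, n_symptoms = 40,
                   seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}
quick_params <- function(seed = 1, k = 3, theta = 0.6) {
  privacy_params(k, threshold_map(default = theta), seed = seed)
}
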