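# The three-stage anonymizer and its variants.

test_that("same-CaseID rows merge into super records with hull and union", {
  sch <- mixed_schema()
  q <- data.frame(case_id = c(5, 5, 9), quarter = 1,
                  Sex = c("Male", "Male", "Female"),
                  Age = c("30", "32", "40"), drugs = c("D1", "D2", "D1"),
                  sensitive = c("Flu", "Fever", "Flu"))
  sup <- combine_super_records(q, sch)
  expect_equal(nrow(sup), 2)
  r5 <- sup[sup$case_id == 5, ]
  expect_equal(r5$Age, "30-32")
  expect_setequal(strsplit(r5$sensitive, ";")[[1]], c("Flu", "Fever"))
  expect_setequal(strsplit(r5$drugs, ";")[[1]], c("D1", "D2"))
  expect_equal(r5$n_members, 2L)
  # all-distinct quarter passes through unchanged
  expect_equal(nrow(combine_super_records(q[3, ], sch)), 1)
  # empty quarter
  expect_equal(nrow(combine_super_records(q[0, ], sch)), 0)
})

test_that("old cases are widened to cover the designated prior publication", {
  sch <- mixed_schema()
  hist <- list(
    data.frame(case_id = 7, quarter = 2, Sex = "ANY", Age = "30-40",
               drugs = "", sensitive = "Diabetes"))
  sup <- data.frame(case_id = c(7, 8, 18), quarter = 3,
                    Sex = "Male", Age = c("31", "34", "33"),
                    drugs = "", sensitive = c("Diabetes", "Fever", "HIV"))
  out <- cover_old_cases(sup, hist, sch, "ppms")
  expect_equal(out$Sex[out$case_id == 7], "ANY")
  expect_equal(out$Age[out$case_id == 7], "30-40")
  expect_equal(out$Sex[out$case_id == 8], "Male")   # new: untouched
  expect_true(all(out$new_case == c(FALSE, TRUE, TRUE)))
  # a record already covering its prior publication stays unchanged
  sup2 <- data.frame(case_id = 7, quarter = 3, Sex = "ANY", Age = "25-45",
                     drugs = "", sensitive = "Diabetes")
  out2 <- cover_old_cases(sup2, hist, sch, "ppms")
  expect_equal(out2$Age, "25-45")
})

test_that("ppms scans newest-first and ppms+ earliest-first for covering", {
  sch <- mixed_schema()
  hist <- list(
    data.frame(case_id = 1, quarter = 1, Sex = "Male", Age = "30-31",
               drugs = "", sensitive = "Flu"),
    data.frame(case_id = 1, quarter = 2, Sex = "ANY", Age = "20-40",
               drugs = "", sensitive = "Flu"))
  sup <- data.frame(case_id = 1, quarter = 3, Sex = "Male", Age = "30",
                    drugs = "", sensitive = "Flu")
  # ppms covers the accumulated (latest) publication
  got <- cover_old_cases(sup, hist, sch, "ppms")
  expect_equal(got$Sex, "ANY"); expect_equal(got$Age, "20-40")
  # ppms+ covers only the earliest, escaping the accumulation
  got_p <- cover_old_cases(sup, hist, sch, "ppms+")
  expect_equal(got_p$Sex, "Male"); expect_equal(got_p$Age, "30-31")
})

test_that("emitted groups satisfy NC-bounding and every term bound", {
  ser <- generate_series(quick_synth(21))
  prm <- quick_params(seed = 21, k = 3, theta = 0.5)
  for (v in c("ppms", "ppms+", "ppms++")) {
    anon <- anonymize_series(ser$quarters, ser$schema, prm, v)
    for (i in seq_along(anon$released)) {
      rel <- anon$released[[i]]
      if (!nrow(rel)) next
      hist_ids <- unique(unlist(lapply(anon$released[seq_len(i - 1)],
                                       `[[`, "case_id")))
      grp <- ppmsanon:::release_groups(rel, ser$schema)
      for (g in unique(grp)) {
        gg <- qid_group(rel[grp == g, ],
                        new_case_ids = setdiff(rel$case_id, hist_ids))
        expect_gte(gg$nc_count, prm$k)
        eta <- eta_bound(0.5, gg$nc_count)
        expect_true(all(gg$sigma <= eta))
      }
    }
  }
})

test_that("published QIDs of old cases cover their designated prior value", {
  ser <- generate_series(quick_synth(31))
  sch <- ser$schema
  for (v in c("ppms", "ppms+", "ppms++")) {
    anon <- anonymize_series(ser$quarters, sch, quick_params(31), v)
    pubs <- do.call(rbind, anon$released)
    for (cid in unique(pubs$case_id[duplicated(pubs$case_id)])) {
      rows <- pubs[pubs$case_id == cid, ]
      rows <- rows[order(rows$quarter), ]
      qs <- unique(rows$quarter)
      qcols <- c("Sex", "Age", "Weight")
      for (qi in seq_along(qs)[-1]) {
        cur <- rows[rows$quarter == qs[qi], qcols][1, ]
        prior_q <- if (v == "ppms") qs[qi - 1] else qs[1]
        prior <- rows[rows$quarter == prior_q, qcols][1, ]
        expect_true(covers(cur, prior, sch),
                    info = paste(v, "case", cid, "quarter", qs[qi]))
      }
    }
  }
})

test_that("identical seeds give identical releases", {
  ser <- generate_series(quick_synth(5))
  prm <- quick_params(seed = 99)
  a1 <- anonymize_series(ser$quarters, ser$schema, prm, "ppms++")
  a2 <- anonymize_series(ser$quarters, ser$schema, prm, "ppms++")
  expect_identical(a1$released, a2$released)
  a3 <- anonymize_series(ser$quarters, ser$schema, quick_params(seed = 100),
                         "ppms++")
  expect_false(identical(a1$released, a3$released))
})

test_that("without repeated CaseIDs the MS baseline equals PPMS", {
  cf <- quick_synth(13, followup_prob = 0, dup_prob = 0, n_quarters = 1)
  ser <- generate_series(cf)
  prm <- quick_params(seed = 13)
  ppms <- anonymize_series(ser$quarters, ser$schema, prm, "ppms")
  ms <- anonymize_series(ser$quarters, ser$schema, prm, "ms")
  expect_identical(ppms$released, ms$released)
})

test_that("records that fit nowhere are suppressed, never force-placed", {
  sch <- mixed_schema()
  # five cases share one term; theta = 0.4, k = 3 admits at most
  # floor(0.4 * nc) of them per group -> overflow must be suppressed
  q <- data.frame(case_id = 1:8, quarter = 1, Sex = "Male",
                  Age = as.character(30:37), drugs = "",
                  sensitive = c(rep("HIV", 5), "Flu", "Fever", "Cold"))
  prm <- privacy_params(3, threshold_map(default = 0.4), seed = 2)
  res <- anonymize_quarter(q, list(), sch, prm, "ppms++")
  expect_gt(nrow(res$suppressed), 0)
  expect_true("HIV" %in% res$infeasible_terms)
  # published part still satisfies the bounds
  rel <- res$release
  grp <- ppmsanon:::release_groups(rel, sch)
  for (g in unique(grp)) {
    gg <- qid_group(rel[grp == g, ])
    expect_true(all(gg$sigma <= eta_bound(0.4, gg$nc_count)))
  }
})

test_that("mean information loss orders ppms++ <= ppms+ <= ppms over seeds", {
  nil_of <- function(v, seed) {
    ser <- generate_series(synth_config(
      n_quarters = 4, cases_per_quarter = 150, n_symptoms = 50,
      seed = seed))
    prm <- privacy_params(4, threshold_map(default = 0.6), seed = seed)
    anon <- anonymize_series(ser$quarters, ser$schema, prm, v)
    # an infeasible quarter publishes nothing and has no information loss
    # to average (failed releases are likewise omitted from NIL summaries
    # in practice)
    rels <- Filter(nrow, anon$released)
    mean(vapply(rels, metric_nil, 0, schema = ser$schema))
  }
  seeds <- 1:20
  m_pp <- mean(vapply(seeds, function(s) nil_of("ppms++", s), 0))
  m_p <- mean(vapply(seeds, function(s) nil_of("ppms+", s), 0))
  m_0 <- mean(vapply(seeds, function(s) nil_of("ppms", s), 0))
  expect_lte(m_pp, m_p)
  expect_lte(m_p, m_0)
})
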