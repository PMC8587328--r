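# Confidence, the occurrence bound, privacy risk, and threshold schemes.

# thresholds are looked up through the map
theta_of_export <- function(tm, terms) ppmsanon:::theta_of(tm, terms)

test_that("confidence follows sigma_s(g)/|g| through the exclusion chain", {
  rel2 <- example_series_vulnerable()$released[[2]]
  g <- qid_group(rel2[rel2$case_id %in% c(1, 4, 7), ])
  expect_equal(confidence(g, "HIV"), 1 / 3)
  expect_equal(confidence(g, "Flu"), 1 / 3)
  g2 <- qid_group(rel2[rel2$case_id %in% c(4, 7), ])
  expect_equal(confidence(g2, "HIV"), 1 / 2)
  expect_equal(confidence(g2, "Measles"), 0)   # absent term
  # cases, not rows: duplicate rows of one case count once
  dup <- data.frame(case_id = c(1, 1, 2), sensitive = c("HIV", "HIV", "Flu"))
  expect_equal(confidence(qid_group(dup), "HIV"), 1 / 2)
})

test_that("eta bound is the floor form and reproduces the printed failure", {
  # 3877 cases of one symptom among 18462 new cases breaks theta = 0.2:
  # 21.00% > 20%
  expect_equal(eta_bound(0.2, 18462), 3692L)
  expect_true(3877 > eta_bound(0.2, 18462))
  expect_equal(round(100 * 3877 / 18462, 2), 21.00)
  expect_equal(eta_bound(1, 7), 7L)
  expect_equal(eta_bound(0.5, 4), 2L)
  expect_equal(eta_bound(0.5, 5), 2L)
  # monotone nondecreasing in both arguments
  th <- seq(0, 1, by = 0.1)
  expect_true(all(diff(eta_bound(th, 10)) >= 0))
  expect_true(all(diff(vapply(1:30, function(n) eta_bound(0.3, n), 0L)) >= 0))
})

test_that("privacy risk grows with term concentration and hits Inf at the bound", {
  recs <- data.frame(case_id = 1:10, sensitive = c(rep("Flu", 4), rep("HIV", 2),
                                                   rep("Fever", 4)))
  g <- qid_group(recs)          # all new: nc = 10
  tm <- threshold_map(default = 0.5)
  # eta(11) = 5; Flu would reach 5 <= 5: feasible; risk exceeds 1
  expect_gt(privacy_risk(g, "Flu", tm), 1)
  # a term new to g contributes little but PR stays > 1
  expect_gt(privacy_risk(g, "Measles", tm), 1)
  # pushing past the bound is infinite: theta 0.2 -> eta(11) = 2 < 5
  expect_identical(privacy_risk(g, "Flu", threshold_map(default = 0.2)), Inf)
  # strictly increasing in sigma at fixed eta
  risks <- vapply(1:5, function(s) {
    gi <- qid_group(data.frame(case_id = 1:10,
                               sensitive = c(rep("X", s),
                                             paste0("pad", seq_len(10 - s)))))
    privacy_risk(gi, "X", tm)
  }, 0)
  expect_true(all(diff(risks) > 0))
})

test_that("feasibility bridges the confidence definition", {
  # all-new groups with sigma <= eta keep conf <= theta
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    sig <- sample(0:n, 1)
    theta <- runif(1)
    if (sig > eta_bound(theta, n)) next
    g <- qid_group(data.frame(case_id = seq_len(n),
                              sensitive = c(rep("S", sig),
                                            paste0("p", seq_len(n - sig)))))
    expect_lte(confidence(g, "S"), theta + 1e-12)
  }
})

test_that("delta_il_prime multiplies risk into loss with Inf dominance", {
  sch <- mixed_schema()
  recs <- data.frame(case_id = 1:3, Sex = "Male", Age = c("30", "32", "34"),
                     sensitive = c("Flu", "Flu", "Fever"))
  g <- qid_group(recs)
  tm <- threshold_map(default = 0.5)
  inside <- data.frame(Sex = "Male", Age = "33", sensitive = "Measles")
  expect_equal(delta_il_prime(g, inside, tm, sch), 0)   # covered, feasible
  infeas <- data.frame(Sex = "Male", Age = "33", sensitive = "Flu")
  expect_identical(delta_il_prime(g, infeas, threshold_map(default = 0.2),
                                  sch), Inf)
  # between two equal-loss candidates the rarer-term one scores lower
  r_rare <- data.frame(Sex = "Female", Age = "32", sensitive = "Measles")
  r_common <- data.frame(Sex = "Female", Age = "32", sensitive = "Flu")
  expect_lt(delta_il_prime(g, r_rare, tm, sch),
            delta_il_prime(g, r_common, tm, sch))
})

test_that("threshold schemes assign the documented bands", {
  # uniform
  tmu <- set_thresholds(NULL, "uniform", theta = 0.2)
  expect_equal(theta_of_export(tmu, c("a", "b")), c(0.2, 0.2))
  # frequency: m = 20.8, population SD = 39.6 -> a..d mid band, e top band
  cts <- c(a = 1, b = 1, c = 1, d = 1, e = 100)
  tmf <- set_thresholds(cts, "frequency")
  expect_equal(theta_of_export(tmf, c("a", "b", "c", "d")), rep(0.6, 4))
  expect_equal(theta_of_export(tmf, "e"), 1.0)
  # a genuinely rare term lands in the bottom band
  cts2 <- c(x = 1, y = 50, z = 50, w = 50, v = 50)
  expect_equal(theta_of_export(set_thresholds(cts2, "frequency"), "x"), 0.2)
  # invariant to relabelling
  cts3 <- cts; names(cts3) <- paste0("T", seq_along(cts))
  tmf3 <- set_thresholds(cts3, "frequency")
  expect_equal(unname(sort(tmf3$theta)), unname(sort(tmf$theta)))
  # level-wise mapping
  tml <- set_thresholds(c(hiv = 5, cough = 50), "levelwise",
                        levels = c(hiv = "high", cough = "non"))
  expect_equal(theta_of_export(tml, c("hiv", "cough", "other")),
               c(0.2, 1.0, 0.4))
  expect_error(set_thresholds(cts, "levelwise", levels = c(a = "weird")),
               "level")
})

test_that("infeasibility report reproduces the printed diagnosis ratios", {
  rep1 <- infeasibility_report(
    c(`Diabetes Mellitus Non-Insulin-Dependent` = 3877), 20467, 18462,
    threshold_map(default = 0.2))
  expect_equal(round(rep1$share_pct, 2), 18.94)
  expect_equal(round(rep1$new_case_pct, 2), 21.00)
  expect_false(rep1$feasible)
  rep2 <- infeasibility_report(c(`Smoking Cessation Therapy` = 12727),
                               56550, 56550, threshold_map(default = 0.2))
  expect_equal(round(rep2$share_pct, 2), 22.51)
  expect_false(rep2$feasible)
})
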