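# PRR signal mechanics on raw and anonymized data.

test_that("PRR arithmetic and the a >= 3 validity gate", {
  expect_equal(prr(4, 6, 16, 74), 2.25)
  expect_equal(prr(2, 100, 1, 1), 0)          # rare rule forced to 0
  expect_equal(prr(5, 5, 10, 10), 1)          # no disproportionality
  expect_identical(prr(3, 7, 0, 90), Inf)     # no comparator reaction
  expect_error(prr(3, -1, 1, 1), "nonnegative")
  # scale invariance when a >= 3 on both scales
  expect_equal(prr(3, 9, 6, 30), prr(30, 90, 60, 300))
})

test_that("entailment requires the whole generalization to satisfy the condition", {
  sch <- mixed_schema()
  r_any <- adr_rule("D1", "X", "Sex", "==", "Female")
  expect_false(condition_entails(qid_value(sch, Sex = "ANY", Age = 30),
                                 r_any, sch))
  expect_true(condition_entails(qid_value(sch, Sex = "Female", Age = 30),
                                r_any, sch))
  r_age <- adr_rule("D1", "X", "Age", ">", 18)
  expect_true(condition_entails(qid_value(sch, Sex = "Male", Age = c(30, 35)),
                                r_age, sch))
  expect_false(condition_entails(qid_value(sch, Sex = "Male", Age = c(15, 25)),
                                 r_age, sch))
  expect_false(condition_entails(qid_value(sch, Sex = "Male", Age = 18),
                                 r_age, sch))  # boundary not entailed by >
})

test_that("rule evaluation matches the brute-force tabulation oracle", {
  cf <- quick_synth(17, n_quarters = 1, cases_per_quarter = 400)
  ser <- generate_series(cf)
  q <- ser$quarters[[1]]
  rule <- adr_rule("D01", "MyocardialInfarction", "Age", ">", 60)
  got <- evaluate_rule(q, rule, ser$schema)
  want <- oracle_rule_counts(q, "D01", "MyocardialInfarction",
                             function(qid) qid$Age[1] > 60)
  expect_equal(got$a, want$a)
  expect_equal(got$b, want$b)
  expect_equal(got$c, want$c)
  expect_equal(got$d, want$d)
  expect_equal(got$n, want$n)
  expect_equal(got$prr, prr(want$a, want$b, want$c, want$d))
})

test_that("the planted association is recovered as a valid signal", {
  ser <- generate_series(quick_synth(23, n_quarters = 1,
                                     cases_per_quarter = 800))
  rule <- adr_rule("D01", "MyocardialInfarction", "Age", ">", 60)
  res <- evaluate_rule(ser$quarters[[1]], rule, ser$schema)
  expect_gte(res$a, 3)
  expect_gt(res$prr, 2)
  expect_true(res$valid)
})

test_that("generalization never increases the a count", {
  set.seed(9)
  for (s in 1:5) {
    ser <- generate_series(quick_synth(30 + s, n_quarters = 1,
                                       cases_per_quarter = 300))
    q <- ser$quarters[[1]]
    anon <- anonymize_series(list(q), ser$schema, quick_params(s), "ppms")
    rule <- adr_rule("D01", "MyocardialInfarction", "Age", ">", 60)
    a_raw <- evaluate_rule(q, rule, ser$schema)$a
    a_anon <- tryCatch(evaluate_rule(anon$released[[1]], rule, ser$schema)$a,
                       error = function(e) 0L)
    expect_lte(a_anon, a_raw)
  }
})

test_that("a rare rule is invalidated by a single missing count", {
  sch <- mixed_schema()
  # raw: a = 3 exactly, strong rule
  mk <- function(sexes) data.frame(
    case_id = 1:12, quarter = 1, Sex = sexes, Age = as.character(30:41),
    drugs = c(rep("Zel", 5), rep("Other", 7)),
    sensitive = c(rep("CVA", 3), "Flu", "Flu", "CVA", rep("Flu", 6)))
  raw <- mk(rep("Female", 12))
  rule <- adr_rule("Zel", "CVA", "Sex", "==", "Female")
  r0 <- evaluate_rule(raw, rule, sch)
  expect_equal(r0$a, 3)
  expect_true(r0$valid)
  # anonymization generalizes one contributing report's sex to ANY
  anon <- mk(c("ANY", rep("Female", 11)))
  sb <- signal_bias(raw, anon, rule, sch)
  expect_equal(sb$anonymized$a, 2)
  expect_equal(sb$anonymized$prr, 0)
  expect_equal(sb$count_delta, -1)
  expect_lt(sb$prr_delta, -2)   # the full raw strength is wiped out
  # root-generalizing the condition attribute wipes the count entirely
  allany <- mk(rep("ANY", 12))
  expect_error(evaluate_rule(allany, rule, sch), "entails")
})
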