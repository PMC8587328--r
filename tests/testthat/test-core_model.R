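# QID values, the cover relation, least common generalization, and the
# information-loss family.

test_that("covers matches the linkage scenarios and basic geometry", {
  sch <- mixed_schema()
  alice <- qid_value(sch, Sex = "Female", Age = 32)
  expect_true(covers(qid_value(sch, Sex = "ANY", Age = c(30, 40)), alice, sch))
  expect_false(covers(qid_value(sch, Sex = "Male", Age = c(35, 40)), alice, sch))
  expect_true(covers(alice, alice, sch))                       # reflexive
  # inclusive interval ends
  expect_true(covers(qid_value(sch, Sex = "Female", Age = c(30, 32)), alice, sch))
  expect_false(covers(qid_value(sch, Sex = "Female", Age = c(30, 31)), alice, sch))
})

test_that("covers is a partial order on random values", {
  sch <- two_cat_schema()
  tx_sex <- sch$attrs$Sex$taxonomy
  tx_age <- sch$attrs$Age$taxonomy
  set.seed(42)
  vals <- replicate(30, qid_value(sch,
    Sex = sample(tx_sex$labels, 1), Age = sample(tx_age$labels, 1)),
    simplify = FALSE)
  for (rep in 1:200) {
    i <- sample(30, 3, replace = TRUE)
    a <- vals[[i[1]]]; b <- vals[[i[2]]]; c <- vals[[i[3]]]
    # transitivity
    if (covers(a, b, sch) && covers(b, c, sch))
      expect_true(covers(a, c, sch))
    # antisymmetry on canonical values
    if (covers(a, b, sch) && covers(b, a, sch))
      expect_identical(unclass(a), unclass(b))
  }
})

test_that("qid_lub is the least upper bound", {
  sch <- mixed_schema()
  m <- qid_value(sch, Sex = "Male", Age = c(30, 35))
  f <- qid_value(sch, Sex = "Female", Age = c(35, 40))
  lub <- qid_lub(list(m, f), sch)
  expect_identical(lub$Sex, "ANY")
  expect_equal(lub$Age, c(30, 40))
  expect_identical(qid_lub(list(m), sch), m)      # singleton
  # lub covers every input, and no strictly less general value does:
  # brute-force over the small value lattice of the categorical schema
  sch2 <- two_cat_schema()
  tx_age <- sch2$attrs$Age$taxonomy
  all_vals <- expand.grid(Sex = sch2$attrs$Sex$taxonomy$labels,
                          Age = tx_age$labels, stringsAsFactors = FALSE)
  set.seed(7)
  for (rep in 1:25) {
    pick <- all_vals[sample(nrow(all_vals), 3, replace = TRUE), ]
    vs <- lapply(seq_len(3), function(i)
      qid_value(sch2, Sex = pick$Sex[i], Age = pick$Age[i]))
    lub <- qid_lub(vs, sch2)
    for (v in vs) expect_true(covers(lub, v, sch2))
    for (i in seq_len(nrow(all_vals))) {
      cand <- qid_value(sch2, Sex = all_vals$Sex[i], Age = all_vals$Age[i])
      covers_all <- all(vapply(vs, function(v) covers(cand, v, sch2), TRUE))
      if (covers_all) expect_true(covers(cand, lub, sch2))
    }
  }
})

test_that("group information loss reproduces hand-computed values", {
  sch <- two_cat_schema()
  # three records generalized to <ANY, Nonadult>: 3 * (1/1 + 1/2)
  g <- data.frame(Sex = c("Male", "Female", "Male"),
                  Age = c("Newborn", "Preschool", "Child"))
  expect_equal(group_il(g, sch), 4.5)
  # a single leaf record loses nothing
  expect_equal(group_il(data.frame(Sex = "Male", Age = "Newborn"), sch), 0)
  # everything at the root costs |g| * |QID|
  root <- data.frame(Sex = c("Male", "Female"), Age = c("Newborn", "Aged"))
  expect_equal(group_il(root, sch), 2 * 2)
  # numeric share: group range over global range
  schm <- mixed_schema()
  gm <- data.frame(Sex = c("Male", "Male"), Age = c("30", "40"))
  expect_equal(group_il(gm, schm), 2 * (10 / 100))
})

test_that("delta_il is the nonnegative marginal loss, zero iff covered", {
  sch <- two_cat_schema()
  g <- data.frame(Sex = "Male", Age = "Newborn")
  r <- data.frame(Sex = "Male", Age = "Preschool")
  expect_equal(delta_il(g, r, sch), 1.0)   # 2 * (0 + 1/2) - 0
  expect_equal(delta_il(g, g, sch), 0)     # identical value
  # property: delta_il >= 0, and == 0 when the group lub covers r
  set.seed(11)
  tx_age <- sch$attrs$Age$taxonomy
  for (rep in 1:50) {
    gdf <- data.frame(Sex = sample(c("Male", "Female", "ANY"), 2, TRUE),
                      Age = sample(tx_age$labels, 2, TRUE))
    rdf <- data.frame(Sex = sample(c("Male", "Female"), 1),
                      Age = sample(tx_age$labels[tx_age$is_leaf], 1))
    d <- delta_il(gdf, rdf, sch)
    expect_gte(d, 0)
    if (covers(qid_lub(gdf, sch), qid_value(sch, Sex = rdf$Sex, Age = rdf$Age),
               sch))
      expect_equal(d, 0)
  }
})

test_that("group_il is monotone under further generalization", {
  sch <- two_cat_schema()
  set.seed(5)
  tx_age <- sch$attrs$Age$taxonomy
  leaves <- tx_age$labels[tx_age$is_leaf]
  for (rep in 1:30) {
    gdf <- data.frame(Sex = sample(c("Male", "Female"), 3, TRUE),
                      Age = sample(leaves, 3, TRUE))
    il0 <- group_il(gdf, sch)
    coarser <- gdf
    coarser$Age <- "ANY"                     # widen one attribute to root
    expect_gte(group_il(coarser, sch), il0)
  }
})

test_that("taxonomy files round-trip and malformed trees are rejected", {
  tx <- toy_age_taxonomy()
  p <- tempfile(fileext = ".tsv")
  write_taxonomy(tx, p)
  tx2 <- read_taxonomy(p)
  expect_setequal(tx2$labels, tx$labels)
  expect_equal(tx2$height, tx$height)
  expect_error(taxonomy(c(A = "B", B = "A")), "cycle|root")
  expect_error(taxonomy(c(A = "ANY", A = "B")))  # duplicate child
})
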