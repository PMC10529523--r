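test_that("variance percentage follows the published formula and conventions", {
  expect_equal(variance_percentage(10, 8), 20)
  expect_equal(variance_percentage(5, 14), -180)
  expect_true(is.na(variance_percentage(0, 22)))
  expect_equal(variance_percentage(0, 0), 0)
  expect_equal(variance_percentage(37, 37), 0)
  expect_error(variance_percentage(101, 5), "\\[0, 100\\]")
  expect_error(variance_percentage(50, -1), "\\[0, 100\\]")
})

test_that("variance percentage sign tracks the observer difference", {
  for (i in 1:50) {
    o1 <- (i * 7) %% 101
    o2 <- (i * 13) %% 101
    vp <- variance_percentage(o1, o2)
    if (o1 > 0) {
      expect_equal(sign(vp), sign(o1 - o2))
    }
  }
})

test_that("truncation toward zero matches the printed rendering", {
  expect_equal(truncate_decimals(97.777, 1), 97.7)
  expect_equal(truncate_decimals(71.58, 1), 71.5)
  expect_equal(truncate_decimals(68.571, 2), 68.57)
  expect_equal(truncate_decimals(-6.666, 1), -6.6)   # toward zero, not down
})

test_that("variance tables compute each observer against the reference", {
  tab <- observer_table(data.frame(nodule_id = 1, P1 = 50, P2 = 25, DSS = 25))
  vt <- variance_table(tab, "DSS")
  expect_equal(vt$P1, 50)
  expect_equal(vt$P2, 0)
  same <- observer_table(data.frame(nodule_id = 1:3, A = c(10, 20, 30),
                                    DSS = c(10, 20, 30)))
  expect_equal(variance_table(same, "DSS")$A, c(0, 0, 0))
  expect_error(variance_table(tab, "missing"), "not found")
})

test_that("composition categories bin with upper-boundary assignment", {
  sch <- composition_scheme()
  expect_equal(as.character(composition_category(0, sch)), "solid")
  expect_equal(as.character(composition_category(100, sch)), "cystic")
  expect_equal(as.character(composition_category(50, sch)), "predominantly cystic")
  expect_equal(as.character(composition_category(10, sch)), "predominantly solid")
  expect_equal(as.character(composition_category(9.99, sch)), "solid")
  expect_error(composition_scheme(c(50, 10)), "increasing")
  expect_error(composition_category(120, sch), "\\[0, 100\\]")
})

test_that("match percentages behave on identical, disjoint and mixed columns", {
  sch <- composition_scheme()
  tab <- observer_table(data.frame(nodule_id = 1:4,
                                   A = c(5, 20, 60, 95),
                                   B = c(5, 20, 60, 95),
                                   DSS = c(95, 60, 20, 5)))
  expect_equal(classification_match_percentage(tab, "A", "B", sch), 100)
  expect_equal(classification_match_percentage(tab, "A", "DSS", sch), 0)
  mixed <- observer_table(data.frame(nodule_id = 1:4,
                                     A = c(5, 20, 60, 95),
                                     DSS = c(7, 60, 55, 95)))
  expect_equal(classification_match_percentage(mixed, "A", "DSS"), 75)
  # 15 of 26 matching rows -> 57.69...
  t26 <- observer_table(data.frame(nodule_id = 1:26,
                                   A = c(rep(5, 15), rep(95, 11)),
                                   DSS = c(rep(5, 15), rep(20, 11))))
  expect_equal(classification_match_percentage(t26, "A", "DSS"), 100 * 15 / 26)
})

test_that("match percentages are row-order invariant and bounded", {
  tab <- load_fixtures()$table2
  sch <- composition_scheme()
  p <- classification_match_percentage(tab, "P1", "DSS", sch)
  shuffled <- observer_table(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(classification_match_percentage(shuffled, "P1", "DSS", sch), p)
  expect_gte(p, 0); expect_lte(p, 100)
})

test_that("the all-observer match reports both readings of the statistic", {
  tab <- observer_table(data.frame(nodule_id = 1:4,
                                   A = c(5, 20, 60, 95),
                                   B = c(5, 20, 60, 95),
                                   DSS = c(5, 20, 60, 95)))
  res <- all_observer_match_percentage(tab, c("A", "B"), "DSS")
  expect_equal(res$all_agree_pct, 100)
  expect_equal(res$mean_pairwise_pct, 100)
  disj <- observer_table(data.frame(nodule_id = 1:4,
                                    A = c(5, 20, 60, 95),
                                    B = c(95, 60, 20, 5),
                                    DSS = c(20, 5, 95, 60)))
  expect_equal(all_observer_match_percentage(disj, c("A", "B"), "DSS")$all_agree_pct, 0)
  # 5 fully-agreeing rows of 26
  t26 <- observer_table(data.frame(
    nodule_id = 1:26,
    A = c(rep(5, 5), rep(95, 21)),
    B = c(rep(5, 5), rep(60, 21)),
    DSS = c(rep(5, 5), rep(20, 21))))
  expect_equal(all_observer_match_percentage(t26, c("A", "B"), "DSS")$all_agree_pct,
               100 * 5 / 26)
})

test_that("the chi-squared test matches the Pearson formula and degenerates safely", {
  # observers with identical category distributions -> statistic 0, p = 1
  tab <- observer_table(data.frame(nodule_id = 1:10,
                                   A = rep(c(5, 95), 5),
                                   B = rep(c(95, 5), 5)))
  res <- chi_squared_variance_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # counts [[10,0],[0,10]] -> uncorrected Pearson statistic 20
  polar <- observer_table(data.frame(nodule_id = 1:10,
                                     A = rep(5, 10),     # all "solid"
                                     B = rep(20, 10)))   # all "predominantly solid"
  res2 <- chi_squared_variance_test(polar)
  expect_equal(res2$statistic, 20)
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$df, 1)

  # single realised category
  flat <- observer_table(data.frame(nodule_id = 1:5, A = rep(5, 5), B = rep(5, 5)))
  expect_warning(res3 <- chi_squared_variance_test(flat), "degenerate")
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
})
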