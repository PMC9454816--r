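test_that("diagnostic accuracy reproduces the study's headline cells", {
  # automated karyometry, modified standard, >4% + aneuploidy rule
  st <- contingency_stats(contingency_table(tp = 18, fp = 1, tn = 66,
                                            fn = 7))
  g <- function(m) st$pct[st$metric == m]
  expect_equal(g("sensitivity"), 72.0)
  expect_equal(g("specificity"), 98.5)
  expect_equal(g("ppv"), 94.7)
  expect_equal(g("npv"), 90.4)
  expect_equal(g("oda"), 91.3)
  # manual cytology, original standard
  cy <- contingency_stats(contingency_table(tp = 16, fp = 18, tn = 54,
                                            fn = 4))
  expect_equal(cy$pct[cy$metric == "sensitivity"], 80.0)
  expect_equal(cy$pct[cy$metric == "specificity"], 75.0)
  expect_equal(cy$pct[cy$metric == "oda"], 76.1)
})

test_that("undefined ratios report as not-applicable, never zero", {
  st <- contingency_stats(contingency_table(tp = 0, fp = 0, tn = 10,
                                            fn = 0))
  expect_equal(st$pct[st$metric == "specificity"], 100)
  expect_equal(st$pct[st$metric == "oda"], 100)
  expect_true(is.na(st$value[st$metric == "sensitivity"]))
  expect_equal(st$fraction[st$metric == "sensitivity"], "n/a")
  expect_true(is.na(st$value[st$metric == "ppv"]))
  expect_error(contingency_table(0, 0, 0, 0), "all zero")
  expect_error(contingency_table(-1, 0, 1, 0), "non-negative")
})

test_that("ODA is exactly (TP+TN)/total for arbitrary tables", {
  set.seed(30)
  for (i in 1:25) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    ct <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    st <- contingency_stats(ct)
    expect_equal(st$value[st$metric == "oda"],
                 (cells[1] + cells[3]) / sum(cells))
  }
})

test_that("the packaged count fixture regenerates every printed accuracy cell", {
  # printed percentages of the published table, by standard/rule/metric
  expected <- rbind(
    data.frame(standard = "original", rule = "single_cell_9cEE",
               sensitivity = 20.0, specificity = 95.8, ppv = 57.1,
               npv = 81.2, oda = 79.3),
    data.frame(standard = "original", rule = "stemline",
               sensitivity = 30.0, specificity = 97.2, ppv = 75.0,
               npv = 83.3, oda = 82.6),
    data.frame(standard = "original", rule = "aneuploidy",
               sensitivity = 35.0, specificity = 94.4, ppv = 63.6,
               npv = 84.0, oda = 81.5),
    data.frame(standard = "original", rule = "abnormal_gt5",
               sensitivity = 50.0, specificity = 93.1, ppv = 66.7,
               npv = 87.0, oda = 83.7),
    data.frame(standard = "original", rule = "abnormal_gt4",
               sensitivity = 60.0, specificity = 91.7, ppv = 66.7,
               npv = 89.2, oda = 84.8),
    data.frame(standard = "original", rule = "aneuploidy_or_gt5",
               sensitivity = 55.0, specificity = 93.1, ppv = 68.8,
               npv = 88.2, oda = 84.8),
    data.frame(standard = "original", rule = "aneuploidy_or_gt4",
               sensitivity = 65.0, specificity = 91.7, ppv = 68.4,
               npv = 90.4, oda = 85.9),
    data.frame(standard = "original", rule = "cytology",
               sensitivity = 80.0, specificity = 75.0, ppv = 47.1,
               npv = 93.1, oda = 76.1),
    data.frame(standard = "modified", rule = "single_cell_9cEE",
               sensitivity = 28.0, specificity = 100, ppv = 100,
               npv = 78.8, oda = 80.4),
    data.frame(standard = "modified", rule = "stemline",
               sensitivity = 32.0, specificity = 100, ppv = 100,
               npv = 79.8, oda = 81.5),
    data.frame(standard = "modified", rule = "aneuploidy",
               sensitivity = 44.0, specificity = 100, ppv = 100,
               npv = 82.7, oda = 84.8),
    data.frame(standard = "modified", rule = "abnormal_gt5",
               sensitivity = 60.0, specificity = 100, ppv = 100,
               npv = 87.0, oda = 89.1),
    data.frame(standard = "modified", rule = "abnormal_gt4",
               sensitivity = 68.0, specificity = 98.5, ppv = 94.4,
               npv = 89.2, oda = 90.2),
    data.frame(standard = "modified", rule = "aneuploidy_or_gt5",
               sensitivity = 64.0, specificity = 100, ppv = 100,
               npv = 88.2, oda = 90.2),
    data.frame(standard = "modified", rule = "aneuploidy_or_gt4",
               sensitivity = 72.0, specificity = 98.5, ppv = 94.7,
               npv = 90.4, oda = 91.3),
    data.frame(standard = "modified", rule = "cytology",
               sensitivity = 72.0, specificity = 76.1, ppv = 52.9,
               npv = 87.9, oda = 75.0)
  )
  for (std in c("original", "modified")) {
    tab <- table1(std)
    exp_std <- expected[expected$standard == std, ]
    for (i in seq_len(nrow(exp_std))) {
      for (m in c("sensitivity", "specificity", "ppv", "npv", "oda")) {
        got <- tab$pct[tab$rule == exp_std$rule[i] & tab$metric == m]
        expect_equal(got, exp_std[[m]][i],
                     info = paste(std, exp_std$rule[i], m))
      }
    }
  }
  # the NPV cell printed as 84% comes out of the same rounding rule
  tab_o <- table1("original")
  expect_equal(tab_o$pct[tab_o$rule == "aneuploidy" & tab_o$metric == "npv"],
               84.0)
})

test_that("rule evaluation is invariant to slide order and checks completeness", {
  set.seed(31)
  n <- 30
  truth <- data.frame(slide_id = sprintf("s%02d", 1:n),
                      truth = rep(c(TRUE, FALSE), c(10, 20)))
  res <- data.frame(slide_id = truth$slide_id,
                    ruleA = truth$truth | runif(n) < 0.1,
                    ruleB = runif(n) < 0.5)
  a <- evaluate_rules(res, truth)
  b <- evaluate_rules(res[sample(n), ], truth[sample(n), ])
  expect_equal(a[order(a$rule, a$metric), ], b[order(b$rule, b$metric), ],
               ignore_attr = TRUE)
  res_na <- res; res_na$ruleA[3] <- NA
  expect_error(evaluate_rules(res_na, truth), "missing a result")
  expect_error(evaluate_rules(res[1:5, -2][, 1, drop = FALSE], truth),
               "no rule columns")
})

test_that("all-negative predictions score the closed-form baseline", {
  truth <- data.frame(slide_id = sprintf("s%02d", 1:92),
                      truth = rep(c(TRUE, FALSE), c(25, 67)))
  res <- data.frame(slide_id = truth$slide_id, never = FALSE)
  st <- evaluate_rules(res, truth)
  expect_equal(st$pct[st$metric == "sensitivity"], 0)
  expect_equal(st$pct[st$metric == "specificity"], 100)
  expect_equal(st$pct[st$metric == "oda"], 72.8) # 67/92
})
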