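test_that("top_k_true counts essentials among the top k", {
  ordering <- c("e1", "n1", "e2", "n2")
  ess <- c("e1", "e2")
  expect_identical(top_k_true(ordering, ess, ks = c(2, 4)),
                   c(`2` = 1L, `4` = 2L))
  expect_identical(unname(top_k_true(ordering, character(0), ks = 1:4)),
                   rep(0L, 4))
  expect_error(top_k_true(ordering, ess, ks = 5), "between 1 and")
})

test_that("confusion counts at a top-fraction cutoff", {
  ordering <- c("e1", "e2", "n1", "n2", "e3", "n3", "e4", "n4", "n5", "n6")
  ess <- c("e1", "e2", "e3", "e4")
  cc <- confusion_at_fraction(ordering, ess, fraction = 0.2)
  expect_equal(cc$cutoff, 2)
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 2, FP = 0, TN = 6, FN = 2))
  expect_error(confusion_at_fraction(ordering, ess, fraction = 1),
               "in \\(0, 1\\)")
  expect_error(confusion_at_fraction(character(0), ess), "empty")
  # all-nonessential set
  cc2 <- confusion_at_fraction(ordering, character(0), fraction = 0.2)
  expect_equal(cc2$TP + cc2$FN, 0)
})

test_that("the six statistics follow their defining ratios", {
  s <- confusion_statistics(list(TP = 2, FP = 0, TN = 6, FN = 2))
  expect_equal(s, c(SN = 0.5, SP = 1, PPV = 1, NPV = 0.75,
                    F = 2 / 3, ACC = 0.8))
  s2 <- confusion_statistics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(unname(s2[c("SN", "PPV", "F", "ACC")]),
               c(0.75, 0.75, 0.75, 0.8))
  expect_error(confusion_statistics(list(TP = 0, FP = 0, TN = 3, FN = 0)),
               "essential")
})

test_that("statistics agree with direct formula evaluation on random rankings", {
  set.seed(555)
  for (trial in 1:20) {
    n <- sample(20:60, 1)
    ids <- sprintf("p%02d", 1:n)
    ess <- sample(ids, sample(2:(n - 2), 1))
    ordering <- sample(ids)
    cc <- confusion_at_fraction(ordering, ess, stats::runif(1, 0.05, 0.95))
    # conservation laws
    expect_equal(cc$TP + cc$FN, length(ess))
    expect_equal(cc$TN + cc$FP, n - length(ess))
    expect_equal(cc$TP + cc$FP, cc$cutoff)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
    st <- confusion_statistics(cc)
    expect_equal(st[["SN"]], cc$TP / (cc$TP + cc$FN))
    expect_equal(st[["SP"]], cc$TN / (cc$TN + cc$FP))
    expect_equal(st[["ACC"]], (cc$TP + cc$TN) / n)
    expect_true(all(st >= 0 & st <= 1))
  }
})

test_that("PR and jackknife curves are consistent with top-k counts", {
  expect_equal(pr_curve(c("e", "n"), "e"),
               data.frame(rank = 1:2, tp = c(1L, 1L),
                          precision = c(1, 0.5), recall = c(1, 1)))
  all_ess <- sprintf("e%d", 1:5)
  expect_true(all(pr_curve(all_ess, all_ess)$precision == 1))
  worst <- c("n1", "n2", "e1")
  expect_equal(pr_curve(worst, "e1")$precision[1], 0)
  expect_error(pr_curve(c("a", "b"), "z"), "no essential")

  expect_equal(jackknife_curve(c("e1", "n1", "e2"), c("e1", "e2"))$tp,
               c(1L, 1L, 2L))
  expect_equal(jackknife_curve(c("n1", "n2"), character(0))$tp, c(0L, 0L))

  set.seed(666)
  for (trial in 1:10) {
    n <- sample(10:40, 1)
    ids <- sprintf("p%02d", 1:n)
    ess <- sample(ids, sample(1:(n - 1), 1))
    ordering <- sample(ids)
    pr <- pr_curve(ordering, ess)
    jk <- jackknife_curve(ordering, ess)
    expect_equal(pr$tp, jk$tp)
    expect_equal(pr$recall * length(ess), as.numeric(jk$tp))
    expect_equal(as.integer(top_k_true(ordering, ess, ks = seq_len(n))),
                 jk$tp)
    expect_true(all(diff(jk$tp) >= 0))
  }
})

test_that("break-even point is the recall where precision last covers it", {
  # precision: 1, 1/2, 2/3, 1/2 ; recall: 1/2, 1/2, 1, 1
  expect_equal(break_even_point(c("e1", "n1", "e2", "n2"),
                                c("e1", "e2")), 0.5)
  # all-essential ranking: precision stays 1, break-even at full recall
  expect_equal(break_even_point(c("e1", "e2"), c("e1", "e2")), 1)
})

test_that("method difference is symmetric and counts essentials in the gaps", {
  ra <- c("a", "b", "c", "d")
  rb <- c("c", "d", "e", "f")
  ess <- c("a", "e")
  d <- method_difference(ra, rb, ess, k = 4)
  expect_equal(d$intersection_size, 2)
  expect_equal(d$essential_in_a_only, 1)
  expect_equal(d$essential_in_b_only, 1)
  dswap <- method_difference(rb, ra, ess, k = 4)
  expect_equal(dswap$a_only, d$b_only)
  expect_equal(dswap$essential_in_a_only, d$essential_in_b_only)

  ident <- method_difference(ra, ra, ess, k = 3)
  expect_equal(ident$intersection_size, 3)
  expect_equal(ident$a_only_size, 0)

  disjoint <- method_difference(c("a", "b"), c("x", "y"), ess, k = 2)
  expect_equal(disjoint$intersection_size, 0)
  expect_error(method_difference(ra, rb, ess, k = 9), "within both")
})

test_that("evaluate_ranking bundles the protocol coherently", {
  set.seed(777)
  n <- 50
  ids <- sprintf("p%02d", 1:n)
  ess <- sample(ids, 15)
  ordering <- sample(ids)
  res <- suppressMessages(evaluate_ranking(ordering, ess, ks = c(10, 20, 100)))
  expect_named(res, c("top_k", "confusion", "statistics", "break_even"))
  expect_identical(names(res$top_k), c("10", "20")) # 100 > n dropped
  expect_equal(res$confusion$cutoff, 10)
  expect_equal(res$statistics,
               confusion_statistics(res$confusion))
})
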