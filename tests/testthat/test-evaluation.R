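mk_lr <- function(scores, essential) {
  labeled_ranking(score_table(scores, "toy"), essential)
}

test_that("labeled_ranking restricts the essential list to the ranked universe", {
  expect_message(
    lr <- mk_lr(c(a = 3, b = 2, c = 1), c("a", "c", "ghost")),
    "1 essential")
  expect_setequal(lr$essential, c("a", "c"))
  expect_equal(lr$n_dropped, 1L)
  expect_equal(lr$labels, c(1L, 0L, 1L))
})

test_that("confusion_at_cutoff does direct set arithmetic", {
  lr <- mk_lr(c(e1 = 4, n1 = 3, e2 = 2, n2 = 1), c("e1", "e2"))
  cc <- confusion_at_cutoff(lr, 2)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  all_in <- confusion_at_cutoff(lr, 4)
  expect_equal(all_in$FP, 2L)
  expect_equal(all_in$FN, 0L)
  expect_error(confusion_at_cutoff(lr, 0), "cutoff")
  expect_error(confusion_at_cutoff(lr, 5), "cutoff")
})

test_that("classification_metrics reproduces hand-evaluated values", {
  m <- classification_metrics(list(TP = 10, FP = 5, TN = 80, FN = 5))
  expect_equal(m, naive_metrics(10, 5, 80, 5))
  expect_equal(unname(m["SN"]), 2 / 3)
  expect_equal(unname(m["ACC"]), 0.9)
  expect_equal(unname(m["MCC"]), 0.6078, tolerance = 1e-4)

  perfect <- classification_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect[c("SN", "SP", "PPV", "ACC", "MCC")]),
               rep(1, 5))
  expect_equal(unname(perfect["FPR"]), 0)
  expect_error(classification_metrics(list(TP = 5, FP = 0, TN = 0, FN = 0)),
               "both classes")
})

test_that("the k = |essential| cutoff forces SN = PPV and SP = NPV", {
  set.seed(21)
  for (rep in 1:20) {
    p <- sample(20:100, 1)
    ids <- sprintf("x%03d", seq_len(p))
    ess <- sample(ids, sample(3:(p - 3), 1))
    lr <- mk_lr(setNames(rnorm(p), ids), ess)
    m <- classification_metrics(confusion_at_cutoff(lr))
    expect_equal(m[["SN"]], m[["PPV"]])
    expect_equal(m[["SP"]], m[["NPV"]])
  }
})

test_that("trapezoidal AUC equals the tie-corrected pairwise statistic", {
  expect_equal(roc_auc(mk_lr(c(a = 2, b = 1), "a"))$auc, 1)
  # all scores identical: single diagonal segment
  tied <- mk_lr(c(a = 1, b = 1, c = 1, d = 1), c("a", "c"))
  r <- roc_auc(tied)
  expect_equal(r$auc, 0.5)
  expect_equal(nrow(r$roc), 2L)
  set.seed(99)
  for (rep in 1:20) {
    n <- 150
    scores <- setNames(sample(seq(0, 1, 0.05), n, TRUE), sprintf("p%03d", 1:n))
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    lr <- mk_lr(scores, names(scores)[labels == 1])
    expect_equal(roc_auc(lr)$auc,
                 mw_auc(unname(lr$scores), lr$labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(mk_lr(c(a = 1, b = 2), character())), "both")
})

test_that("roc points run from (0,0) to (1,1) with monotone coordinates", {
  set.seed(3)
  lr <- mk_lr(setNames(rnorm(50), sprintf("p%02d", 1:50)),
              sprintf("p%02d", sample(50, 15)))
  r <- roc_auc(lr)
  expect_equal(r$roc$FPR[1], 0); expect_equal(r$roc$TPR[1], 0)
  expect_equal(r$roc$FPR[nrow(r$roc)], 1)
  expect_equal(r$roc$TPR[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$FPR) >= 0) && all(diff(r$roc$TPR) >= 0))
})

test_that("roc_auc_top_fraction restricts to the head of the ranking", {
  set.seed(13)
  n <- 100
  scores <- setNames(rnorm(n), sprintf("p%03d", 1:n))
  ess <- names(scores)[rbinom(n, 1, 0.4) == 1]
  lr <- mk_lr(scores, ess)
  expect_equal(roc_auc_top_fraction(lr, 1)$auc, roc_auc(lr)$auc)
  m <- ceiling(0.2 * n)
  keep <- lr$ranking[seq_len(m)]
  expect_equal(roc_auc_top_fraction(lr, 0.2)$auc,
               mw_auc(unname(lr$scores[keep]),
                      as.integer(keep %in% ess)), tolerance = 1e-12)
  # a single-class head is a domain error
  only_ess <- mk_lr(c(a = 5, b = 4, c = 3, d = 2, e = 1, f = 0), c("a", "b"))
  expect_error(roc_auc_top_fraction(only_ess, 0.2), "both")
})

test_that("jackknife curves are prefix sums of the essential indicator", {
  lr <- mk_lr(c(e1 = 3, n1 = 2, e2 = 1), c("e1", "e2"))
  expect_equal(jackknife_curve(lr), c(1, 1, 2))
  all_e <- mk_lr(setNames(5:1, paste0("e", 1:5)), paste0("e", 1:5))
  expect_equal(jackknife_curve(all_e), 1:5)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    ids <- sprintf("p%03d", 1:n)
    lr <- mk_lr(setNames(rnorm(n), ids), sample(ids, sample(2:(n - 2), 1)))
    jk <- jackknife_curve(lr)
    expect_equal(jk, cumsum(lr$labels))
    expect_true(all(diff(jk) %in% c(0L, 1L)))
    expect_equal(jk[n], length(lr$essential))
    # top-percent slices agree with the jackknife values
    tk <- top_percent_counts(lr)
    expect_equal(unname(tk), jk[ceiling(c(1, 5, 10, 15, 20, 25) * n / 100)])
  }
  expect_equal(unname(top_percent_counts(lr, 100)), length(lr$essential))
  expect_error(top_percent_counts(lr, c(0, 5)), "percents")
})

test_that("overlap_analysis does explicit set arithmetic on top-N sets", {
  a <- score_table(c(p1 = 5, p2 = 4, p3 = 3, p4 = 2, p5 = 1), "A")
  b <- score_table(c(p3 = 9, p4 = 8, p5 = 7, p1 = 1, p2 = 0), "B")
  ov <- overlap_analysis(a, b, essential = c("p1", "p4"), top_n = 2)
  expect_equal(ov$intersection, 0L)
  expect_equal(ov$a_only$size, 2L)       # {p1, p2}
  expect_equal(ov$a_only$essential, 1L)  # p1
  expect_equal(ov$a_only$essential_pct, 50)
  expect_equal(ov$b_only$essential, 1L)  # p4 in {p3, p4}
  same <- overlap_analysis(a, a, essential = "p1", top_n = 3)
  expect_equal(same$intersection, 3L)
  expect_true(same$a_only$empty && same$b_only$empty)
  expect_equal(same$a_only$essential_pct, 0)
  mismatched <- score_table(c(q1 = 1, q2 = 0.5, q3 = 0, q4 = -1, q5 = -2), "C")
  expect_error(overlap_analysis(a, mismatched, "p1", 2), "universe")
})

test_that("hand-rolled ROC/AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- setNames(c(rnorm(60, 1), rnorm(140)), sprintf("p%03d", 1:200))
  ess <- sprintf("p%03d", 1:60)
  lr <- mk_lr(scores, ess)
  ref <- pROC::auc(pROC::roc(response = as.integer(names(scores) %in% ess),
                             predictor = unname(scores), quiet = TRUE,
                             direction = "<"))
  expect_equal(roc_auc(lr)$auc, as.numeric(ref), tolerance = 1e-12)
})
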