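test_that("labels follow the strong-tie threshold on the testing window", {
  cs <- contact_stream(c(1, 11, 12, 13, 11),
                       c("a", "a", "a", "a", "c"),
                       c("b", "b", "b", "b", "d"))
  scores <- structure(
    data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
               score = c(0.9, 0.1), stringsAsFactors = FALSE),
    method = "CN", alpha = 1, class = c("score_table", "data.frame"))
  lab2 <- label_candidates(cs, scores, t1 = 10, t2 = 20, S = 2)
  expect_equal(lab2$n_test_contacts, c(3L, 1L))
  expect_equal(lab2$positive, c(TRUE, FALSE))
  lab4 <- label_candidates(cs, scores, t1 = 10, t2 = 20, S = 4)
  expect_equal(lab4$positive, c(FALSE, FALSE))  # 3 contacts < S = 4
  lab1 <- label_candidates(cs, scores, t1 = 10, t2 = 20, S = 1)
  expect_equal(lab1$positive, c(TRUE, TRUE))
  # window is half-open: the contact at t = 1 is training, not testing
  expect_equal(label_candidates(cs, scores, 0.5, 20, S = 4)$positive[1],
               TRUE)
  bad <- scores; bad$node_a[1] <- "zz"
  expect_error(label_candidates(cs, bad, 10, 20), "registry")
})

test_that("confusion counts and precision/recall match hand enumeration", {
  lab <- make_labeled(c(0.9, 0.8, 0.4, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  cm <- confusion(lab, 0.5)
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  pr <- precision_recall(cm)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)

  # threshold at -Inf predicts everything positive; above max, nothing
  low <- confusion(lab, -Inf)
  expect_equal(low$FN + low$TN, 0L)
  hi <- confusion(lab, 1)
  expect_equal(hi$TP + hi$FP, 0L)
  und <- precision_recall(hi)
  expect_equal(und$precision, 0)
  expect_false(und$precision_defined)

  # the predicted-positive rule is score >= threshold
  eq <- confusion(lab, 0.4)
  expect_equal(eq$TP, 2L)

  # brute-force check on a larger random instance
  set.seed(3)
  s <- round(runif(200), 2)
  p <- runif(200) < 0.3
  labr <- make_labeled(s, p)
  for (thr in c(0.2, 0.5, 0.9)) {
    cm <- confusion(labr, thr)
    expect_equal(cm$TP, sum(s >= thr & p))
    expect_equal(cm$TN, sum(s < thr & !p))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 200L)
  }
})

test_that("PR curve enumerates distinct thresholds", {
  lab <- make_labeled(c(0.9, 0.8, 0.4, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  pr <- pr_curve(lab)
  expect_equal(pr$recall[pr$threshold == 0.9], 0.5)
  expect_equal(pr$precision[pr$threshold == 0.9], 1.0)
  expect_equal(pr$recall[pr$threshold == 0.4], 1.0)
  expect_equal(pr$precision[pr$threshold == 0.4], 2 / 3, tolerance = 1e-12)

  sep <- make_labeled(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  prs <- pr_curve(sep)
  expect_true(any(prs$recall == 1 & prs$precision == 1))

  tie <- make_labeled(rep(1, 10), rep(c(TRUE, FALSE), 5))
  prt <- pr_curve(tie)
  expect_equal(nrow(prt), 1L)
  expect_equal(prt$recall, 1)
  expect_equal(prt$precision, 0.5)  # prevalence

  expect_error(pr_curve(make_labeled(c(1, 2), c(FALSE, FALSE))),
               "no positive")
})

test_that("AUC equals the positive-beats-negative probability with ties half", {
  lab <- make_labeled(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(lab)$auc, 0.75)  # 3 of 4 pos-neg pairs ordered
  perfect <- make_labeled(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(roc_auc(perfect)$auc, 1)
  ties <- make_labeled(rep(3, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(roc_auc(ties)$auc, 0.5)
  expect_error(roc_auc(make_labeled(1:3, c(TRUE, TRUE, TRUE))),
               "positive and one negative")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  for (rep in 1:20) {
    s <- runif(60)
    p <- runif(60) < 0.4
    if (!any(p) || all(p)) next
    base <- roc_auc(make_labeled(s, p))$auc
    expect_equal(roc_auc(make_labeled(2 * s + 1, p))$auc, base)
    expect_equal(roc_auc(make_labeled(s^3, p))$auc, base)
  }
})

test_that("eval_result reports an operating point and a valid ROC", {
  lab <- make_labeled(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  ev <- roc_auc(lab, threshold = 0.5)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  expect_true(all(diff(ev$roc$fpr) >= 0), all(diff(ev$roc$tpr) >= 0))
})

test_that("DeLong self-comparison and symmetric swaps are null results", {
  set.seed(13)
  lab <- make_labeled(runif(100), runif(100) < 0.4)
  self <- delong_test(lab, lab)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)

  # swapping the two halves of the score pattern preserves the AUC
  p <- c(TRUE, FALSE, TRUE, FALSE)
  a <- make_labeled(c(4, 3, 2, 1), p)
  b <- make_labeled(c(2, 1, 4, 3), p)
  dl <- delong_test(a, b)
  expect_equal(dl$auc_a, dl$auc_b)
  expect_equal(dl$z, 0)

  mismatch <- make_labeled(runif(50), runif(50) < 0.4)
  expect_error(delong_test(lab, mismatch), "same pairs")
})

test_that("DeLong agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  sig <- rnorm(300)
  p <- sig + rnorm(300) > 0.3
  if (!any(p) || all(p)) p[1:2] <- c(TRUE, FALSE)
  sa <- sig + rnorm(300, sd = 0.8)
  sb <- sig + rnorm(300, sd = 1.2)
  la <- make_labeled(sa, p)
  lb <- make_labeled(sb, p)
  ours <- delong_test(la, lb)
  ref <- pROC::roc.test(
    pROC::roc(p, sa, quiet = TRUE, direction = "<"),
    pROC::roc(p, sb, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(ours$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-8)
})
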