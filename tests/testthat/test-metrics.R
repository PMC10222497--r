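test_that("confusion counts match brute-force enumeration", {
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), c(0L, 0L, 1L, 1L))
  obs <- c(1, 1, 0, 0)
  cc <- confusion_counts(obs, obs)
  expect_identical(c(cc$fp, cc$fn), c(0L, 0L))
  set.seed(14)
  o <- sample(0:1, 50, replace = TRUE)
  p <- sample(0:1, 50, replace = TRUE)
  brute <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in 1:50) {
    cell <- if (o[i] == 1 && p[i] == 1) "tp" else
      if (o[i] == 0 && p[i] == 0) "tn" else
        if (o[i] == 0 && p[i] == 1) "fp" else "fn"
    brute[cell] <- brute[cell] + 1L
  }
  cc <- confusion_counts(o, p)
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]), brute)
  expect_error(confusion_counts(0:1, 0), "length mismatch")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("classification statistics handle perfect and degenerate tables", {
  st <- classification_stats(list(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_equal(unlist(st[1:4]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, mcc = 1))
  # no observed positives: sensitivity undefined, MCC 0 by convention
  st <- classification_stats(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(st$sensitivity))
  expect_identical(st$mcc, 0)
  expect_setequal(st$degenerate, c("sensitivity", "mcc"))
})

test_that("statistics reproduce a published-style confusion table at 4 d.p.", {
  rows <- list(
    list(cc = list(tp = 119, tn = 99, fp = 49, fn = 47),
         # accuracy is forced by the counts: (119+99)/314 = 0.6943
         want = c(0.7169, 0.6689, 0.6943, 0.3861)),
    list(cc = list(tp = 123, tn = 101, fp = 32, fn = 63),
         want = c(0.6613, 0.7594, 0.7022, 0.4150)),
    list(cc = list(tp = 160, tn = 100, fp = 28, fn = 31),
         # specificity 100/128 = 0.78125 must round half-up to 0.7813
         want = c(0.8377, 0.7813, 0.8150, 0.6167)),
    list(cc = list(tp = 181, tn = 86, fp = 20, fn = 35),
         want = c(0.8380, 0.8113, 0.8292, 0.6300)),
    list(cc = list(tp = 583, tn = 386, fp = 129, fn = 176),
         want = c(0.7681, 0.7495, 0.7606, 0.5116)))
  for (r in rows) {
    st <- classification_stats(r$cc)
    got <- semicor:::round_half_up(
      c(st$sensitivity, st$specificity, st$accuracy, st$mcc), 4)
    expect_equal(got, r$want, tolerance = 1e-12)
  }
})

test_that("label swap preserves MCC/accuracy and swaps sensitivity/specificity", {
  set.seed(4)
  for (i in 1:20) {
    o <- sample(0:1, 40, replace = TRUE)
    p <- sample(0:1, 40, replace = TRUE)
    a <- classification_stats(confusion_counts(o, p))
    b <- classification_stats(confusion_counts(1 - o, 1 - p))
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
    expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
    expect_equal(a$sensitivity, b$specificity, tolerance = 1e-12)
    expect_equal(a$specificity, b$sensitivity, tolerance = 1e-12)
  }
})

test_that("MCC agrees with the phi coefficient on 1000 random tables", {
  # independent route: MCC of binary vectors is their Pearson correlation
  set.seed(77)
  checked <- 0
  while (checked < 1000) {
    n <- sample(4:60, 1)
    o <- sample(0:1, n, replace = TRUE)
    p <- sample(0:1, n, replace = TRUE)
    if (length(unique(o)) < 2 || length(unique(p)) < 2) next
    expect_equal(mcc_score(o, p), stats::cor(o, p), tolerance = 1e-12)
    expect_lte(abs(mcc_score(o, p)), 1)
    checked <- checked + 1
  }
})

test_that("classification_report mirrors the per-set table layout", {
  obs <- c(1, 0, 1, 1, 0, 0, 1, 0)
  pred <- c(1, 0, 0, 1, 1, 0, 1, 0)
  set <- rep(c("active_training", "validation"), each = 4)
  rep_ <- classification_report(obs, pred, set,
                                set_order = c("active_training",
                                              "validation"))
  expect_identical(names(rep_),
                   c("Set", "TP", "TN", "FP", "FN", "N", "Sensitivity",
                     "Specificity", "Accuracy", "MCC"))
  expect_identical(rep_$Set, c("active_training", "validation", "Total"))
  expect_identical(rep_$N, c(4L, 4L, 8L))
  expect_identical(rep_$TP[3], rep_$TP[1] + rep_$TP[2])
})
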