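test_that("confusion counts match a brute-force per-frame tally", {
  truth <- list(c("Motor", "Environment"), "Motor", character(0))
  preds <- list("Motor", character(0), "Motor")
  cc <- confusion_counts(preds, truth, "Motor")
  expect_identical(cc, c(TP = 1L, TN = 0L, FP = 1L, FN = 1L))

  # identical predictions: no errors at all
  cc2 <- confusion_counts(truth, truth, "Motor")
  expect_identical(cc2[["FP"]] + cc2[["FN"]], 0L)

  withr::with_seed(21, {
    truth <- random_label_sets(1000)
    preds <- random_label_sets(1000)
    for (lab in c("Forceps", "Environment", "Scissors")) {
      cc <- confusion_counts(preds, truth, lab)
      brute <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
      for (i in 1:1000) {
        a <- lab %in% truth[[i]]; p <- lab %in% preds[[i]]
        k <- if (a && p) "TP" else if (!a && !p) "TN"
             else if (p) "FP" else "FN"
        brute[k] <- brute[k] + 1L
      }
      expect_identical(cc, brute)
      # partition invariants
      expect_identical(cc[["TP"]] + cc[["FN"]],
                       sum(vapply(truth, function(s) lab %in% s, logical(1))))
    }
  })
  expect_error(confusion_counts(preds[1:2], truth, "Motor"), "length")
})

test_that("precision and recall follow their defining ratios", {
  expect_equal(metric_precision(c(TP = 3, TN = 0, FP = 1, FN = 0)), 75)
  expect_equal(metric_precision(c(TP = 0, TN = 0, FP = 4, FN = 0)), 0)
  expect_equal(metric_precision(c(TP = 5, TN = 0, FP = 0, FN = 2)), 100)
  expect_equal(metric_recall(c(TP = 3, TN = 0, FP = 0, FN = 1)), 75)
  # zero denominators are not-applicable, never silently 0 or 100
  expect_true(is.na(metric_precision(c(TP = 0, TN = 9, FP = 0, FN = 1))))
  expect_true(is.na(metric_recall(c(TP = 0, TN = 9, FP = 1, FN = 0))))
})

test_that("F1 reproduces the reference worked examples", {
  expect_equal(f1_from_pr(72.5, 100), 84.1)   # motor, from-scratch model
  expect_equal(f1_from_pr(96.4, 100), 98.2)   # scalpel, VGG16 transfer
  expect_equal(f1_from_pr(100, 100), 100)
  expect_true(is.na(f1_from_pr(0, 0)))
  expect_equal(f1_from_pr(72.5, 100, digits = NULL), 2 * 72.5 * 100 / 172.5)
})

test_that("F1 lies between min and max of precision and recall", {
  withr::with_seed(31, {
    for (i in 1:200) {
      p <- runif(1, 0, 100); r <- runif(1, 0, 100)
      if (p + r == 0) next
      f1 <- f1_from_pr(p, r, digits = NULL)
      expect_gte(f1, min(p, r) - 1e-9)
      expect_lte(f1, max(p, r) + 1e-9)
    }
  })
})

test_that("exact-match accuracy requires the full label set to agree", {
  truth <- c(rep(list(c("Motor", "Environment")), 9), list("Motor"))
  preds <- c(rep(list(c("Motor", "Environment")), 9),
             list(c("Motor", "Environment")))
  expect_equal(exact_match_accuracy(preds, truth), 90)

  # an extra predicted tool spoils the frame even with 3 correct labels
  truth1 <- list(c("Forceps", "Scalpel", "Motor"))
  pred1 <- list(c("Forceps", "Scalpel", "Motor", "Pointer"))
  expect_equal(exact_match_accuracy(pred1, truth1), 0)
  expect_error(exact_match_accuracy(list(), list()), "no frames")

  withr::with_seed(41, {
    truth <- random_label_sets(500)
    preds <- random_label_sets(500)
    brute <- mean(vapply(1:500, function(i)
      setequal(truth[[i]], preds[[i]]), logical(1))) * 100
    expect_equal(exact_match_accuracy(preds, truth), brute)
  })
})

test_that("frame exact-match never exceeds any per-label accuracy", {
  withr::with_seed(51, {
    truth <- random_label_sets(400)
    preds <- lapply(truth, function(s) {
      if (runif(1) < 0.3) random_label_sets(1)[[1]] else s
    })
    em <- exact_match_accuracy(preds, truth)
    for (lab in tool_labels()) {
      acc <- metric_accuracy(confusion_counts(preds, truth, lab))
      expect_lte(em, acc + 1e-9)
    }
  })
})

test_that("per-tool confusion percentages partition to 100/100", {
  expect_equal(table4_percentages(c(TP = 40, TN = 360, FP = 0, FN = 0)),
               c(TP = 100, TN = 100, FP = 0, FN = 0))
  # row shape as printed for a near-perfect tool: (100, 99, 1, 0)
  t4 <- table4_percentages(c(TP = 50, TN = 99, FP = 1, FN = 0))
  expect_equal(unname(t4), c(100, 99, 1, 0))
  withr::with_seed(61, {
    for (i in 1:100) {
      cc <- c(TP = rpois(1, 20) + 1, TN = rpois(1, 50) + 1,
              FP = rpois(1, 3), FN = rpois(1, 3))
      t4 <- table4_percentages(cc)
      expect_equal(t4[["TP"]] + t4[["FN"]], 100)
      expect_equal(t4[["TN"]] + t4[["FP"]], 100)
      expect_equal(t4[["TP"]], 100 * cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]))
    }
  })
  expect_true(all(is.na(
    table4_percentages(c(TP = 0, TN = 5, FP = 0, FN = 0))[c("TP", "FN")])))
})

test_that("column averages reproduce the reference Average-row cells", {
  expect_equal(column_average(c(100, 100, 95.8, 72.5, 100, 94.5, 100, 100, 100)),
               95.9)  # from-scratch model precision column
  expect_equal(column_average(c(rep(100, 8), 98.5)), 99.8)  # MobileNetV2
  expect_equal(column_average(rep(87.3, 5)), 87.3)
  expect_error(column_average(numeric(0)), "empty")
  expect_error(column_average(c(90, NA)), "not-applicable")
  expect_equal(column_average(c(90, NA), na_rm = TRUE), 90)
})

test_that("metric reports tabulate nine tools plus an Average row", {
  withr::with_seed(71, {
    truth <- random_label_sets(300)
    preds <- lapply(truth, function(s) {
      if (runif(1) < 0.2) unique(c(s, "Motor")) else s
    })
  })
  rep <- metric_report(preds, truth)
  expect_identical(nrow(rep), 10L)
  expect_identical(rep$tool,
                   c(setdiff(tool_labels(), "Environment"), "Average"))
  expect_false("Environment" %in% rep$tool)
  expect_true(all(rep$precision >= 0 & rep$precision <= 100, na.rm = TRUE))
  em <- attr(rep, "exact_match")
  expect_true(em >= 0 && em <= 100)
  expect_equal(em, exact_match_accuracy(preds, truth))
  # serialisation
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, csv = csv, json = json)
  back <- utils::read.csv(csv)
  expect_identical(nrow(back), 10L)
  js <- jsonlite::read_json(json)
  expect_equal(js$exact_match, em)
})
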