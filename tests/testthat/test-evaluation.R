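test_that("per-class accuracy divides correct predictions by class counts", {
  labels <- c("alive", "alive", "necroptosis", "apoptosis")
  preds <- c("alive", "necroptosis", "necroptosis", "apoptosis")
  acc <- per_class_accuracy(labels, preds)
  expect_equal(acc$accuracy[acc$class == "alive"], 0.5)
  expect_equal(acc$accuracy[acc$class == "apoptosis"], 1.0)
  expect_equal(acc$accuracy[acc$class == "necroptosis"], 1.0)
  # all correct
  expect_equal(per_class_accuracy(labels, labels)$accuracy, rep(1, 3))
  # absent class is NA, not zero
  two <- per_class_accuracy(c("alive", "apoptosis"), c("alive", "alive"))
  expect_true(is.na(two$accuracy[two$class == "necroptosis"]))
  expect_error(per_class_accuracy(character(0), character(0)), "Empty")
  expect_error(per_class_accuracy(labels, preds[1:2]), "length")
})

test_that("ROC/AUC matches hand-computed and degenerate cases", {
  # perfectly separating scores
  expect_equal(roc_ovr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  # tie case: pairs (1+0.5+1+1)/4 = 0.875
  r <- roc_ovr(c(0.9, 0.8, 0.8, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.875)
  # curve anchored at (0,0) and (1,1)
  expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  # single-class labels are undefined
  expect_error(roc_ovr(c(0.1, 0.2), c(1, 1)),
               class = "phasedeath_degenerate_labels")
})

test_that("trapezoidal AUC equals brute-force pair counting with ties", {
  withr::with_seed(19, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      # coarse scores force plenty of ties
      scores <- round(runif(n), sample(1:2, 1))
      expect_equal(roc_ovr(scores, labels)$auc, oracle_auc(scores, labels),
                   tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    labels <- rbinom(300, 1, 0.4)
    scores <- runif(300) + 0.4 * labels
    expect_equal(
      roc_ovr(scores, labels)$auc,
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     direction = "<"))),
      tolerance = 1e-9
    )
  })
})

fake_predictions <- function(truth, probs) {
  tibble::tibble(
    crop_id = as.character(seq_along(truth)),
    p_alive = probs[, 1], p_apoptosis = probs[, 2],
    p_necroptosis = probs[, 3],
    .pred_class = factor(class_order()[max.col(probs, ties.method = "first")],
                         levels = class_order())
  )
}

test_that("a perfect predictor yields a diagonal confusion and unit AUCs", {
  truth <- rep(class_order(), each = 10)
  probs <- t(vapply(truth, function(cl) {
    p <- c(0.05, 0.05, 0.05); p[match(cl, class_order())] <- 0.9; p
  }, numeric(3)))
  report <- build_report(fake_predictions(truth, probs), truth)
  expect_equal(unname(diag(report$confusion)), rep(10L, 3))
  expect_equal(sum(report$confusion) - sum(diag(report$confusion)), 0L)
  expect_equal(unname(report$auc), rep(1, 3))
  expect_equal(tidy(report)$accuracy, rep(1, 3))
  expect_equal(glance(report)$overall_accuracy, 1)
})

test_that("confusion rows conserve class counts on arbitrary predictions", {
  withr::with_seed(31, {
    truth <- sample(class_order(), 200, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    probs <- matrix(runif(600), 200, 3)
    probs <- probs / rowSums(probs)
    report <- build_report(fake_predictions(truth, probs), truth)
    expect_equal(unname(rowSums(report$confusion)),
                 unname(as.integer(table(factor(truth,
                                                levels = class_order())))))
    expect_identical(sum(report$confusion), 200L)
    # a uniform-random scorer hovers at chance AUC
    expect_true(all(abs(report$auc - 0.5) < 0.15))
  })
})

test_that("relabeling the classes permutes the report consistently", {
  withr::with_seed(37, {
    truth <- sample(class_order(), 150, replace = TRUE)
    probs <- matrix(runif(450), 150, 3) + 0.5 *
      t(vapply(truth, function(cl) class_order() == cl, logical(3)))
    probs <- probs / rowSums(probs)
    rep1 <- build_report(fake_predictions(truth, probs), truth)

    perm <- c(2L, 3L, 1L) # apoptosis, necroptosis, alive
    map <- stats::setNames(class_order()[perm], class_order())
    truth2 <- unname(map[truth])
    probs2 <- probs
    preds2 <- fake_predictions(truth, probs) # then relabel consistently
    relabeled <- tibble::tibble(
      crop_id = preds2$crop_id,
      p_alive = probs[, match("alive", map)],
      p_apoptosis = probs[, match("apoptosis", map)],
      p_necroptosis = probs[, match("necroptosis", map)],
      .pred_class = factor(unname(map[as.character(preds2$.pred_class)]),
                           levels = class_order())
    )
    rep2 <- build_report(relabeled, truth2)
    for (cl in class_order()) {
      expect_equal(rep2$auc[[unname(map[cl])]], rep1$auc[[cl]])
      expect_equal(
        tidy(rep2)$accuracy[tidy(rep2)$class == unname(map[cl])],
        tidy(rep1)$accuracy[tidy(rep1)$class == cl]
      )
    }
  })
})

test_that("misaligned or incomplete report inputs are rejected", {
  truth <- rep(class_order(), each = 5)
  probs <- matrix(1 / 3, 15, 3)
  expect_error(build_report(fake_predictions(truth, probs), truth[1:10]),
               "aligned")
  expect_error(build_report(fake_predictions(truth, probs),
                            rep("alive", 15)),
               "represented")
})

test_that("report serialization and plotting round out the surface", {
  truth <- rep(class_order(), each = 8)
  probs <- matrix(runif(72), 24, 3); probs <- probs / rowSums(probs)
  report <- build_report(fake_predictions(truth, probs), truth)
  dir <- withr::local_tempdir()
  write_eval_report(report, dir)
  expect_true(file.exists(file.path(dir, "eval_report.json")))
  back <- jsonlite::read_json(file.path(dir, "eval_report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, report$overall_accuracy)
  p <- autoplot(report)
  expect_s3_class(p, "ggplot")
})
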