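test_that("metrics match a hand-computed contingency exactly", {
  rep0 <- compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  pc <- rep0$per_class
  expect_equal(pc$precision[pc$class == "A"], 1)
  expect_equal(pc$recall[pc$class == "A"], 0.5)
  expect_equal(pc$f1[pc$class == "A"], 2 / 3, tolerance = 1e-12)
  expect_equal(pc$precision[pc$class == "B"], 2 / 3, tolerance = 1e-12)
  expect_equal(pc$recall[pc$class == "B"], 1)
  expect_equal(pc$f1[pc$class == "B"], 0.8)
  expect_equal(rep0$weighted_avg[["f1"]], (2 * (2 / 3) + 2 * 0.8) / 4,
               tolerance = 1e-12)
  expect_equal(rep0$n_eval, 4L)

  perfect <- compute_metrics(c("A", "B"), c("A", "B"))
  expect_equal(unname(perfect$weighted_avg), c(1, 1, 1))
  expect_equal(perfect$accuracy, 1)

  expect_error(compute_metrics("A", c("A", "B")), "equal length")
  expect_error(compute_metrics(c("A", "Z"), c("A", "A"), class_set = "A"),
               "outside class_set")
})

test_that("degenerate classes report zero metrics with support zero", {
  expect_warning(
    r <- compute_metrics(c("A", "A"), c("A", "A"), class_set = c("A", "B")),
    "zero denominator"
  )
  b <- r$per_class[r$per_class$class == "B", ]
  expect_equal(c(b$precision, b$recall, b$f1, b$support), c(0, 0, 0, 0))
})

test_that("weighted averages are support-weighted and recall matches accuracy", {
  classes <- c("A", "B", "C")
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- sample(20:60, 1)
      gold <- sample(classes, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      gold[1:3] <- classes  # ensure every class occurs
      pred <- ifelse(stats::runif(n) < 0.7, gold,
                     sample(classes, n, replace = TRUE))
      r <- quiet_metrics(gold, pred, classes)
      pc <- r$per_class
      w <- pc$support / sum(pc$support)
      expect_equal(r$weighted_avg[["f1"]], sum(w * pc$f1), tolerance = 1e-9)
      expect_equal(r$weighted_avg[["precision"]], sum(w * pc$precision),
                   tolerance = 1e-9)
      expect_equal(r$macro_avg[["f1"]], mean(pc$f1), tolerance = 1e-9)
      expect_equal(sum(pc$support), r$n_eval)
      # single-label task, predictions within the class set:
      # support-weighted recall is micro recall is accuracy
      expect_equal(r$weighted_avg[["recall"]], r$accuracy, tolerance = 1e-9)
    }
  })
})

test_that("seed averaging is the metric-wise arithmetic mean", {
  r1 <- compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  r2 <- compute_metrics(c("A", "A", "B", "B"), c("A", "A", "B", "B"))
  r3 <- compute_metrics(c("A", "A", "B", "B"), c("B", "A", "B", "B"))
  expect_equal(average_over_seeds(list(r1, r1, r1))$weighted_avg,
               r1$weighted_avg)
  avg <- average_over_seeds(list(r1, r2, r3))
  expect_equal(avg$weighted_avg[["f1"]],
               mean(c(r1$weighted_avg[["f1"]], r2$weighted_avg[["f1"]],
                      r3$weighted_avg[["f1"]])), tolerance = 1e-12)
  expect_equal(avg$per_class$recall,
               (r1$per_class$recall + r2$per_class$recall +
                  r3$per_class$recall) / 3)
  bad <- compute_metrics(c("X", "Y"), c("X", "Y"))
  expect_error(average_over_seeds(list(r1, bad)), "mismatched class sets")
})

test_that("train/validation splits are seeded, disjoint and exhaustive", {
  d <- tibble::tibble(id = 1:100)
  s <- split_train_eval(d, 0.9, seed = 24)
  expect_equal(nrow(s$train), 90L)
  expect_equal(nrow(s$eval), 10L)
  expect_length(intersect(s$train$id, s$eval$id), 0L)
  expect_setequal(c(s$train$id, s$eval$id), d$id)
  s2 <- split_train_eval(d, 0.9, seed = 24)
  expect_identical(s$train$id, s2$train$id)
  big <- tibble::tibble(id = 1:1000)
  expect_false(identical(split_train_eval(big, 0.9, 24)$train$id,
                         split_train_eval(big, 0.9, 48)$train$id))
  expect_error(split_train_eval(d[1:5, , drop = FALSE], 0.9, 1), "at least 10")
})

test_that("GSC evaluation ranks models and enforces disjointness", {
  lx <- default_lexicon("activity", "extended")
  gsc <- make_gsc_standin("activity", n = 120, seed = 14)
  ev <- evaluate_on_gsc(list(rule_based = rule_classifier(lx)), gsc,
                        class_set = task_classes("activity"))
  # clean in-lexicon stand-in: the rule labeler is the oracle
  expect_equal(unname(ev$reports$rule_based$weighted_avg), c(1, 1, 1))
  expect_true(all(ev$table$best_f1))
  expect_error(
    evaluate_on_gsc(list(rule_based = rule_classifier(lx)), gsc,
                    train_texts = gsc$text[1]),
    "overlap"
  )
  md <- report_markdown(ev$table)
  expect_match(md, "\\| Model \\|")
  expect_match(md, "rule_based")
})
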