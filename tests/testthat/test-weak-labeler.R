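test_that("keyword scanning reports half-open spans with longest-match shadowing", {
  lx <- default_lexicon("diet", "extended")
  m <- scan_keywords(tokenize_text("he had token high calorie diet for 2 weeks"), lx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$class, "high_calorie_diet")
  expect_equal(c(m$start, m$end), c(3L, 6L))

  # "normal diet" shadows the bare "normal" at the same start
  m2 <- scan_keywords(tokenize_text("she backs to normal diet"), lx)
  expect_equal(m2$phrase, "normal diet")
  expect_equal(c(m2$start, m2$end), c(3L, 5L))

  expect_equal(nrow(scan_keywords(tokenize_text("no relevant content here"), lx)), 0L)
})

test_that("the pre-match window is capped at window_size and the sentence start", {
  toks <- paste0("t", 0:9)
  expect_equal(window_before(toks, 7L, 5L), paste0("t", 2:6))
  expect_equal(window_before(toks, 2L, 5L), c("t0", "t1"))
  expect_equal(window_before(toks, 0L, 5L), character(0))
  expect_error(window_before(toks, 11L, 5L))
})

test_that("negation detection is window-token membership", {
  negs <- default_lexicon("activity")$negation_terms
  expect_true(detect_negation(c("didnt", "maintain", "daily"), negs))
  expect_false(detect_negation(character(0), negs))
  expect_false(detect_negation(c("has", "increase", "regular"), negs))
})

test_that("activity labels follow the opposite-class negation rule", {
  lx <- default_lexicon("activity", "extended")
  lab <- function(tx) classify_sentence(tx, lx)
  expect_equal(lab("pt has increase regular physical activity")$label,
               "physical_activity")
  r <- lab("he didnt maintain daily exercise")
  expect_equal(r$label, "physical_inactivity")
  expect_equal(r$code, -1L)
  expect_true(r$negated)
  expect_equal(lab("patient reports weight gain")$label, "NONE")
  expect_equal(lab("patient reports weight gain")$code, 0L)
  # negated inactivity keyword flips to the activity class and back
  expect_equal(lab("she has been inactive lately")$label, "physical_inactivity")
  expect_equal(lab("she has not been inactive lately")$label, "physical_activity")
})

test_that("diet labels follow the high-X / normal-family coding rules", {
  lx <- default_lexicon("diet", "extended")
  lab <- function(tx) classify_sentence(tx, lx)
  expect_equal(lab("he had token high calorie diet for 2 weeks")$label,
               "high_calorie_diet")
  expect_equal(lab("she backs to normal diet")$label, "normal_diet")
  r <- lab("she has no knowledge of salt restrictions")
  expect_equal(r$label, "nonspecific_abnormal")
  expect_equal(r$code, -1L)
  p <- lab("patient can resume normal diet")
  expect_equal(p$label, "nonspecific_abnormal")
  expect_equal(p$code, 4L)
  expect_true(p$prospective)
  # negated high-X is voided (code 0), not reassigned
  expect_equal(lab("patient does not eat a high fat diet")$label, "NONE")
  expect_equal(lab("patient does not eat a high fat diet")$code, 0L)
  # negation takes precedence over a prospective trigger in the same window
  expect_equal(lab("she can not resume normal diet")$code, -1L)
})

test_that("match selection is leftmost, then longest, then class priority", {
  lx <- default_lexicon("activity", "extended")
  expect_equal(classify_sentence("pt inactive and activity improving", lx)$label,
               "physical_inactivity")  # leftmost wins
  # same start, same length: fixed priority (inactivity over activity)
  tie <- lexicon("activity",
                 list(physical_activity = "training",
                      physical_inactivity = "training"),
                 negation_terms = "not")
  expect_equal(classify_sentence("pt likes training", tie)$label,
               "physical_inactivity")
})

test_that("corpus labeling emits one label per sentence and logs exclusions", {
  lx <- default_lexicon("activity", "extended")
  sents <- tibble::tibble(
    sentence_id = paste0("s", 1:3),
    text = c("pt has daily activity", "no keywords at all",
             "he didnt maintain daily exercise")
  )
  out <- label_corpus(sents, lx)
  expect_equal(nrow(out$labels), 2L)
  expect_equal(nrow(out$excluded), 1L)
  expect_equal(out$excluded$sentence_id, "s2")
  expect_setequal(c(out$labels$sentence_id, out$excluded$sentence_id),
                  sents$sentence_id)

  # byte-identical label files on repeated runs
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(label_corpus(sents, lx)$labels, p1)
  write_jsonl(label_corpus(sents, lx)$labels, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the worked example sentences get their reference classes", {
  for (task in c("activity", "diet")) {
    ex <- normalized_examples(task)
    lx <- default_lexicon(task, "extended")
    got <- vapply(ex$text, function(tx) classify_sentence(tx, lx)$label, "",
                  USE.NAMES = FALSE)
    expect_equal(got, ex$expected_label)
  }
})
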