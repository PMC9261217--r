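test_that("generator config validates mixtures and fractions", {
  expect_error(generator_config("activity", 10,
                                class_mixture = c(physical_activity = 0.8,
                                                  physical_inactivity = 0.1)),
               "summing to 1")
  expect_error(generator_config("activity", 10, negated_fraction = 1.2),
               "fractions")
  expect_equal(nrow(generate_corpus(generator_config("diet", 0))), 0L)
})

test_that("generation is a pure function of the seed", {
  cfg <- generator_config("diet", 150, seed = 99,
                          out_of_lexicon_fraction = 0.3)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  c2 <- generate_corpus(generator_config("diet", 150, seed = 100,
                                         out_of_lexicon_fraction = 0.3))
  expect_false(identical(a$text, c2$text))
})

test_that("class frequencies track the mixture within binomial tolerance", {
  n <- 1000
  corp <- generate_corpus(generator_config("activity", n, seed = 11))
  k <- sum(corp$gold_label == "physical_activity")
  expect_lt(abs(k - n * 0.957), 3 * sqrt(n * 0.957 * 0.043))
  # sentences satisfy the preprocessing invariants
  expect_identical(corp$text, normalize_text(corp$text))
})

test_that("trace distances equal realised token distances", {
  negs <- c("no", "not", "never", "denies", "didnt", "doesnt", "without")
  for (task in c("activity", "diet")) {
    corp <- generate_corpus(generator_config(task, 300, seed = 5,
                                             negated_fraction = 0.6))
    neg_rows <- which(corp$negated)
    expect_gt(length(neg_rows), 30)
    for (i in neg_rows) {
      toks <- tokenize_text(corp$text[i])
      neg_pos <- which(toks %in% negs)[1] - 1L           # 0-based
      kw_start <- scan_keywords(toks, default_lexicon(task, "extended"))$start[1]
      expect_equal(kw_start - neg_pos, corp$neg_distance[i])
    }
  }
})

test_that("label noise flips at the configured binomial rate", {
  corp <- generate_corpus(generator_config("activity", 200, seed = 3))
  clean <- derive_weak_labels(corp, epsilon = 0, seed = 1)
  expect_identical(clean$weak_label, clean$gold_label)
  flipped <- derive_weak_labels(corp, epsilon = 1, seed = 1)
  # binary task: epsilon = 1 deterministically yields the opposite class
  expect_true(all(flipped$weak_label != flipped$gold_label))

  big <- generate_corpus(generator_config("activity", 10000, seed = 4))
  noisy <- derive_weak_labels(big, epsilon = 0.1, seed = 2)
  rate <- mean(noisy$weak_label != noisy$gold_label)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("the GSC stand-in honours exact class counts and template disjointness", {
  gsc <- make_gsc_standin("activity", class_counts = c(physical_activity = 78,
                                                       physical_inactivity = 122),
                          seed = 8)
  expect_equal(nrow(gsc), 200L)
  expect_equal(as.vector(table(gsc$gold_label)[c("physical_activity",
                                                 "physical_inactivity")]),
               c(78L, 122L))
  gsc_d <- make_gsc_standin("diet",
                            class_counts = c(high_calorie_diet = 18,
                                             high_fat_diet = 20,
                                             high_salt_diet = 20,
                                             normal_diet = 18,
                                             nonspecific_abnormal = 12),
                            seed = 8)
  expect_equal(nrow(gsc_d), 88L)

  train <- generate_corpus(generator_config("activity", 300, seed = 8))
  expect_length(intersect(unique(train$template_id), unique(gsc$template_id)), 0L)
  expect_length(intersect(train$note_id, gsc$note_id), 0L)
})

test_that("clean in-lexicon corpora are labeled exactly as their traces say", {
  for (task in c("activity", "diet")) {
    corp <- generate_corpus(generator_config(task, 300, seed = 21))
    for (profile in c("extended", "strict")) {
      lx <- default_lexicon(task, profile)
      got <- vapply(corp$text, function(tx) classify_sentence(tx, lx)$label,
                    "", USE.NAMES = FALSE)
      expect_identical(got, weak_label_oracle(corp))
    }
  }
})

test_that("out-of-lexicon paraphrases are missed by the strict rules", {
  for (task in c("activity", "diet")) {
    corp <- generate_corpus(generator_config(task, 300, seed = 31,
                                             out_of_lexicon_fraction = 0.5))
    expect_gt(sum(corp$out_of_lexicon), 50)
    lx <- default_lexicon(task, "strict")
    got <- vapply(corp$text, function(tx) classify_sentence(tx, lx)$label,
                  "", USE.NAMES = FALSE)
    expect_true(all(got[corp$out_of_lexicon] == "NONE"))
    expect_true(all(got[!corp$out_of_lexicon] ==
                      weak_label_oracle(corp)[!corp$out_of_lexicon]))
  }
})
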