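# Template grammar vocabulary. Every pool is screened so that negators,
# prospective triggers and keyword phrases can only appear where the
# generator plants them; planted matches are therefore the only matches.
generator_slots <- function(task, template_split = c("train", "heldout")) {
  template_split <- match.arg(template_split)
  subjects <- switch(template_split,
    train = c("pt", "he", "she"),
    heldout = c("patient", "individual")
  )
  verbs <- switch(task,
    activity = switch(template_split,
      train = c("maintains", "reports", "has", "does"),
      heldout = c("continues", "demonstrates")
    ),
    diet = switch(template_split,
      train = c("is having", "had", "follows", "reports"),
      heldout = c("is on", "consumes")
    )
  )
  list(subjects = subjects, verbs = verbs)
}

generator_fillers <- c("been", "being", "quite", "really", "very", "so",
                       "rather", "much", "that", "too", "still", "somewhat")

generator_trailers <- c("", "daily", "for 2 weeks", "lately", "at home",
                        "most days")

# In-lexicon keyword pools; the strict pool is labeled identically by both
# shipped lexicon profiles ("normal diet" matches strict "normal" at the
# same start and class family).
generator_keywords <- function(task, keyword_profile = c("strict", "extended")) {
  keyword_profile <- match.arg(keyword_profile)
  pools <- switch(task,
    activity = list(
      physical_activity = c("active", "activity"),
      physical_inactivity = c("inactive", "inactivity")
    ),
    diet = list(
      high_calorie_diet = "high calorie diet",
      high_fat_diet = "high fat diet",
      high_salt_diet = "high salt diet",
      normal_diet = "normal diet",
      nonspecific_abnormal = "normal diet"  # realised via negation/triggers
    )
  )
  if (task == "activity" && keyword_profile == "extended") {
    pools$physical_activity <- c(pools$physical_activity, "exercise",
                                 "exercises", "exercising",
                                 "physical activity")
  }
  pools
}

# Versioned out-of-lexicon paraphrase inventory: phrases absent from the
# strict lexicon (several are covered by the extended profile, mirroring the
# worked paraphrase examples "fatty food" and "salt restrictions").
ool_inventory <- list(
  activity = list(
    physical_activity = c("exercise regimen", "works out"),
    physical_inactivity = "sedentary"
  ),
  diet = list(
    high_calorie_diet = "junk food",
    high_fat_diet = "fatty food",
    high_salt_diet = "salty snacks",
    normal_diet = "regular meals",
    nonspecific_abnormal = "salt restrictions"  # realised with a negator
  )
)

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the study corpus: the two tasks' class priors, negators
#' at controlled token distances uniform on 1..7 (so roughly 2/7 of negated
#' sentences fall outside the 5-token rule window, stressing the boundary),
#' and an out-of-lexicon paraphrase fraction.
#'
#' @param task `"activity"` or `"diet"`.
#' @param n_sentences Number of sentences to generate.
#' @param class_mixture Named probability vector over [task_classes()];
#'   defaults to the corpus priors (activity 95.7/4.3; diet
#'   33.8/17.4/15/28.2/5.6).
#' @param negated_fraction Probability a sentence carries a negator
#'   (default 0.15; negated lifestyle mentions are a minority in note
#'   prose).
#' @param negation_distances,negation_distance_probs Support and
#'   probabilities of the token distance between a planted negator and the
#'   keyword start (default uniform on 1..7).
#' @param out_of_lexicon_fraction Probability a sentence uses a paraphrase
#'   absent from the strict lexicon (default 0).
#' @param prospective_fraction Diet only: share of "nonspecific abnormal"
#'   sentences realised through prospective triggers ("can resume normal
#'   diet") rather than negation (default 0.5).
#' @param weak_label_noise_rate Symmetric label-flip rate epsilon applied by
#'   [derive_weak_labels()] (default 0).
#' @param keyword_profile Keyword pool used for in-lexicon sentences
#'   (`"strict"`, the default, is labelable by both lexicon profiles).
#' @param template_split `"train"` or `"heldout"`; the two splits use
#'   disjoint subject/verb templates so a gold-standard stand-in never
#'   shares templates with training data.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(task,
                             n_sentences,
                             class_mixture = NULL,
                             negated_fraction = 0.15,
                             negation_distances = 1:7,
                             negation_distance_probs = NULL,
                             out_of_lexicon_fraction = 0,
                             prospective_fraction = 0.5,
                             weak_label_noise_rate = 0,
                             keyword_profile = c("strict", "extended"),
                             template_split = c("train", "heldout"),
                             seed = 1L) {
  task <- match.arg(task, c("activity", "diet"))
  keyword_profile <- match.arg(keyword_profile)
  template_split <- match.arg(template_split)
  classes <- task_classes(task)
  if (is.null(class_mixture)) {
    class_mixture <- switch(task,
      activity = c(physical_activity = 0.957, physical_inactivity = 0.043),
      diet = c(high_calorie_diet = 0.338, high_fat_diet = 0.174,
               high_salt_diet = 0.150, normal_diet = 0.282,
               nonspecific_abnormal = 0.056)
    )
  }
  if (!setequal(names(class_mixture), classes)) {
    stop("class_mixture must be named with the task classes", call. = FALSE)
  }
  class_mixture <- class_mixture[classes]
  if (abs(sum(class_mixture) - 1) > 1e-9 || any(class_mixture < 0)) {
    stop("class_mixture must be a probability vector summing to 1",
         call. = FALSE)
  }
  if (is.null(negation_distance_probs)) {
    negation_distance_probs <- rep(1 / length(negation_distances),
                                   length(negation_distances))
  }
  stopifnot(length(negation_distance_probs) == length(negation_distances),
            all(negation_distances >= 1),
            abs(sum(negation_distance_probs) - 1) < 1e-9)
  for (f in c(negated_fraction, out_of_lexicon_fraction, prospective_fraction,
              weak_label_noise_rate)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_sentences >= 0)
  structure(
    list(task = task, n_sentences = as.integer(n_sentences),
         class_mixture = class_mixture,
         negated_fraction = negated_fraction,
         negation_distances = as.integer(negation_distances),
         negation_distance_probs = negation_distance_probs,
         out_of_lexicon_fraction = out_of_lexicon_fraction,
         prospective_fraction = prospective_fraction,
         weak_label_noise_rate = weak_label_noise_rate,
         keyword_profile = keyword_profile,
         template_split = template_split,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Compose one synthetic sentence with exact slot control
#'
#' Low-level assembly used by [generate_corpus()] and by boundary probes in
#' tests. The realised token distance between `negator` and the first
#' keyword token is exactly `distance` (the negator is followed by
#' `distance - 1` filler tokens).
#'
#' @param subject,verb Template slot strings (verb may be multi-token; it is
#'   omitted in negated sentences, whose pre-keyword context is the negator
#'   plus fillers).
#' @param keyword Keyword phrase (1+ tokens).
#' @param negator Optional single-token negator.
#' @param distance Token distance from negator to keyword start (>= 1).
#' @param triggers Optional prospective trigger tokens placed before the
#'   keyword (diet).
#' @param trailing Optional trailing clause ("" for none).
#' @param fillers Filler vocabulary for distance padding.
#' @return Character vector of tokens.
#' @export
compose_sentence <- function(subject, verb, keyword, negator = NULL,
                             distance = 1L, triggers = character(0),
                             trailing = "", fillers = generator_fillers) {
  subj <- tokenize_text(subject)
  kw <- tokenize_text(keyword)
  trail <- tokenize_text(trailing)
  if (!is.null(negator)) {
    stopifnot(distance >= 1L)
    pad <- if (distance > 1L) {
      fillers[1L + (seq_len(distance - 1L) - 1L) %% length(fillers)]
    } else character(0)
    pre <- c(subj, negator, pad)
  } else if (length(triggers)) {
    pre <- c(subj, triggers)
  } else {
    pre <- c(subj, tokenize_text(verb))
  }
  c(pre, kw, trail)
}

# Expected rule-labeler output implied by a generation trace. For
# out-of-lexicon sentences the gold class is asserted by the generator (the
# rule family cannot derive it); otherwise the rule coding applies, with a
# negator only effective within the window.
trace_label <- function(task, intended_class, keyword_class, negated,
                        distance, prospective, out_of_lexicon,
                        window_size = 5L) {
  if (out_of_lexicon) return(intended_class)
  eff_neg <- isTRUE(negated) && !is.na(distance) && distance <= window_size
  if (task == "activity") {
    if (eff_neg) return(opposite_activity_class(keyword_class))
    return(keyword_class)
  }
  if (keyword_class %in% high_x_classes) {
    if (eff_neg) return(NONE_LABEL)
    return(keyword_class)
  }
  if (eff_neg) return("nonspecific_abnormal")
  if (isTRUE(prospective)) return("nonspecific_abnormal")
  "normal_diet"
}

#' Expected labels from generation traces
#'
#' Applies the rule-coding semantics to each sentence's generation trace,
#' independently of the labeler's text scanning; used as the oracle in
#' equivalence checks.
#'
#' @param corpus A corpus tibble from [generate_corpus()].
#' @param window_size Rule window in tokens (default 5).
#' @return Character vector of expected labels (may include `"NONE"`).
#' @export
weak_label_oracle <- function(corpus, window_size = 5L) {
  vapply(seq_len(nrow(corpus)), function(i) {
    trace_label(corpus$task[i], corpus$gold_label[i], corpus$keyword_class[i],
                corpus$negated[i], corpus$neg_distance[i],
                corpus$prospective[i], corpus$out_of_lexicon[i], window_size)
  }, "")
}

#' Generate a synthetic gold-labeled corpus
#'
#' Template-based clinical-style sentences with generator-assigned gold
#' labels and full generation traces. Gold labels are consistent with the
#' rule semantics of the trace by construction (a far negator, beyond the
#' window, does not flip the gold class), so an in-lexicon corpus is an
#' exact oracle for the weak labeler.
#'
#' @param config A [generator_config()].
#' @param classes Optional explicit character vector of gold classes, one
#'   per sentence (overrides mixture sampling; used for exact class counts).
#' @return A tibble with sentence record columns (`sentence_id`, `note_id`,
#'   `text`), `task`, `gold_label`, and trace columns (`template_id`,
#'   `keyword_class`, `phrase`, `negated`, `neg_distance`, `prospective`,
#'   `out_of_lexicon`).
#' @export
generate_corpus <- function(config, classes = NULL) {
  stopifnot(inherits(config, "generator_config"))
  task <- config$task
  w <- 5L
  slots <- generator_slots(task, config$template_split)
  kw_pools <- generator_keywords(task, config$keyword_profile)
  ool_pool <- ool_inventory[[task]]
  negs <- c("no", "not", "never", "denies", "didnt", "doesnt", "without")
  trig_pairs <- list(c("can", "resume"), c("can", "start"), c("may", "begin"),
                     c("going", "to"), c("can"), c("may"))
  dists <- config$negation_distances
  dprobs <- config$negation_distance_probs
  near <- dists <= w
  n <- if (is.null(classes)) config$n_sentences else length(classes)
  if (n == 0L) {
    return(tibble::tibble(sentence_id = character(0), note_id = character(0),
                          text = character(0), task = character(0),
                          gold_label = character(0), template_id = character(0),
                          keyword_class = character(0), phrase = character(0),
                          negated = logical(0), neg_distance = integer(0),
                          prospective = logical(0), out_of_lexicon = logical(0)))
  }
  withr::with_seed(config$seed, {
    if (is.null(classes)) {
      classes <- sample(names(config$class_mixture), n, replace = TRUE,
                        prob = config$class_mixture)
    } else {
      stopifnot(all(classes %in% task_classes(task)))
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- classes[i]
      subject <- sample(slots$subjects, 1L)
      verb <- sample(slots$verbs, 1L)
      trailing <- sample(generator_trailers, 1L)
      ool <- stats::runif(1) < config$out_of_lexicon_fraction &&
        !is.null(ool_pool[[g]])
      negated <- FALSE; dist <- NA_integer_; prospective <- FALSE
      kw_class <- NA_character_
      if (ool) {
        phrase <- sample(rep(ool_pool[[g]], 2L), 1L)
        if (task == "diet" && g == "nonspecific_abnormal") {
          # paraphrase of the negated normal-family pattern
          negated <- TRUE
          dist <- sample(rep(dists[near], 2L), 1L,
                         prob = rep(dprobs[near], 2L))
          toks <- compose_sentence(subject, verb, phrase,
                                   negator = sample(negs, 1L), distance = dist,
                                   trailing = trailing)
        } else {
          toks <- compose_sentence(subject, verb, phrase, trailing = trailing)
        }
      } else if (task == "activity") {
        phrase_class <- g
        if (stats::runif(1) < config$negated_fraction) {
          negated <- TRUE
          dist <- sample(rep(dists, 2L), 1L, prob = rep(dprobs, 2L))
          phrase_class <- if (dist <= w) opposite_activity_class(g) else g
        }
        kw_class <- phrase_class
        phrase <- sample(rep(kw_pools[[phrase_class]], 2L), 1L)
        toks <- compose_sentence(subject, verb, phrase,
                                 negator = if (negated) sample(negs, 1L),
                                 distance = if (negated) dist else 1L,
                                 trailing = trailing)
      } else {  # diet, in-lexicon
        if (g == "nonspecific_abnormal") {
          kw_class <- "normal_diet"
          phrase <- "normal diet"
          if (stats::runif(1) < config$prospective_fraction) {
            prospective <- TRUE
            trig <- trig_pairs[[sample.int(length(trig_pairs), 1L)]]
            toks <- compose_sentence(subject, verb, phrase, triggers = trig,
                                     trailing = trailing)
          } else {
            negated <- TRUE
            dist <- sample(rep(dists[near], 2L), 1L,
                           prob = rep(dprobs[near], 2L))
            toks <- compose_sentence(subject, verb, phrase,
                                     negator = sample(negs, 1L),
                                     distance = dist, trailing = trailing)
          }
        } else {
          kw_class <- g
          phrase <- sample(rep(kw_pools[[g]], 2L), 1L)
          far <- dists > w
          if (any(far) && stats::runif(1) < config$negated_fraction) {
            # a far negator leaves the rule label (and the gold) unchanged
            negated <- TRUE
            dist <- sample(rep(dists[far], 2L), 1L, prob = rep(dprobs[far], 2L))
            toks <- compose_sentence(subject, verb, phrase,
                                     negator = sample(negs, 1L),
                                     distance = dist, trailing = trailing)
          } else {
            toks <- compose_sentence(subject, verb, phrase, trailing = trailing)
          }
        }
      }
      rows[[i]] <- tibble::tibble(
        sentence_id = paste0(config$template_split, "-", i),
        note_id = paste0(config$template_split, "-note-", i),
        text = paste(toks, collapse = " "),
        task = task,
        gold_label = g,
        template_id = paste(task, config$template_split, subject, verb,
                            sep = "|"),
        keyword_class = kw_class,
        phrase = phrase,
        negated = negated,
        neg_distance = dist,
        prospective = prospective,
        out_of_lexicon = ool
      )
    }
    out <- do.call(rbind, rows)
  })
  # gold labels are rule-semantics-of-trace by construction
  stopifnot(identical(weak_label_oracle(out), out$gold_label))
  out
}

#' Apply symmetric label noise to gold labels
#'
#' Each label is kept with probability `1 - epsilon` and otherwise resampled
#' uniformly from the other task classes; flips are recorded.
#'
#' @param corpus A corpus tibble with `gold_label` and `task` columns.
#' @param epsilon Flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The corpus with added columns `weak_label` and `flipped`.
#' @export
derive_weak_labels <- function(corpus, epsilon, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, nrow(corpus) == 0 ||
              length(unique(corpus$task)) == 1L)
  classes <- if (nrow(corpus)) task_classes(corpus$task[1L]) else character(0)
  out <- corpus
  withr::with_seed(seed, {
    flip <- stats::runif(nrow(corpus)) < epsilon
    weak <- corpus$gold_label
    for (i in which(flip)) {
      others <- setdiff(classes, corpus$gold_label[i])
      weak[i] <- others[sample.int(length(others), 1L)]
    }
  })
  out$weak_label <- weak
  out$flipped <- flip
  out
}

#' Generate a gold-standard-corpus stand-in
#'
#' A noise-free, gold-labeled evaluation set drawn from held-out templates
#' disjoint from training templates. By default the class composition
#' follows the task's corpus mixture; pass `class_counts` for an exact
#' composition (e.g. the published gold sets: activity
#' `c(physical_activity = 78, physical_inactivity = 122)`, diet
#' 18/20/20/18/12).
#'
#' @param task `"activity"` or `"diet"`.
#' @param n Number of sentences when sampling from the mixture.
#' @param class_counts Optional named integer vector of exact per-class
#'   counts (overrides `n`).
#' @param seed Integer seed.
#' @param out_of_lexicon_fraction Share of paraphrase sentences outside the
#'   strict lexicon (default 0).
#' @param ... Further arguments passed to [generator_config()].
#' @return A corpus tibble (see [generate_corpus()]).
#' @export
make_gsc_standin <- function(task, n = 200L, class_counts = NULL, seed = 1L,
                             out_of_lexicon_fraction = 0, ...) {
  if (!is.null(class_counts)) {
    stopifnot(setequal(names(class_counts), task_classes(task)))
    n <- sum(class_counts)
  }
  config <- generator_config(
    task = task, n_sentences = n, template_split = "heldout",
    out_of_lexicon_fraction = out_of_lexicon_fraction, seed = seed, ...
  )
  classes <- NULL
  if (!is.null(class_counts)) {
    classes <- withr::with_seed(seed + 1L, sample(
      rep(names(class_counts), times = class_counts)
    ))
  }
  out <- generate_corpus(config, classes = classes)
  out$sentence_id <- sub("^heldout", "gsc", out$sentence_id)
  out$note_id <- sub("^heldout", "gsc", out$note_id)
  out
}
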