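#' Scan a token sequence for lexicon keyword phrases
#'
#' Reports every keyword-phrase occurrence as a half-open, 0-based token
#' span. At a given start position only the longest matching phrase(s) are
#' kept, so multiword phrases shadow their single-token prefixes ("normal
#' diet" beats "normal" at the same start).
#'
#' @param tokens Character vector of normalised tokens.
#' @param lex A `lifestyle_lexicon`.
#' @return A data frame with columns `class`, `phrase`, `start`, `end`
#'   (0-based, half-open), ordered by `start`.
#' @export
scan_keywords <- function(tokens, lex) {
  stopifnot(inherits(lex, "lifestyle_lexicon"))
  n <- length(tokens)
  phrases <- phrase_table(lex)
  out <- list()
  for (s in seq_len(n)) {  # s is 1-based start
    hit_len <- 0L
    hits <- list()
    for (k in seq_len(nrow(phrases))) {
      len <- phrases$len[k]
      if (len < hit_len || s + len - 1L > n) next
      if (identical(tokens[s:(s + len - 1L)], phrases$toks[[k]])) {
        if (len > hit_len) {
          hits <- list()
          hit_len <- len
        }
        hits[[length(hits) + 1L]] <-
          data.frame(class = phrases$class[k], phrase = phrases$phrase[k],
                     start = s - 1L, end = s - 1L + len,
                     stringsAsFactors = FALSE)
      }
    }
    out <- c(out, hits)
  }
  if (!length(out)) {
    return(data.frame(class = character(0), phrase = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Flattened phrase inventory, longest phrases first.
phrase_table <- function(lex) {
  cls <- rep(names(lex$class_keywords),
             vapply(lex$class_keywords, length, integer(1)))
  phr <- unlist(lex$class_keywords, use.names = FALSE)
  toks <- strsplit(phr, " ", fixed = TRUE)
  len <- lengths(toks)
  ord <- order(-len)
  tab <- data.frame(class = cls[ord], phrase = phr[ord], len = len[ord],
                    stringsAsFactors = FALSE)
  tab$toks <- toks[ord]
  tab
}

# Deterministic match selection: leftmost start, then longest phrase, then
# fixed class priority (see class_match_priority()).
select_match <- function(matches, task) {
  if (!nrow(matches)) return(NULL)
  prio <- match(matches$class, class_match_priority(task))
  ord <- order(matches$start, -(matches$end - matches$start), prio)
  matches[ord[1L], , drop = FALSE]
}

#' Tokens immediately before a match span
#'
#' @param tokens Character vector of tokens.
#' @param span_start 0-based index of the first token of the match;
#'   must satisfy `0 <= span_start <= length(tokens)`.
#' @param window_size Maximum number of preceding tokens returned.
#' @return The up-to-`window_size` tokens before `span_start`, in order.
#' @export
window_before <- function(tokens, span_start, window_size) {
  stopifnot(span_start >= 0L, span_start <= length(tokens), window_size >= 1L)
  if (span_start == 0L) return(character(0))
  from <- max(0L, span_start - as.integer(window_size))
  tokens[(from + 1L):span_start]
}

#' Test a token window for negation
#'
#' @param window Character vector (possibly empty) of window tokens.
#' @param negation_terms Character vector of single-token negators.
#' @return `TRUE` iff any window token is a negator.
#' @export
detect_negation <- function(window, negation_terms) {
  any(window %in% negation_terms)
}

opposite_activity_class <- function(class) {
  unname(c(physical_activity = "physical_inactivity",
           physical_inactivity = "physical_activity")[class])
}

no_match_label <- function(task) {
  list(task = task, label = NONE_LABEL, code = 0L, matched_phrase = NA_character_,
       span_start = NA_integer_, span_end = NA_integer_,
       window = character(0), negated = FALSE, prospective = FALSE)
}

make_label <- function(task, label, code, m, window, negated, prospective) {
  list(task = task, label = label, code = as.integer(code),
       matched_phrase = m$phrase, span_start = m$start, span_end = m$end,
       window = window, negated = negated, prospective = prospective)
}

#' Weak-label one sentence for the physical-activity task
#'
#' The selected keyword match returns its own class when unnegated (code 1);
#' a negator in the window flips the assignment to the opposite class
#' (code -1). No match gives the `"NONE"` label (code 0).
#'
#' @param tokens Character vector of normalised tokens.
#' @param lex An activity `lifestyle_lexicon`.
#' @return A list with `label`, `code`, and a full audit trace
#'   (`matched_phrase`, `span_start`/`span_end`, `window`, `negated`,
#'   `prospective`).
#' @export
classify_activity <- function(tokens, lex) {
  stopifnot(lex$task == "activity")
  m <- select_match(scan_keywords(tokens, lex), "activity")
  if (is.null(m)) return(no_match_label("activity"))
  win <- window_before(tokens, m$start, lex$window_size)
  neg <- detect_negation(win, lex$negation_terms)
  label <- if (neg) opposite_activity_class(m$class) else m$class
  make_label("activity", label, if (neg) -1L else 1L, m, win, neg, FALSE)
}

#' Weak-label one sentence for the excessive-diet task
#'
#' Candidate matches are visited in deterministic order (leftmost, longest,
#' fixed class priority). A "high X diet" match yields its class when
#' unnegated (code 1) and is voided by negation (code 0; a later candidate
#' may still fire). A normal-family match yields "nonspecific abnormal" when
#' negated (code -1) or when a prospective trigger such as "can"/"resume"
#' sits in the window (code 4), and "normal diet" otherwise (code 1).
#' Negation takes precedence over prospective triggers.
#'
#' @inheritParams classify_activity
#' @param lex A diet `lifestyle_lexicon`.
#' @return Same shape as [classify_activity()].
#' @export
classify_diet <- function(tokens, lex) {
  stopifnot(lex$task == "diet")
  matches <- scan_keywords(tokens, lex)
  if (!nrow(matches)) return(no_match_label("diet"))
  prio <- match(matches$class, class_match_priority("diet"))
  ord <- order(matches$start, -(matches$end - matches$start), prio)
  for (i in ord) {
    m <- matches[i, , drop = FALSE]
    win <- window_before(tokens, m$start, lex$window_size)
    neg <- detect_negation(win, lex$negation_terms)
    if (m$class %in% high_x_classes) {
      if (neg) next  # code 0: negated high-X contributes nothing
      return(make_label("diet", m$class, 1L, m, win, FALSE, FALSE))
    }
    # normal/abnormal rule family
    if (neg) {
      return(make_label("diet", "nonspecific_abnormal", -1L, m, win, TRUE, FALSE))
    }
    pro <- any(win %in% lex$prospective_triggers)
    if (pro) {
      return(make_label("diet", "nonspecific_abnormal", 4L, m, win, FALSE, TRUE))
    }
    return(make_label("diet", "normal_diet", 1L, m, win, FALSE, FALSE))
  }
  no_match_label("diet")
}

#' Weak-label one sentence
#'
#' @param text A normalised sentence string (or a token vector via
#'   `tokens`).
#' @param lex A `lifestyle_lexicon`; its `task` selects the rule set.
#' @param tokens Optional pre-tokenized input (overrides `text`).
#' @return See [classify_activity()] / [classify_diet()].
#' @export
classify_sentence <- function(text, lex, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_text(text)
  switch(lex$task,
    activity = classify_activity(tokens, lex),
    diet = classify_diet(tokens, lex)
  )
}

#' Weak-label a corpus of sentences
#'
#' Applies the rule labeler to every sentence, emitting exactly one label
#' per sentence. Sentences whose label is `"NONE"` are routed to the
#' exclusion log rather than the training set. Deterministic given
#' (`sentences`, `lex`).
#'
#' @param sentences A data frame with columns `sentence_id` and `text`
#'   (normalised), as produced by [preprocess_notes()] or
#'   [generate_corpus()].
#' @param lex A `lifestyle_lexicon`.
#' @return A list with `labels` (tibble: `sentence_id`, `task`, `text`,
#'   `label`, `code`, `matched_phrase`, `window`, `negated`, `prospective`)
#'   and `excluded` (same columns, the `"NONE"` rows).
#' @export
label_corpus <- function(sentences, lex) {
  stopifnot(is.data.frame(sentences),
            all(c("sentence_id", "text") %in% names(sentences)),
            inherits(lex, "lifestyle_lexicon"))
  res <- lapply(sentences$text, classify_sentence, lex = lex)
  out <- tibble::tibble(
    sentence_id = sentences$sentence_id,
    task = lex$task,
    text = sentences$text,
    label = vapply(res, `[[`, "", "label"),
    code = vapply(res, `[[`, 0L, "code"),
    matched_phrase = vapply(res, `[[`, "", "matched_phrase"),
    window = vapply(res, function(r) paste(r$window, collapse = " "), ""),
    negated = vapply(res, `[[`, FALSE, "negated"),
    prospective = vapply(res, `[[`, FALSE, "prospective")
  )
  keep <- out$label != NONE_LABEL
  list(labels = out[keep, , drop = FALSE],
       excluded = out[!keep, , drop = FALSE])
}

#' A rule-based labeler wrapped as a classifier
#'
#' Lets the weak labeler sit in the same evaluation roster as trained
#' models. Predictions may include `"NONE"` for unmatched sentences, which
#' evaluation counts as a miss for every gold class.
#'
#' @param lex A `lifestyle_lexicon`.
#' @return An object of class `rule_classifier` with a `predict` method.
#' @export
rule_classifier <- function(lex) {
  stopifnot(inherits(lex, "lifestyle_lexicon"))
  structure(list(lexicon = lex), class = "rule_classifier")
}

#' @export
predict.rule_classifier <- function(object, newdata, ...) {
  vapply(newdata, function(tx) classify_sentence(tx, object$lexicon)$label,
         "", USE.NAMES = FALSE)
}
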