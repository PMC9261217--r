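#' @keywords internal
NONE_LABEL <- "NONE"

#' Class sets for the two lifestyle tasks
#'
#' @param task `"activity"` or `"diet"`.
#' @return Character vector of class names for the task (excluding the
#'   `"NONE"` pseudo-label used for unmatched sentences).
#' @export
task_classes <- function(task) {
  switch(match.arg(task, c("activity", "diet")),
    activity = c("physical_activity", "physical_inactivity"),
    diet = c("high_calorie_diet", "high_fat_diet", "high_salt_diet",
             "normal_diet", "nonspecific_abnormal")
  )
}

# Fixed tie-break priority among classes whose matches start at the same
# token with the same phrase length.
class_match_priority <- function(task) {
  switch(match.arg(task, c("activity", "diet")),
    activity = c("physical_inactivity", "physical_activity"),
    diet = c("high_calorie_diet", "high_fat_diet", "high_salt_diet",
             "normal_diet")
  )
}

# Diet classes handled by the "high X diet" rule (negation voids the match);
# everything keyed under normal_diet follows the normal/abnormal rule family.
high_x_classes <- c("high_calorie_diet", "high_fat_diet", "high_salt_diet")

#' Construct a rule lexicon
#'
#' A lexicon bundles, for one task, the keyword phrases per class, the
#' negation vocabulary scanned in the token window before a match, the
#' prospective triggers (diet only; they reroute "normal diet" to
#' "nonspecific abnormal"), and the window size in tokens.
#'
#' @param task `"activity"` or `"diet"`.
#' @param class_keywords Named list mapping class names to character vectors
#'   of normalised keyword phrases (1+ tokens, lowercase, no punctuation).
#' @param negation_terms Character vector of single-token negators.
#' @param prospective_triggers Character vector of single-token triggers
#'   (typically empty for the activity task).
#' @param window_size Number of tokens immediately before a matched phrase
#'   scanned for negators/triggers (default 5).
#' @return An object of class `lifestyle_lexicon`.
#' @export
lexicon <- function(task, class_keywords, negation_terms,
                    prospective_triggers = character(0), window_size = 5L) {
  task <- match.arg(task, c("activity", "diet"))
  window_size <- as.integer(window_size)
  stopifnot(length(window_size) == 1L, window_size >= 1L)
  if (!is.list(class_keywords) || is.null(names(class_keywords)) ||
      any(!nzchar(names(class_keywords)))) {
    stop("class_keywords must be a named list", call. = FALSE)
  }
  unknown <- setdiff(names(class_keywords), task_classes(task))
  if (length(unknown)) {
    stop("unknown classes for task '", task, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_phrases <- function(x, what) {
    x <- as.character(x)
    bad <- !grepl("^[a-z0-9]+( [a-z0-9]+)*$", x)
    if (!length(x) || any(bad)) {
      stop(what, " must be non-empty, normalised (lowercase alphanumeric, ",
           "single spaces)", call. = FALSE)
    }
    x
  }
  class_keywords <- lapply(class_keywords, check_phrases, what = "keyword phrases")
  negation_terms <- check_phrases(negation_terms, "negation terms")
  if (any(grepl(" ", negation_terms, fixed = TRUE))) {
    stop("negation terms must be single tokens", call. = FALSE)
  }
  prospective_triggers <- as.character(prospective_triggers)
  if (length(prospective_triggers)) {
    prospective_triggers <- check_phrases(prospective_triggers,
                                          "prospective triggers")
    if (any(grepl(" ", prospective_triggers, fixed = TRUE))) {
      stop("prospective triggers must be single tokens", call. = FALSE)
    }
  }
  structure(
    list(task = task, window_size = window_size,
         class_keywords = class_keywords,
         negation_terms = negation_terms,
         prospective_triggers = prospective_triggers),
    class = "lifestyle_lexicon"
  )
}

#' @export
print.lifestyle_lexicon <- function(x, ...) {
  cat("<lifestyle_lexicon> task:", x$task,
      " window:", x$window_size, "tokens\n")
  for (cl in names(x$class_keywords)) {
    cat("  ", cl, ": ", paste(x$class_keywords[[cl]], collapse = ", "),
        "\n", sep = "")
  }
  cat("  negation terms:", length(x$negation_terms),
      "| prospective triggers:", length(x$prospective_triggers), "\n")
  invisible(x)
}

#' Load a shipped default lexicon
#'
#' Two profiles are shipped per task. `"strict"` contains only the core
#' published keyword lists. `"extended"` (the default) additionally covers
#' common paraphrases ("exercise", "fatty food", "salt restrictions", the
#' multiword "physical activity"/"normal diet"/"high salt" phrases) that the
#' worked examples require; it is the profile a practitioner would deploy.
#'
#' @param task `"activity"` or `"diet"`.
#' @param profile `"extended"` (default) or `"strict"`.
#' @return A `lifestyle_lexicon`.
#' @export
default_lexicon <- function(task, profile = c("extended", "strict")) {
  task <- match.arg(task, c("activity", "diet"))
  profile <- match.arg(profile)
  path <- system.file("lexicons", paste0(task, "_", profile, ".yaml"),
                      package = "weaklabelr", mustWork = TRUE)
  read_lexicon(path)
}

#' Read a lexicon from a YAML or JSON file
#'
#' Expected keys: `task`, `window_size`, `class_keywords`,
#' `negation_terms`, `prospective_triggers`.
#'
#' @param path File path; format inferred from the extension.
#' @return A `lifestyle_lexicon`.
#' @export
read_lexicon <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported lexicon format: .", ext, call. = FALSE)
  )
  lexicon(
    task = raw$task,
    class_keywords = lapply(raw$class_keywords, as.character),
    negation_terms = as.character(raw$negation_terms),
    prospective_triggers = as.character(raw$prospective_triggers %||% character(0)),
    window_size = raw$window_size %||% 5L
  )
}

#' Write a lexicon to YAML or JSON
#'
#' @param lex A `lifestyle_lexicon`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lifestyle_lexicon"))
  obj <- unclass(lex)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(obj, path),
    json = jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported lexicon format: .", ext, call. = FALSE)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
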