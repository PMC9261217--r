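#' Split raw note text into sentences
#'
#' Splitting happens before normalisation because terminal punctuation is the
#' boundary evidence. Boundaries are `.`, `!` or `?` followed by whitespace,
#' so decimal numbers ("98.6") are never split.
#'
#' @param text A single character string (one note); `NA` or empty text
#'   yields an empty character vector.
#' @param boundary_regex Perl regex locating the split point; the default
#'   splits after sentence-final punctuation followed by whitespace.
#' @return Character vector of raw (unnormalised) sentence strings, in
#'   document order.
#' @export
split_into_sentences <- function(text, boundary_regex = "(?<=[.!?])\\s+") {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  parts <- strsplit(text, boundary_regex, perl = TRUE)[[1L]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Normalise a sentence string
#'
#' Lowercases, removes every character that is not a lowercase letter, digit
#' or space (apostrophes are removed, not blanked, so "didn't" becomes the
#' single token "didnt"), collapses whitespace runs to single spaces and
#' trims. Idempotent.
#'
#' @param x Character vector of raw sentence strings.
#' @return Character vector of normalised strings.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  x <- gsub("[^a-z0-9 ]+", "", x, perl = TRUE)
  x <- gsub(" {2,}", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize a normalised sentence
#'
#' @param x A single normalised string (see [normalize_text()]).
#' @return Character vector of tokens (0-based indexing is used wherever
#'   token positions are reported); empty input gives `character(0)`.
#' @export
tokenize_text <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

#' Drop exact duplicate sentences corpus-wide
#'
#' Keeps the first occurrence of each normalised text; order otherwise
#' preserved. Deduplication is corpus-global, not per note, because repeated
#' boilerplate recurs across notes.
#'
#' @param sentences A data frame with a `text` column of normalised strings.
#' @return The data frame restricted to first occurrences.
#' @export
deduplicate_sentences <- function(sentences) {
  sentences[!duplicated(sentences$text), , drop = FALSE]
}

#' Preprocess raw notes into sentence records
#'
#' Runs the full cleaning cascade: sentence splitting, normalisation,
#' removal of empty sentences, and corpus-global deduplication.
#'
#' @param notes A data frame with columns `note_id` (non-empty strings) and
#'   `text` (raw free text; may be empty).
#' @param deduplicate Drop repeated sentences (default `TRUE`).
#' @return A tibble with columns `sentence_id`, `note_id`, `text`
#'   (normalised). `sentence_id` is unique within the corpus.
#' @export
preprocess_notes <- function(notes, deduplicate = TRUE) {
  stopifnot(is.data.frame(notes), all(c("note_id", "text") %in% names(notes)))
  if (any(!nzchar(notes$note_id) | is.na(notes$note_id))) {
    stop("note_id must be non-empty", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(notes)), function(i) {
    raw <- split_into_sentences(notes$text[i])
    txt <- normalize_text(raw)
    txt <- txt[nzchar(txt)]
    if (!length(txt)) return(NULL)
    tibble::tibble(
      sentence_id = paste0(notes$note_id[i], "-s", seq_along(txt)),
      note_id = notes$note_id[i],
      text = txt
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(sentence_id = character(0), note_id = character(0),
                          text = character(0))
  }
  if (deduplicate) out <- deduplicate_sentences(out)
  out
}
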