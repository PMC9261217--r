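#' Read a JSON-lines file into a tibble
#'
#' One JSON object per line; all records must share a flat schema.
#'
#' @param path Path to a `.jsonl` file.
#' @return A tibble with one row per line.
#' @export
read_jsonl <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
}

#' Write a data frame as JSON-lines
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(x), con, verbose = FALSE)
  invisible(path)
}

#' Read raw notes from JSONL, CSV or TSV
#'
#' Expects columns `note_id` and `text`.
#'
#' @param path Input file; format inferred from the extension
#'   (`.jsonl`/`.json` for JSON-lines, `.csv`, `.tsv`).
#' @return A tibble with columns `note_id` and `text`.
#' @export
read_notes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  notes <- switch(ext,
    jsonl = ,
    json = read_jsonl(path),
    csv = tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)),
    tsv = tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE)),
    stop("unsupported notes format: .", ext, call. = FALSE)
  )
  if (!all(c("note_id", "text") %in% names(notes))) {
    stop("notes input must have columns 'note_id' and 'text'", call. = FALSE)
  }
  notes$note_id <- as.character(notes$note_id)
  notes$text <- as.character(notes$text)
  if (any(!nzchar(notes$note_id))) {
    stop("note_id must be non-empty", call. = FALSE)
  }
  notes
}
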