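#' Tokenize narrative text
#'
#' Splits free text into word and punctuation tokens with character offsets.
#' Alphanumeric runs, including internal hyphens and apostrophes
#' (`"self-harm"`, `"doesn't"`), form single tokens; every other
#' non-whitespace character is a single-character token. Whitespace is never
#' tokenized. Offsets are 0-based, half-open, so
#' `substr(text, start + 1, end)` recovers the surface form.
#'
#' @param text a single character string (UTF-8).
#' @return a data frame with one row per token and columns `surface`,
#'   `start`, `end` (0-based half-open character offsets) and `folded`
#'   (lower-cased surface used for all dictionary matching).
#' @examples
#' tokenize("accused is suffering from schizophrenia")$folded
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), folded = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  pat <- "[[:alnum:]]+(?:['’-][[:alnum:]]+)*|[^[:alnum:][:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  surface <- substring(text, start + 1L, start + len)
  data.frame(surface = surface, start = start, end = start + len,
             folded = tolower(surface), stringsAsFactors = FALSE)
}

#' Segment a token sequence into sentences
#'
#' Sentences are the scope within which extraction rules may match: no rule
#' match ever crosses a sentence boundary. A boundary is placed after each
#' sentence-final punctuation token (`.`, `!`, `?`) and wherever the original
#' text contains a newline between two consecutive tokens (the latter
#' requires `text`).
#'
#' @param tokens token data frame from [tokenize()].
#' @param text the original text the tokens were produced from; used to
#'   detect newline boundaries between tokens. Optional: without it only
#'   punctuation boundaries are applied.
#' @return a data frame with columns `begin` and `end`: 1-based, half-open
#'   token-index spans (`begin <= i < end`). Spans partition the token
#'   sequence.
#' @export
segment_sentences <- function(tokens, text = NULL) {
  n <- nrow(tokens)
  if (n == 0L) {
    return(data.frame(begin = integer(), end = integer()))
  }
  brk <- tokens$surface %in% c(".", "!", "?")
  if (!is.null(text) && n > 1L) {
    gaps <- substring(text, tokens$end[-n] + 1L, tokens$start[-1L])
    brk[-n] <- brk[-n] | grepl("\n", gaps, fixed = TRUE)
  }
  brk[n] <- TRUE
  ends <- which(brk)
  begins <- c(1L, ends[-length(ends)] + 1L)
  data.frame(begin = begins, end = ends + 1L)
}

validate_narratives <- function(df) {
  required <- c("event_id", "narrative_id", "text")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    dv_stop("narrative input is missing required column(s): %s",
            paste(missing, collapse = ", "))
  }
  df <- df[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (any(!nzchar(trimws(df$text)) | is.na(df$text))) {
    dv_stop("narrative text must be non-empty after whitespace stripping")
  }
  key <- paste(df$event_id, df$narrative_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    dv_stop("duplicate (event_id, narrative_id) key: %s",
            gsub("\r", ", ", dup, fixed = TRUE))
  }
  df
}

#' Read an event-narrative corpus
#'
#' Accepts record-per-line JSON (one object per line with fields `event_id`,
#' `narrative_id`, `text`) or a delimited table with those columns in a
#' header row.
#'
#' @param path file to read.
#' @param format one of `"jsonl"`, `"csv"`, `"tsv"`.
#' @return a data frame of narratives with character columns `event_id`,
#'   `narrative_id`, `text`; keys are checked for uniqueness.
#' @export
read_narratives <- function(path, format = c("jsonl", "csv", "tsv")) {
  format <- match.arg(format)
  df <- switch(format,
    jsonl = {
      con <- file(path, "r")
      on.exit(close(con))
      jsonlite::stream_in(con, verbose = FALSE)
    },
    csv = utils::read.csv(path, colClasses = "character"),
    tsv = utils::read.delim(path, colClasses = "character")
  )
  validate_narratives(df)
}

#' Write records as record-per-line JSON
#'
#' Generic writer for all pipeline artifacts (narratives, mentions, mapped
#' records, gold annotations). One JSON object per line; round-trip stable
#' with [read_records()].
#'
#' @param records a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(records, con, verbose = FALSE)
  invisible(path)
}

#' Read record-per-line JSON written by [write_records()]
#'
#' @param path file to read.
#' @return a data frame.
#' @export
read_records <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}
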