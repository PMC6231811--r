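# The 13 task dictionaries. Role anchors (poi, victim), linking vocabulary
# (be, have, history, verbs, negation, family) and the four capture
# vocabularies that can yield a mention (mental_disorder, drug_names,
# drug_types, drug_addiction) plus disorder adjectives.
DICTIONARY_NAMES <- c(
  "adjectives", "be", "drug_addiction", "drug_names", "drug_types",
  "family", "have", "history", "mental_disorder", "negation",
  "poi", "verbs", "victim"
)

# dictionaries whose entries may fill a rule's capture slot
CAPTURE_DICTIONARIES <- c("mental_disorder", "drug_names", "drug_types",
                          "drug_addiction", "adjectives")

parse_lst_line <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  term <- trimws(parts[1L])
  canonical <- if (length(parts) >= 2L && nzchar(trimws(parts[2L]))) {
    trimws(parts[2L])
  } else {
    NA_character_
  }
  attrs <- if (length(parts) >= 3L) trimws(parts[3L]) else ""
  list(term = term, canonical = canonical, attrs = attrs)
}

parse_attrs <- function(s) {
  if (!nzchar(s)) return(character())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- vapply(kv, function(p) trimws(p[2L]), character(1))
  names(out) <- vapply(kv, function(p) trimws(p[1L]), character(1))
  out
}

#' Load the task dictionaries (gazetteers)
#'
#' Reads one plain-text `.lst` file per dictionary from `dir`. Each
#' non-comment line holds one entry: the term, optionally followed by a tab
#' and a canonical (standardized) form, optionally followed by a tab and
#' `key=value;key=value` attributes (e.g. `misspelling=true`,
#' `class=antidepressant`). Terms are matched case-insensitively; multiword
#' terms are tokenized with [tokenize()] so that matching operates on the
#' same token stream as the narratives.
#'
#' Every `mental_disorder` entry must carry an explicit canonical form (this
#' is what standardizes misspellings such as "schitzophrenia" to
#' "Schizophrenia"); for other dictionaries the canonical defaults to the
#' term itself.
#'
#' @param dir directory holding exactly the 13 `.lst` files. Defaults to the
#'   dictionary set shipped with the package.
#' @return an object of class `dv_gazetteers`: a list with `entries` (named
#'   list of per-dictionary data frames) and a prebuilt first-token index
#'   used by [match_gazetteers()].
#' @export
load_gazetteers <- function(dir = dv_dict_dir()) {
  files <- list.files(dir, pattern = "\\.lst$", full.names = TRUE)
  found <- sub("\\.lst$", "", basename(files))
  unknown <- setdiff(found, DICTIONARY_NAMES)
  if (length(unknown)) {
    dv_stop("unknown dictionary file(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(DICTIONARY_NAMES, found)
  if (length(missing)) {
    dv_stop("missing dictionary file(s): %s", paste(missing, collapse = ", "))
  }

  entries <- list()
  for (i in seq_along(files)) {
    dict <- found[i]
    lines <- readLines(files[i], encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (!length(lines)) dv_stop("dictionary '%s' is empty", dict)
    parsed <- lapply(lines, parse_lst_line)
    term <- vapply(parsed, `[[`, character(1), "term")
    canonical <- vapply(parsed, `[[`, character(1), "canonical")
    attrs <- vapply(parsed, `[[`, character(1), "attrs")
    if (anyDuplicated(tolower(term))) {
      dv_stop("dictionary '%s' has duplicate entries: %s", dict,
              paste(unique(term[duplicated(tolower(term))]), collapse = ", "))
    }
    if (dict == "mental_disorder" && anyNA(canonical)) {
      dv_stop("mental_disorder entries lacking a canonical form: %s",
              paste(term[is.na(canonical)], collapse = ", "))
    }
    canonical[is.na(canonical)] <- term[is.na(canonical)]
    entries[[dict]] <- data.frame(term = tolower(term), canonical = canonical,
                                  attrs = attrs, stringsAsFactors = FALSE)
  }
  entries <- entries[DICTIONARY_NAMES]
  build_gazetteers(entries)
}

# assemble the combined match table + first-token index
build_gazetteers <- function(entries) {
  dict <- rep(names(entries), vapply(entries, nrow, integer(1)))
  term <- unlist(lapply(entries, `[[`, "term"), use.names = FALSE)
  canonical <- unlist(lapply(entries, `[[`, "canonical"), use.names = FALSE)
  attrs <- unlist(lapply(entries, `[[`, "attrs"), use.names = FALSE)
  toks <- lapply(term, function(t) tokenize(t)$folded)
  bad <- lengths(toks) == 0L
  if (any(bad)) {
    dv_stop("dictionary entries with no tokens: %s",
            paste(term[bad], collapse = ", "))
  }
  tab <- list(dict = dict, term = term, canonical = canonical, attrs = attrs,
              tokens = toks, n_tokens = lengths(toks))
  index <- new.env(parent = emptyenv(), size = length(term))
  first <- vapply(toks, `[[`, character(1), 1L)
  for (i in order(-tab$n_tokens)) { # longer entries tried first
    index[[first[i]]] <- c(index[[first[i]]], i)
  }
  structure(list(entries = entries, table = tab, index = index),
            class = "dv_gazetteers")
}

#' Per-dictionary entry counts
#'
#' @param gazetteers a `dv_gazetteers` object.
#' @return a data frame with columns `dictionary` and `n_entries`.
#' @export
gazetteer_manifest <- function(gazetteers) {
  stopifnot(inherits(gazetteers, "dv_gazetteers"))
  data.frame(dictionary = names(gazetteers$entries),
             n_entries = vapply(gazetteers$entries, nrow, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.dv_gazetteers <- function(x, ...) {
  m <- gazetteer_manifest(x)
  cat(sprintf("<dv_gazetteers> %d dictionaries, %d entries\n",
              nrow(m), sum(m$n_entries)))
  print(m, row.names = FALSE)
  invisible(x)
}

empty_lookups <- function() {
  data.frame(dictionary = character(), tok_begin = integer(),
             tok_end = integer(), start = integer(), end = integer(),
             term = character(), canonical = character(),
             attrs = character(), stringsAsFactors = FALSE)
}

#' Match gazetteer entries against a token sequence
#'
#' Case-insensitive multiword matching. Within each dictionary, matching is
#' leftmost-longest: scanning left to right, the longest entry starting at
#' the current position wins and shorter entries it covers are suppressed,
#' so per-dictionary matches never overlap. Matches from *different*
#' dictionaries may overlap freely (a role anchor and a disorder term must
#' be able to coexist in one clause).
#'
#' @param tokens token data frame from [tokenize()].
#' @param gazetteers a `dv_gazetteers` object.
#' @return a data frame of lookups sorted by span start: `dictionary`,
#'   `tok_begin`/`tok_end` (1-based half-open token indices), `start`/`end`
#'   (character offsets), `term`, `canonical`, `attrs`.
#' @export
match_gazetteers <- function(tokens, gazetteers) {
  stopifnot(inherits(gazetteers, "dv_gazetteers"))
  n <- nrow(tokens)
  if (n == 0L) return(empty_lookups())
  folded <- tokens$folded
  tab <- gazetteers$table
  idx <- gazetteers$index

  rows <- integer(0); begins <- integer(0)
  for (i in seq_len(n)) {
    cand <- idx[[folded[i]]]
    if (is.null(cand)) next
    for (r in cand) {
      len <- tab$n_tokens[r]
      if (i + len - 1L > n) next
      if (len == 1L ||
          identical(tab$tokens[[r]][-1L], folded[(i + 1L):(i + len - 1L)])) {
        rows <- c(rows, r); begins <- c(begins, i)
      }
    }
  }
  if (!length(rows)) return(empty_lookups())

  lens <- tab$n_tokens[rows]
  dicts <- tab$dict[rows]
  ord <- order(dicts, begins, -lens)
  keep <- logical(length(rows))
  next_free <- 0L; cur_dict <- ""
  for (k in ord) {
    if (dicts[k] != cur_dict) { cur_dict <- dicts[k]; next_free <- 0L }
    if (begins[k] >= next_free) {
      keep[k] <- TRUE
      next_free <- begins[k] + lens[k]
    }
  }
  rows <- rows[keep]; begins <- begins[keep]; lens <- lens[keep]
  out <- data.frame(
    dictionary = tab$dict[rows],
    tok_begin = begins,
    tok_end = begins + lens,
    start = tokens$start[begins],
    end = tokens$end[begins + lens - 1L],
    term = tab$term[rows],
    canonical = tab$canonical[rows],
    attrs = tab$attrs[rows],
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$dictionary, method = "radix"), , drop = FALSE]
}

#' Path to the shipped dictionary directory
#' @return directory path inside the installed package.
#' @export
dv_dict_dir <- function() {
  system.file("extdata", "dicts", package = "dvmh", mustWork = TRUE)
}
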