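# Shared fixtures: load the shipped resources once per test run.
dv_res <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gaz <- load_gazetteers()
      cache <<- list(gaz = gaz,
                     rules = parse_rules(gazetteers = gaz),
                     schema = read_schema())
    }
    cache
  }
})

one_narrative <- function(text, event_id = "E1", narrative_id = "E1-N1") {
  data.frame(event_id = event_id, narrative_id = narrative_id, text = text,
             stringsAsFactors = FALSE)
}

extract_text <- function(text, ...) {
  r <- dv_res()
  extract_mentions(one_narrative(text, ...), r$gaz, r$rules)
}

# Independent brute-force gazetteer matcher: enumerate every token span,
# keep spans whose folded tokens equal some entry of the dictionary, then
# per dictionary iteratively select the span with the smallest start (ties:
# the longest) and drop every remaining span overlapping it.
brute_match <- function(folded, entries) {
  out <- list()
  n <- length(folded)
  for (d in names(entries)) {
    tok_terms <- lapply(entries[[d]], function(t) tokenize(t)$folded)
    spans <- list()
    if (n > 0) {
      for (i in seq_len(n)) {
        for (j in i:n) {
          if (any(vapply(tok_terms, identical, logical(1), y = folded[i:j]))) {
            spans[[length(spans) + 1L]] <- c(begin = i, end = j + 1L)
          }
        }
      }
    }
    kept <- list()
    while (length(spans)) {
      b <- vapply(spans, `[`, integer(1), 1L)
      e <- vapply(spans, `[`, integer(1), 2L)
      pick <- order(b, -e)[1L]
      kept[[length(kept) + 1L]] <- spans[[pick]]
      ov <- b < e[pick] & e > b[pick]
      spans <- spans[!ov]
    }
    for (k in kept) {
      out[[length(out) + 1L]] <-
        data.frame(dictionary = d, tok_begin = k[["begin"]],
                   tok_end = k[["end"]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(dictionary = character(), tok_begin = integer(),
                      tok_end = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$dictionary, df$tok_begin), , drop = FALSE]
}

# random matching instance for the oracle property: small alphabet so that
# matches (incl. multiword and overlapping-dictionary ones) are frequent
random_match_case <- function() {
  alphabet <- c("alpha", "beta", "gamma", "delta", "echo")
  rand_term <- function() {
    paste(sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = " ")
  }
  dicts <- list(
    mental_disorder = unique(replicate(sample(2:5, 1), rand_term())),
    poi = unique(replicate(sample(1:3, 1), rand_term())),
    negation = unique(replicate(sample(1:3, 1), rand_term()))
  )
  entries <- lapply(dicts, function(terms) {
    data.frame(term = terms, canonical = terms, attrs = "",
               stringsAsFactors = FALSE)
  })
  tokens <- tokenize(paste(sample(alphabet, sample(4:12, 1), replace = TRUE),
                           collapse = " "))
  list(tokens = tokens,
       gaz = dvmh:::build_gazetteers(entries),
       terms = dicts)
}
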