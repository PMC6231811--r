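# Declarative lexical rules over tokens + gazetteer lookups.
#
# Rule file format (plain text; blocks separated by blank lines, '#' starts a
# comment):
#
#   rule poi_suffers_from
#   role POI
#   pattern lookup(poi) not(negation)[0,1] lookup(be)[0,1] lookup(verbs) \
#           literal(from)[0,1] capture(mental_disorder)
#
# Element kinds:
#   lookup(d1|d2)   one gazetteer lookup from any listed dictionary
#   capture(d1|d2)  as lookup, but its match becomes the emitted mention;
#                   exactly one per rule, restricted to disorder dictionaries
#   literal(word)   one token equal (case-insensitively) to `word`
#   not(d1|d2)      one token not covered by any lookup from the listed
#                   dictionaries (the negation-exclusion window)
#   any             one arbitrary token
# Quantifiers: `?` == [0,1]; `[m,n]` repeats the element m..n times
# (default [1,1]). Matching never crosses a sentence boundary.

parse_pattern_element <- function(txt, dict_names) {
  m <- regmatches(txt, regexec(
    "^(lookup|capture|literal|not|any)(?:\\(([^)]*)\\))?(\\?|\\[([0-9]+),([0-9]+)\\])?$",
    txt))[[1L]]
  if (!length(m)) dv_stop("cannot parse rule element '%s'", txt)
  kind <- m[2L]
  payload <- m[3L]
  quant <- m[4L]
  if (kind == "any") {
    if (nzchar(payload)) dv_stop("'any' takes no argument: '%s'", txt)
    payload <- character()
  } else {
    if (!nzchar(payload)) dv_stop("element '%s' needs an argument", txt)
    payload <- tolower(trimws(strsplit(payload, "|", fixed = TRUE)[[1L]]))
    if (any(!nzchar(payload))) dv_stop("empty argument in '%s'", txt)
  }
  if (kind %in% c("lookup", "capture", "not")) {
    bad <- setdiff(payload, dict_names)
    if (length(bad)) {
      dv_stop("rule element references unknown dictionary '%s'", bad[1L])
    }
  }
  if (kind == "capture") {
    bad <- setdiff(payload, CAPTURE_DICTIONARIES)
    if (length(bad)) {
      dv_stop("capture element must use a disorder dictionary, got '%s'",
              bad[1L])
    }
  }
  lim <- if (!nzchar(quant)) c(1L, 1L)
         else if (quant == "?") c(0L, 1L)
         else c(as.integer(m[5L]), as.integer(m[6L]))
  if (lim[1L] > lim[2L]) dv_stop("bad quantifier in '%s'", txt)
  list(kind = kind, payload = payload, min = lim[1L], max = lim[2L],
       capture = kind == "capture")
}

#' Parse a rule file
#'
#' @param path rule file (see file format notes in the package vignette);
#'   defaults to the rule set shipped with the package.
#' @param gazetteers optional `dv_gazetteers`; when supplied, dictionary
#'   references are validated against it, otherwise against the 13 standard
#'   dictionary names.
#' @return an object of class `dv_rules`: a list of rules, each with
#'   `rule_id`, `role` (`"POI"` or `"victim"`) and an element list.
#' @export
parse_rules <- function(path = dv_rules_path(), gazetteers = NULL) {
  dict_names <- if (is.null(gazetteers)) DICTIONARY_NAMES
                else names(gazetteers$entries)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  # honour trailing-backslash continuations
  joined <- character(); buf <- ""
  for (ln in lines) {
    if (grepl("\\\\\\s*$", ln)) {
      buf <- paste0(buf, sub("\\\\\\s*$", " ", ln))
    } else {
      joined <- c(joined, paste0(buf, ln)); buf <- ""
    }
  }
  if (nzchar(buf)) joined <- c(joined, buf)
  lines <- trimws(joined)

  rules <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$rule_id) || is.null(cur$role) || is.null(cur$elements)) {
      dv_stop("incomplete rule block (need rule, role and pattern lines)")
    }
    ncap <- sum(vapply(cur$elements, `[[`, logical(1), "capture"))
    if (ncap != 1L) {
      dv_stop("rule '%s' must have exactly one capture element (has %d)",
              cur$rule_id, ncap)
    }
    cur
  }
  for (ln in lines) {
    if (!nzchar(ln)) {
      r <- flush(cur); if (!is.null(r)) rules[[r$rule_id]] <- r
      cur <- NULL
      next
    }
    kv <- regmatches(ln, regexec("^(rule|role|pattern)\\s+(.*)$", ln))[[1L]]
    if (!length(kv)) dv_stop("cannot parse rule line: '%s'", ln)
    key <- kv[2L]; val <- trimws(kv[3L])
    if (key == "rule") {
      if (!is.null(cur)) { r <- flush(cur); rules[[r$rule_id]] <- r }
      cur <- list(rule_id = val)
    } else if (is.null(cur)) {
      dv_stop("'%s' line outside a rule block", key)
    } else if (key == "role") {
      if (!val %in% c("POI", "victim")) {
        dv_stop("rule '%s': role must be POI or victim, got '%s'",
                cur$rule_id, val)
      }
      cur$role <- val
    } else {
      elems <- strsplit(val, "\\s+")[[1L]]
      cur$elements <- lapply(elems, parse_pattern_element, dict_names)
    }
  }
  r <- flush(cur); if (!is.null(r)) rules[[r$rule_id]] <- r
  if (!length(rules)) dv_stop("no rules found in '%s'", path)
  structure(unname(rules), class = "dv_rules")
}

#' @export
print.dv_rules <- function(x, ...) {
  roles <- vapply(x, `[[`, character(1), "role")
  cat(sprintf("<dv_rules> %d rules (%d POI, %d victim)\n",
              length(x), sum(roles == "POI"), sum(roles == "victim")))
  invisible(x)
}

#' Path to the shipped rule file
#' @return file path inside the installed package.
#' @export
dv_rules_path <- function() {
  system.file("extdata", "rules", "default.rules",
              package = "dvmh", mustWork = TRUE)
}

empty_mentions <- function() {
  data.frame(event_id = character(), narrative_id = character(),
             role = character(), surface = character(),
             canonical = character(), start = integer(), end = integer(),
             rule_id = character(), stringsAsFactors = FALSE)
}

# All (end, capture_row) completions of elements[ei..] starting at token
# position pos within [sb, se]. Sentence-local by construction.
match_elements <- function(elements, ei, pos, se, folded, lkmap, covered,
                           cap = NA_integer_) {
  if (ei > length(elements)) {
    return(list(list(end = pos, cap = cap)))
  }
  el <- elements[[ei]]
  out <- list()
  # consume `count` repeats, greedily trying the largest count first
  consume <- function(count, p, cap2) {
    if (count == 0L) return(list(list(p = p, cap = cap2)))
    states <- list(list(p = p, cap = cap2))
    for (rep_i in seq_len(count)) {
      nxt <- list()
      for (s in states) {
        pp <- s$p
        if (pp > se) next
        if (el$kind %in% c("literal")) {
          if (folded[pp] %in% el$payload) {
            nxt[[length(nxt) + 1L]] <- list(p = pp + 1L, cap = s$cap)
          }
        } else if (el$kind == "any") {
          nxt[[length(nxt) + 1L]] <- list(p = pp + 1L, cap = s$cap)
        } else if (el$kind == "not") {
          hit <- FALSE
          for (d in el$payload) {
            cv <- covered[[d]]
            if (!is.null(cv) && cv[pp]) { hit <- TRUE; break }
          }
          if (!hit) nxt[[length(nxt) + 1L]] <- list(p = pp + 1L, cap = s$cap)
        } else { # lookup / capture
          for (d in el$payload) {
            row <- lkmap[[d]][[as.character(pp)]]
            if (is.null(row)) next
            nxt[[length(nxt) + 1L]] <-
              list(p = row$tok_end,
                   cap = if (el$capture) row$row_id else s$cap)
          }
        }
      }
      states <- nxt
      if (!length(states)) return(list())
    }
    states
  }
  for (count in seq(el$max, el$min)) {
    for (s in consume(count, pos, cap)) {
      out <- c(out, match_elements(elements, ei + 1L, s$p, se, folded,
                                   lkmap, covered, s$cap))
    }
  }
  out
}

# separator grammar for concept enumeration: comma, "and", or comma + "and"
enum_expand <- function(start_pos, se, folded, lkmap, capture_dicts) {
  rows <- integer(0)
  p <- start_pos
  repeat {
    q <- p
    if (q <= se && folded[q] == ",") q <- q + 1L
    if (q <= se && folded[q] == "and") q <- q + 1L
    if (q == p || q > se) break
    row <- NULL
    for (d in capture_dicts) {
      row <- lkmap[[d]][[as.character(q)]]
      if (!is.null(row)) break
    }
    if (is.null(row)) break
    rows <- c(rows, row$row_id)
    p <- row$tok_end
  }
  rows
}

#' Apply extraction rules to one narrative
#'
#' Runs every rule independently over each sentence. For a fixed rule,
#' overlapping candidate matches are resolved leftmost-longest. A matched
#' rule emits one mention per captured disorder lookup; a comma/"and"
#' enumeration following the capture ("depression, self-harm, and suicidal
#' tendencies") emits one mention per enumerated disorder, all inheriting
#' the rule's role. Negated contexts are excluded because the shipped rules
#' place `not(negation)` windows between the role anchor and the capture
#' slot: a negation token in the window makes the rule unmatched. Duplicate
#' emissions (same role, span, canonical) are reported once with the
#' lexicographically smallest rule id.
#'
#' @param narrative a list or one-row data frame with `event_id`,
#'   `narrative_id`, `text`.
#' @param tokens,sentences,lookups precomputed by [tokenize()],
#'   [segment_sentences()] and [match_gazetteers()] on the same text.
#' @param rules a `dv_rules` object.
#' @return a mention data frame: `event_id`, `narrative_id`, `role`,
#'   `surface`, `canonical`, `start`, `end` (character offsets), `rule_id`;
#'   sorted by span start, role, rule id.
#' @export
apply_rules <- function(narrative, tokens, sentences, lookups, rules) {
  stopifnot(inherits(rules, "dv_rules"))
  n <- nrow(tokens)
  if (n == 0L || nrow(lookups) == 0L) return(empty_mentions())
  folded <- tokens$folded
  lookups$row_id <- seq_len(nrow(lookups))

  acc <- list(); na <- 0L
  for (si in seq_len(nrow(sentences))) {
    sb <- sentences$begin[si]; se <- sentences$end[si] - 1L
    in_sent <- lookups$tok_begin >= sb & lookups$tok_end <= se + 1L
    if (!any(in_sent)) next
    lk <- lookups[in_sent, , drop = FALSE]

    # per-dictionary: position -> lookup row; and coverage masks for not()
    lkmap <- list(); covered <- list()
    for (d in unique(lk$dictionary)) {
      sub <- lk[lk$dictionary == d, , drop = FALSE]
      mp <- new.env(parent = emptyenv())
      cv <- logical(n)
      for (j in seq_len(nrow(sub))) {
        mp[[as.character(sub$tok_begin[j])]] <-
          list(tok_end = sub$tok_end[j], row_id = sub$row_id[j])
        cv[sub$tok_begin[j]:(sub$tok_end[j] - 1L)] <- TRUE
      }
      lkmap[[d]] <- mp; covered[[d]] <- cv
    }

    for (rule in rules) {
      first <- rule$elements[[1L]]
      starts <- if (first$kind %in% c("lookup", "capture")) {
        sort(unique(lk$tok_begin[lk$dictionary %in% first$payload]))
      } else if (first$kind == "literal") {
        which(folded %in% first$payload & seq_len(n) >= sb & seq_len(n) <= se)
      } else {
        sb:se
      }
      if (!length(starts)) next
      cand <- list()
      for (st in starts) {
        ms <- match_elements(rule$elements, 1L, st, se, folded, lkmap, covered)
        ms <- Filter(function(m) !is.na(m$cap), ms)
        if (!length(ms)) next
        # the capture binds to the earliest disorder slot (windows are lazy:
        # an enumeration after the first disorder is expanded, not skipped);
        # among those, the longest completion wins
        caps <- vapply(ms, function(m) lookups$tok_begin[m$cap], numeric(1))
        ends <- vapply(ms, `[[`, numeric(1), "end")
        sel <- which(caps == min(caps))
        best <- ms[[sel[which.max(ends[sel])]]]
        cand[[length(cand) + 1L]] <-
          list(start = st, end = best$end, cap = best$cap)
      }
      if (!length(cand)) next
      # leftmost-longest among this rule's candidates
      st <- vapply(cand, `[[`, numeric(1), "start")
      en <- vapply(cand, `[[`, numeric(1), "end")
      keep_end <- 0L
      cdicts <- rule$elements[[which(vapply(rule$elements, `[[`, logical(1),
                                            "capture"))]]$payload
      for (k in order(st, -en)) {
        if (st[k] < keep_end) next
        keep_end <- en[k]
        cap_row <- lookups[cand[[k]]$cap, ]
        extra <- enum_expand(cap_row$tok_end, se, folded, lkmap, cdicts)
        for (rid in c(cand[[k]]$cap, extra)) {
          r <- lookups[rid, ]
          na <- na + 1L
          acc[[na]] <- list(role = rule$role,
                            surface = substr(narrative$text,
                                             r$start + 1L, r$end),
                            canonical = r$canonical,
                            start = r$start, end = r$end,
                            rule_id = rule$rule_id)
        }
      }
    }
  }
  if (!na) return(empty_mentions())
  out <- data.frame(
    event_id = narrative$event_id,
    narrative_id = narrative$narrative_id,
    role = vapply(acc, `[[`, character(1), "role"),
    surface = vapply(acc, `[[`, character(1), "surface"),
    canonical = vapply(acc, `[[`, character(1), "canonical"),
    start = vapply(acc, function(x) as.integer(x$start), integer(1)),
    end = vapply(acc, function(x) as.integer(x$end), integer(1)),
    rule_id = vapply(acc, `[[`, character(1), "rule_id"),
    stringsAsFactors = FALSE
  )
  # identical (role, span, canonical) emitted once, smallest rule_id kept
  out <- out[order(out$start, out$role, out$rule_id, method = "radix"), ,
             drop = FALSE]
  key <- paste(out$role, out$start, out$end, out$canonical, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract role-attributed mentions from a corpus
#'
#' Convenience driver: tokenizes, sentence-segments and gazetteer-matches
#' each narrative, then applies the rule set.
#'
#' @param narratives narrative data frame (`event_id`, `narrative_id`,
#'   `text`).
#' @param gazetteers a `dv_gazetteers` object (default: shipped set).
#' @param rules a `dv_rules` object (default: shipped rules).
#' @return combined mention data frame (see [apply_rules()]).
#' @export
extract_mentions <- function(narratives,
                             gazetteers = load_gazetteers(),
                             rules = parse_rules(gazetteers = gazetteers)) {
  narratives <- validate_narratives(narratives)
  res <- vector("list", nrow(narratives))
  for (i in seq_len(nrow(narratives))) {
    nr <- narratives[i, ]
    toks <- tokenize(nr$text)
    sents <- segment_sentences(toks, nr$text)
    lks <- match_gazetteers(toks, gazetteers)
    res[[i]] <- apply_rules(nr, toks, sents, lks, rules)
  }
  out <- do.call(rbind, c(res, list(empty_mentions())))
  rownames(out) <- NULL
  out
}
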