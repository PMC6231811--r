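test_that("the shipped rule file parses with role-anchored patterns", {
  rules <- dv_res()$rules
  roles <- vapply(rules, `[[`, character(1), "role")
  expect_gte(sum(roles == "POI"), 2L)
  expect_gte(sum(roles == "victim"), 2L)
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  # the anchor + negation-window + verb + disorder pattern exists per role
  expect_true("poi_verb_disorder" %in% ids)
  expect_true("vic_verb_disorder" %in% ids)
  for (r in rules) {
    expect_equal(sum(vapply(r$elements, `[[`, logical(1), "capture")), 1L)
  }
})

test_that("rule parsing rejects invalid rules", {
  d <- withr::local_tempdir()
  f <- file.path(d, "r.rules")

  writeLines(c("rule r1", "role POI",
               "pattern lookup(poi) lookup(mental_disorder)"), f)
  expect_error(parse_rules(f), "capture")

  writeLines(c("rule r2", "role POI", "pattern lookup(foo) capture(mental_disorder)"), f)
  expect_error(parse_rules(f), "unknown dictionary")

  writeLines(c("rule r3", "role POI", "pattern lookup(poi) capture(verbs)"), f)
  expect_error(parse_rules(f), "disorder dictionary")

  writeLines(c("rule r4", "role witness",
               "pattern lookup(poi) capture(mental_disorder)"), f)
  expect_error(parse_rules(f), "role")
})

test_that("role-attributed extraction matches the worked examples", {
  m1 <- extract_text("accused is suffering from schizophrenia")
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$role, "POI")
  expect_equal(m1$canonical, "Schizophrenia")

  m2 <- extract_text("victim takes Valium")
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$role, "victim")
  expect_equal(m2$canonical, "Valium")

  # no role anchor -> no mention
  expect_equal(nrow(extract_text("The neighbour has depression")), 0L)
})

test_that("negated contexts are not extracted", {
  expect_equal(nrow(extract_text("POI does not suffer from depression")), 0L)
  expect_equal(nrow(extract_text("POI denies depression")), 0L)
  expect_equal(nrow(extract_text("POI has no history of self-harm")), 0L)
  kept <- extract_text("POI suffers from depression")
  expect_equal(kept$canonical, "Depression")
})

test_that("inserting a negation token between anchor and disorder kills emission", {
  # each template starts with its role anchor, so any insertion position is
  # strictly between the anchor and the disorder term
  templates <- c("POI has depression",
                 "victim is suffering from anxiety",
                 "defendant has a history of self-harm",
                 "POI takes Xanax",
                 "vic is schizophrenic")
  set.seed(404)
  for (tpl in templates) {
    words <- strsplit(tpl, " ", fixed = TRUE)[[1]]
    base <- extract_text(tpl)
    expect_gte(nrow(base), 1L)
    neg <- sample(c("not", "denies", "never"), 1)
    for (pos in 1:(length(words) - 1)) {
      txt <- paste(c(words[1:pos], neg, words[(pos + 1):length(words)]),
                   collapse = " ")
      after <- extract_text(txt)
      # monotonicity: a negation token never adds mentions
      expect_lte(nrow(after), nrow(base))
      if (pos >= 1 && pos < length(words)) {
        # inserted strictly between anchor and disorder term: no emission
        # (the anchor is the first word in every template above)
        expect_equal(nrow(after), 0L)
      }
    }
  }
})

test_that("concept enumeration emits one mention per listed disorder", {
  m <- extract_text("POI has a history of depression, self-harm, and suicidal tendencies")
  expect_equal(nrow(m), 3L)
  expect_true(all(m$role == "POI"))
  expect_setequal(m$canonical,
                  c("Depression", "Self-harm", "Suicidal ideation"))

  m2 <- extract_text("victim has anxiety and depression")
  expect_equal(nrow(m2), 2L)
  expect_true(all(m2$role == "victim"))
  expect_setequal(m2$canonical, c("Anxiety", "Depression"))

  # enumeration halts at the first non-separator, non-disorder token
  m3 <- extract_text("POI has depression today and left")
  expect_equal(m3$canonical, "Depression")
  expect_equal(nrow(m3), 1L)
})

test_that("matches never cross sentence boundaries", {
  # anchor in one sentence, disorder in the next
  m <- extract_text("Police spoke to the POI. Depression was mentioned by a neighbour.")
  expect_equal(nrow(m), 0L)
  # offsets of real mentions stay within one sentence
  txt <- "POI has depression. The victim is anxious."
  toks <- tokenize(txt)
  sents <- segment_sentences(toks, txt)
  m2 <- extract_text(txt)
  expect_equal(nrow(m2), 2L)
  for (i in seq_len(nrow(m2))) {
    sent_of <- function(chr) {
      ti <- which(toks$start <= chr & toks$end > chr)
      which(sents$begin <= ti & sents$end > ti)
    }
    expect_equal(sent_of(m2$start[i]), sent_of(m2$end[i] - 1L))
  }
})

test_that("a sentence can yield both a POI and a victim mention", {
  m <- extract_text("POI has schizophrenia and the victim has depression")
  expect_setequal(paste(m$role, m$canonical),
                  c("POI Schizophrenia", "victim Depression"))
})

test_that("duplicate emissions collapse to the smallest rule id", {
  # both poi_have_history and poi_history can match this span
  m <- extract_text("POI has a history of depression")
  expect_equal(nrow(m), 1L)
  expect_equal(m$rule_id, "poi_have_history")
})

test_that("extraction output is deterministic and ordered", {
  r <- dv_res()
  corp <- generate_corpus(generation_config(n_events = 80, seed = 5),
                          r$gaz, r$schema)$narratives
  a <- extract_mentions(corp, r$gaz, r$rules)
  b <- extract_mentions(corp, r$gaz, r$rules)
  expect_identical(a, b)
})

test_that("removing a rule never adds mentions; adding a disorder term never removes them", {
  r <- dv_res()
  txts <- c("POI has depression and the victim takes Xanax.",
            "The accused suffers from anxiety. vic has a history of self-harm.")
  corp <- data.frame(event_id = c("E1", "E2"),
                     narrative_id = c("E1-N1", "E2-N1"),
                     text = txts, stringsAsFactors = FALSE)
  full <- extract_mentions(corp, r$gaz, r$rules)
  key <- function(m) paste(m$narrative_id, m$role, m$start, m$end, m$canonical)
  for (drop in seq_along(r$rules)) {
    sub <- structure(r$rules[-drop], class = "dv_rules")
    m <- extract_mentions(corp, r$gaz, sub)
    expect_true(all(key(m) %in% key(full)))
  }
  # extend mental_disorder with a new term: every old mention survives
  entries <- r$gaz$entries
  entries$mental_disorder <- rbind(
    entries$mental_disorder,
    data.frame(term = "zzz syndrome", canonical = "Zzz syndrome", attrs = ""))
  gaz2 <- dvmh:::build_gazetteers(entries)
  m2 <- extract_mentions(corp, gaz2, r$rules)
  expect_true(all(key(full) %in% key(m2)))
})
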