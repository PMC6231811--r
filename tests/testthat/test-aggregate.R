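test_that("precision, recall and F-score follow the standard definitions", {
  expect_equal(fmt_metric(precision(27, 4)), 87.1)
  expect_equal(fmt_metric(recall(164, 44)), 78.8)
  expect_equal(fmt_metric(f_score(88.9, 90.2)), 89.5)
  # harmonic-mean identities
  expect_equal(f_score(80, 80), 80)
  expect_equal(f_score(60, 90), f_score(90, 60))
  p <- precision(7, 3); r <- recall(7, 5)
  f <- f_score(p, r)
  expect_gte(f, min(p, r)); expect_lte(f, max(p, r))
})

test_that("undefined metrics signal instead of returning silent zeros", {
  expect_warning(p <- precision(0, 0), "undefined")
  expect_true(is.na(p))
  expect_warning(r <- recall(0, 0), "undefined")
  expect_true(is.na(r))
  expect_warning(f <- f_score(0, 0), "undefined")
  expect_true(is.na(f))
  expect_warning(expect_true(is.na(f_score(NA_real_, 50))))
})

test_that("both display rounding conventions are available", {
  # 87.0967...: half-up 87.1, truncation 87.0
  expect_equal(fmt_metric(precision(27, 4), mode = "half_up"), 87.1)
  expect_equal(fmt_metric(precision(27, 4), mode = "trunc"), 87.0)
  # 96.1538...: truncation 96.1
  expect_equal(fmt_metric(precision(50, 2), mode = "trunc"), 96.1)
  expect_equal(fmt_metric(recall(50, 4), mode = "trunc"), 92.5)
})

test_that("evaluation counts and metrics come from triple set arithmetic", {
  gold <- data.frame(narrative_id = "N1", role = "POI",
                     canonical = c("A", "B", "C"))
  pred <- data.frame(narrative_id = "N1", role = "POI",
                     canonical = c("A", "B", "D"))
  ev <- evaluate_extractions(gold, pred)
  poi <- ev[ev$role == "POI", ]
  expect_equal(poi$tp, 2L); expect_equal(poi$fp, 1L); expect_equal(poi$fn, 1L)
  expect_equal(fmt_metric(poi$precision), 66.7)
  expect_equal(fmt_metric(poi$recall), 66.7)

  # identity: gold == predicted
  g10 <- data.frame(narrative_id = rep(c("N1", "N2"), each = 5),
                    role = rep(c("POI", "victim"), 5),
                    canonical = paste0("D", 1:10))
  ev2 <- evaluate_extractions(g10, g10)
  expect_true(all(ev2$precision == 100))
  expect_true(all(ev2$recall == 100))
  expect_true(all(ev2$f_score == 100))

  # empty predictions: precision undefined, recall 0
  ev3 <- evaluate_extractions(gold, pred[0, ])
  poi3 <- ev3[ev3$role == "POI", ]
  expect_true(is.na(poi3$precision))
  expect_equal(poi3$recall, 0)

  # duplicates on either side are unified before counting
  ev4 <- evaluate_extractions(rbind(gold, gold), rbind(pred, pred[1, ]))
  expect_equal(ev4[ev4$role == "POI", c("tp", "fp", "fn")],
               poi[, c("tp", "fp", "fn")], ignore_attr = TRUE)
})

test_that("evaluation is symmetric in gold/predicted with P and R exchanged", {
  set.seed(505)
  for (i in 1:10) {
    gold <- data.frame(narrative_id = sample(paste0("N", 1:4), 8, TRUE),
                       role = sample(c("POI", "victim"), 8, TRUE),
                       canonical = sample(LETTERS[1:5], 8, TRUE))
    pred <- data.frame(narrative_id = sample(paste0("N", 1:4), 8, TRUE),
                       role = sample(c("POI", "victim"), 8, TRUE),
                       canonical = sample(LETTERS[1:5], 8, TRUE))
    a <- evaluate_extractions(gold, pred)
    b <- evaluate_extractions(pred, gold)
    expect_equal(a$precision, b$recall)
    expect_equal(a$recall, b$precision)
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
  }
})

test_that("mismatched narrative-to-event maps are rejected", {
  gold <- data.frame(event_id = "E1", narrative_id = "N1", role = "POI",
                     canonical = "A")
  pred <- data.frame(event_id = "E2", narrative_id = "N1", role = "POI",
                     canonical = "A")
  expect_error(evaluate_extractions(gold, pred), "different events")
})

test_that("absolute agreement is intersection over union of triples", {
  expect_equal(absolute_agreement(LETTERS[1:9], LETTERS[1:9]), 100)
  # 8 shared of 10 distinct decisions
  expect_equal(absolute_agreement(LETTERS[1:9], c(LETTERS[1:8], "J")), 80)
  expect_equal(absolute_agreement(c("A", "B"), c("C", "D")), 0)
  expect_warning(na <- absolute_agreement(character(), character()),
                 "undefined")
  expect_true(is.na(na))
  # alternative definition: mean directed overlap
  expect_equal(absolute_agreement(LETTERS[1:10], LETTERS[1:8],
                                  method = "mean_overlap"),
               mean(c(100 * 8 / 10, 100)))
})

test_that("corpus summaries respect flag and summation closure", {
  schema <- dv_res()$schema
  m <- data.frame(event_id = c("E1", "E2", "E2"),
                  narrative_id = c("E1-N1", "E2-N1", "E2-N1"),
                  role = c("POI", "POI", "victim"),
                  canonical = c("Depression", "Schizophrenia", "Depression"),
                  stringsAsFactors = FALSE)
  ext <- deduplicate(map_records(m, schema), by = "event")
  s <- summarize_corpus(ext, n_events_total = 10)
  expect_equal(s$events$n_events_with_mention, 2L)
  expect_equal(s$events$poi_only, 1L)
  expect_equal(s$events$victim_only, 0L)
  expect_equal(s$events$both, 1L)
  expect_equal(s$events$poi_only + s$events$victim_only + s$events$both,
               s$events$n_events_with_mention)
  l1 <- s$levels[[1]]
  for (role in unique(l1$role)) {
    expect_equal(sum(l1$n[l1$role == role]),
                 unique(l1$role_total[l1$role == role]))
    expect_equal(sum(l1$pct[l1$role == role]), 100, tolerance = 0.01)
  }
  # a record without level-3 detail contributes to shallower levels only:
  # Depression maps to level 2, Schizophrenia reaches level 3
  expect_equal(sum(s$levels[[2]]$n), 3L)
  expect_equal(sum(s$levels[[3]]$n), 1L)
  expect_error(summarize_corpus(ext, n_events_total = 1), "n_events_total")

  empty <- deduplicate(map_records(dvmh:::empty_mentions(), schema),
                       by = "event")
  s0 <- summarize_corpus(empty, n_events_total = 5)
  expect_equal(s0$events$n_events_with_mention, 0L)
  expect_equal(nrow(s0$levels[[1]]), 0L)
})

test_that("records lacking deep detail drop out of deeper levels only", {
  schema <- dv_res()$schema
  m <- data.frame(event_id = "E1", narrative_id = "E1-N1",
                  role = "POI",
                  canonical = c("Self-harm", "Intellectual disability",
                                "Schizophrenia"),
                  stringsAsFactors = FALSE)
  ext <- deduplicate(map_records(m, schema), by = "event")
  s <- summarize_corpus(ext, n_events_total = 1)
  expect_equal(sum(s$levels[[1]]$n), 3L)
  expect_equal(sum(s$levels[[2]]$n), 2L) # Self-harm is level-1 only
  expect_equal(sum(s$levels[[3]]$n), 1L) # only Schizophrenia reaches level 3
})
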