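#' Extraction precision
#'
#' `100 * TP / (TP + FP)`. Full precision is returned; use [fmt_metric()]
#' for 1-decimal display.
#'
#' @param tp,fp true/false positive counts.
#' @return percentage, or `NA` (with a warning) when `TP + FP == 0`.
#' @export
precision <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) {
    dv_warn("precision undefined: no predicted positives")
    return(NA_real_)
  }
  100 * tp / (tp + fp)
}

#' Extraction recall
#'
#' `100 * TP / (TP + FN)`.
#'
#' @param tp,fn true positive / false negative counts.
#' @return percentage, or `NA` (with a warning) when `TP + FN == 0`.
#' @export
recall <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) {
    dv_warn("recall undefined: no gold positives")
    return(NA_real_)
  }
  100 * tp / (tp + fn)
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param p,r precision and recall as percentages.
#' @return percentage, or `NA` (with a warning) when `P + R == 0` or either
#'   input is `NA`.
#' @export
f_score <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) {
    dv_warn("F-score undefined")
    return(NA_real_)
  }
  2 * p * r / (p + r)
}

#' Display rounding for metrics
#'
#' Published extraction metrics in this field are usually shown at one
#' decimal; reports are inconsistent about whether the last digit is rounded
#' half-up or truncated, so both conventions are available. Default is
#' half-up.
#'
#' @param x numeric metric(s).
#' @param digits decimals kept (default 1).
#' @param mode `"half_up"` or `"trunc"`.
#' @return rounded numeric vector.
#' @export
fmt_metric <- function(x, digits = 1, mode = c("half_up", "trunc")) {
  mode <- match.arg(mode)
  if (mode == "half_up") round_half_up(x, digits) else trunc_to(x, digits)
}

triple_keys <- function(df, what) {
  need <- c("narrative_id", "role", "canonical")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    dv_stop("%s annotations missing column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  paste(df$narrative_id, df$role, df$canonical, sep = "\r")
}

#' Evaluate predicted extractions against gold annotations
#'
#' Both sides are reduced to unique `(narrative_id, role, canonical)`
#' triples -- the deduplicated narrative-level unit at which the system is
#' scored. Per role, `TP` are triples present in both sets, `FP` predicted
#' only, `FN` gold only.
#'
#' @param gold,predicted data frames with at least `narrative_id`, `role`,
#'   `canonical` (an `event_id` column, when present on both sides, is
#'   checked for consistency across shared narrative ids).
#' @return an object of class `dv_eval`: a data frame with one row per role
#'   and columns `role`, `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`
#'   (full precision; the print method rounds).
#' @export
evaluate_extractions <- function(gold, predicted) {
  if ("event_id" %in% names(gold) && "event_id" %in% names(predicted)) {
    gmap <- unique(gold[c("narrative_id", "event_id")])
    pmap <- unique(predicted[c("narrative_id", "event_id")])
    shared <- merge(gmap, pmap, by = "narrative_id")
    bad <- shared$event_id.x != shared$event_id.y
    if (any(bad)) {
      dv_stop("narrative id(s) mapped to different events in gold vs predicted: %s",
              paste(shared$narrative_id[bad], collapse = ", "))
    }
  }
  g <- unique(triple_keys(gold, "gold"))
  p <- unique(triple_keys(predicted, "predicted"))
  rows <- lapply(c("POI", "victim"), function(role) {
    tag <- paste0("\r", role, "\r")
    gr <- g[grepl(tag, g, fixed = TRUE)]
    pr <- p[grepl(tag, p, fixed = TRUE)]
    tp <- length(intersect(gr, pr))
    fp <- length(setdiff(pr, gr))
    fn <- length(setdiff(gr, pr))
    pe <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
    re <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
    fs <- if (is.na(pe) || is.na(re) || pe + re == 0) NA_real_
          else 2 * pe * re / (pe + re)
    data.frame(role = role, tp = tp, fp = fp, fn = fn, precision = pe,
               recall = re, f_score = fs, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dv_eval", "data.frame"))
}

#' @export
print.dv_eval <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  for (cn in c("precision", "recall", "f_score")) {
    y[[cn]] <- fmt_metric(y[[cn]], digits)
  }
  cat("<dv_eval> narrative-level evaluation (percent)\n")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Absolute inter-annotator agreement
#'
#' Operationalized as intersection-over-union of the two annotators'
#' annotation triple sets: `100 * |A intersect B| / |A union B|`. An
#' alternative definition (mean of the two directed overlap rates) is
#' selectable.
#'
#' @param a,b annotation data frames (reduced to `(narrative_id, role,
#'   canonical)` triples) or plain character vectors of annotation keys.
#' @param method `"iou"` (default) or `"mean_overlap"`.
#' @return agreement percentage; `NA` with a warning when both sets are
#'   empty.
#' @export
absolute_agreement <- function(a, b, method = c("iou", "mean_overlap")) {
  method <- match.arg(method)
  ka <- if (is.data.frame(a)) unique(triple_keys(a, "annotator 1")) else unique(a)
  kb <- if (is.data.frame(b)) unique(triple_keys(b, "annotator 2")) else unique(b)
  if (!length(ka) && !length(kb)) {
    dv_warn("agreement undefined: both annotation sets empty")
    return(NA_real_)
  }
  inter <- length(intersect(ka, kb))
  if (method == "iou") {
    100 * inter / length(union(ka, kb))
  } else {
    mean(c(100 * inter / length(ka), 100 * inter / length(kb)))
  }
}

#' Corpus-level summary of extracted disorders
#'
#' Aggregates deduplicated extractions into the shape of a surveillance
#' report: event counts by role pattern, and per ICD level (1-3) and role
#' the number of unique disorder records per category with percentages of
#' the role's level total. A record lacking level `l` detail contributes
#' only to levels above `l`. Percentages are 100 x count / role-level total,
#' rounded half-up to 2 decimals (`NA` when the total is 0).
#'
#' @param extractions a `dv_extractions` object from [deduplicate()]
#'   (event-level grouping is the usual reporting unit).
#' @param n_events_total number of events in the corpus, including events
#'   without any mention; must be >= the number of events with a mention.
#' @return an object of class `dv_summary`: list with `events` (totals and
#'   role-pattern counts) and `levels` (per level, a data frame of
#'   role/category counts and percentages plus role totals).
#' @export
summarize_corpus <- function(extractions, n_events_total) {
  stopifnot(inherits(extractions, "dv_extractions"))
  ev <- extractions$events
  rec <- extractions$records
  n_with <- nrow(ev)
  if (n_events_total < n_with) {
    dv_stop("n_events_total (%d) < events with a mention (%d)",
            n_events_total, n_with)
  }
  events <- list(
    n_events_total = n_events_total,
    n_events_with_mention = n_with,
    poi_only = sum(ev$poi_any & !ev$victim_any),
    victim_only = sum(ev$victim_any & !ev$poi_any),
    both = sum(ev$both),
    pct_with_mention = if (n_events_total > 0)
      round_half_up(100 * n_with / n_events_total, 2) else NA_real_
  )
  stopifnot(events$poi_only + events$victim_only + events$both == n_with)

  levels <- list()
  for (l in 1:3) {
    col <- paste0("level", l)
    sub <- rec[!is.na(rec[[col]]), , drop = FALSE]
    role_tot <- c(POI = sum(sub$role == "POI"),
                  victim = sum(sub$role == "victim"))
    if (nrow(sub)) {
      tab <- as.data.frame(table(role = sub$role, category = sub[[col]]),
                           stringsAsFactors = FALSE)
      tab <- tab[tab$Freq > 0, , drop = FALSE]
      names(tab)[3L] <- "n"
      tab$role_total <- role_tot[tab$role]
      tab$pct <- round_half_up(100 * tab$n / tab$role_total, 2)
      # summation closure: per (level, role) the categories account for
      # every record mapped at this level
      agg <- tapply(tab$n, tab$role, sum)
      stopifnot(all(agg == role_tot[names(agg)]))
      tab <- tab[order(tab$role, -tab$n, tab$category, method = "radix"), ,
                 drop = FALSE]
      rownames(tab) <- NULL
    } else {
      tab <- data.frame(role = character(), category = character(),
                        n = integer(), role_total = integer(),
                        pct = numeric(), stringsAsFactors = FALSE)
    }
    levels[[l]] <- tab
  }
  structure(list(events = events, levels = levels), class = "dv_summary")
}

#' @export
print.dv_summary <- function(x, max_rows = 10, ...) {
  e <- x$events
  cat("<dv_summary>\n")
  cat(sprintf("  events: %d total, %d with a mention (%s%%): %d POI-only, %d victim-only, %d both\n",
              e$n_events_total, e$n_events_with_mention,
              format(e$pct_with_mention), e$poi_only, e$victim_only, e$both))
  for (l in 1:3) {
    tab <- x$levels[[l]]
    cat(sprintf("  level %d: %d records (POI %d, victim %d)\n", l,
                sum(tab$n), sum(tab$n[tab$role == "POI"]),
                sum(tab$n[tab$role == "victim"])))
    if (nrow(tab)) {
      print(utils::head(tab, max_rows), row.names = FALSE)
      if (nrow(tab) > max_rows) cat(sprintf("  ... %d more rows\n",
                                            nrow(tab) - max_rows))
    }
  }
  invisible(x)
}
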