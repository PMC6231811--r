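# Extended ICD-10 mapping schema: 26 first-level categories (18 ICD-10
# chapter-level groups + 8 custom ones: four psychotropic-medication classes,
# drug prescription abuse, substance abuse (unspecified), traumatic brain
# injury, unspecified drug-induced disorder), with reconstructed second- and
# third-level tables. Fourth-level rubrics are stored directly as third-level
# categories (the reporting merge), so a record carries at most three levels.

#' Read the mapping schema
#'
#' The schema ships as two editable TSV tables: `categories.tsv`
#' (`level`, `name`, `parent`) and `term_groups.tsv` (`term`, `category`).
#' Term groups hold the canonical disorder names that trigger a category;
#' a canonical name is assigned the deepest category whose term group
#' contains it and the ancestor chain is filled backward.
#'
#' @param dir directory with the two TSV files; defaults to the shipped
#'   schema.
#' @return an object of class `dv_schema`.
#' @export
read_schema <- function(dir = dv_schema_dir()) {
  cats <- utils::read.delim(file.path(dir, "categories.tsv"),
                            colClasses = "character")
  terms <- utils::read.delim(file.path(dir, "term_groups.tsv"),
                             colClasses = "character")
  need <- setdiff(c("level", "name", "parent"), names(cats))
  if (length(need)) dv_stop("categories.tsv missing column(s): %s",
                            paste(need, collapse = ", "))
  need <- setdiff(c("term", "category"), names(terms))
  if (length(need)) dv_stop("term_groups.tsv missing column(s): %s",
                            paste(need, collapse = ", "))
  cats$level <- as.integer(cats$level)
  cats$parent[is.na(cats$parent)] <- ""
  schema <- structure(list(categories = cats, terms = terms), class = "dv_schema")
  qc <- validate_schema(schema)
  schema$qc <- qc

  # lookup structures; parent maps are per level because the same category
  # name may legitimately appear at two levels (self-named pass-through)
  lv <- split(cats$name, cats$level)
  parent <- lapply(2:3, function(l) {
    sub <- cats[cats$level == l, , drop = FALSE]
    stats::setNames(sub$parent, sub$name)
  })
  names(parent) <- c("2", "3")
  term_level <- cats$level[match(terms$category, cats$name)]
  tm <- new.env(parent = emptyenv())
  ord <- order(term_level) # deepest written last wins the env slot
  for (i in ord) {
    tm[[tolower(terms$term[i])]] <-
      list(category = terms$category[i], level = term_level[i])
  }
  schema$levels <- lv
  schema$parent <- parent
  schema$term_map <- tm
  schema
}

#' Validate the mapping schema
#'
#' Checks the structural invariants: unique category names per level, every
#' level-2/3 category linked to an existing parent one level up, term-group
#' terms unique within a level and pointing at existing categories. Violations
#' raise errors; the returned report carries per-level category counts and
#' term-group sizes.
#'
#' @param schema a `dv_schema` object (or a bare list with `categories` and
#'   `terms` data frames).
#' @return a list of class `dv_schema_qc` with elements `n_categories`
#'   (named by level), `n_terms`, and `terms_per_level`.
#' @export
validate_schema <- function(schema) {
  cats <- schema$categories
  terms <- schema$terms
  if (!all(cats$level %in% 1:3)) {
    dv_stop("category levels must be 1, 2 or 3")
  }
  for (l in sort(unique(cats$level))) {
    nm <- cats$name[cats$level == l]
    if (anyDuplicated(nm)) {
      dv_stop("duplicate level-%d category: %s", l,
              nm[duplicated(nm)][1L])
    }
  }
  for (l in 2:3) {
    sub <- cats[cats$level == l, , drop = FALSE]
    up <- cats$name[cats$level == l - 1L]
    orphan <- !(sub$parent %in% up)
    if (any(orphan)) {
      dv_stop("orphan level-%d category (parent not at level %d): %s",
              l, l - 1L, sub$name[orphan][1L])
    }
  }
  if (any(cats$level == 1L & nzchar(cats$parent))) {
    dv_stop("level-1 categories must not have a parent")
  }
  unknown <- !(terms$category %in% cats$name)
  if (any(unknown)) {
    dv_stop("term group references unknown category: %s",
            terms$category[unknown][1L])
  }
  tl <- cats$level[match(terms$category, cats$name)]
  for (l in 1:3) {
    tt <- tolower(terms$term[tl == l])
    if (anyDuplicated(tt)) {
      dv_stop("term '%s' appears in more than one level-%d term group",
              tt[duplicated(tt)][1L], l)
    }
  }
  structure(list(
    n_categories = table(factor(cats$level, levels = 1:3)),
    n_terms = nrow(terms),
    terms_per_level = table(factor(tl, levels = 1:3))
  ), class = "dv_schema_qc")
}

#' @export
print.dv_schema_qc <- function(x, ...) {
  cat("<dv_schema_qc>\n")
  cat(sprintf("  categories: level 1 = %d, level 2 = %d, level 3 = %d\n",
              x$n_categories[["1"]], x$n_categories[["2"]],
              x$n_categories[["3"]]))
  cat(sprintf("  trigger terms: %d\n", x$n_terms))
  invisible(x)
}

#' @export
print.dv_schema <- function(x, ...) {
  cat(sprintf("<dv_schema> %d / %d / %d categories at levels 1 / 2 / 3, %d trigger terms\n",
              sum(x$categories$level == 1L), sum(x$categories$level == 2L),
              sum(x$categories$level == 3L), nrow(x$terms)))
  invisible(x)
}

#' Path to the shipped schema directory
#' @return directory path inside the installed package.
#' @export
dv_schema_dir <- function() {
  system.file("extdata", "schema", package = "dvmh", mustWork = TRUE)
}

# markers that let an otherwise unlisted name fall back to the generic
# level-1 category
GENERIC_MARKER <- "mental|psychiatric|psycholog"

#' Map canonical disorder names into the ICD schema
#'
#' Each canonical name is assigned the deepest category whose term group
#' contains it (case-insensitively); levels above are filled backward along
#' the parent chain and levels below the assignment are `NA`. A name absent
#' from every term group maps to the generic level-1 category "Unspecified
#' mental disorder" when it carries a generic mental-health marker
#' ("mental", "psychiatric", "psychological"); otherwise it is an error --
#' unmapped names are never silently dropped.
#'
#' @param canonical character vector of canonical disorder names.
#' @param schema a `dv_schema` from [read_schema()].
#' @return a data frame with columns `canonical`, `level1`, `level2`,
#'   `level3`.
#' @export
map_to_icd <- function(canonical, schema) {
  stopifnot(inherits(schema, "dv_schema"))
  uniq <- unique(canonical)
  l1 <- l2 <- l3 <- rep(NA_character_, length(uniq))
  unmapped <- character()
  for (i in seq_along(uniq)) {
    hit <- schema$term_map[[tolower(uniq[i])]]
    if (is.null(hit)) {
      if (grepl(GENERIC_MARKER, uniq[i], ignore.case = TRUE)) {
        l1[i] <- "Unspecified mental disorder"
      } else {
        unmapped <- c(unmapped, uniq[i])
      }
      next
    }
    chain <- rep(NA_character_, 3L)
    cat <- hit$category
    for (l in seq(hit$level, 1L)) {
      chain[l] <- cat
      if (l > 1L) cat <- schema$parent[[as.character(l)]][[cat]]
    }
    l1[i] <- chain[1L]; l2[i] <- chain[2L]; l3[i] <- chain[3L]
  }
  if (length(unmapped)) {
    dv_stop("unmapped canonical name(s): %s",
            paste(unmapped, collapse = ", "))
  }
  j <- match(canonical, uniq)
  data.frame(canonical = canonical, level1 = l1[j], level2 = l2[j],
             level3 = l3[j], stringsAsFactors = FALSE)
}

#' Map extracted mentions to disorder records
#'
#' Attaches the level-1/2/3 categories to each mention. Unmapped canonical
#' names either raise an error (`on_unmapped = "error"`) or are removed from
#' the records and reported in the `"unmapped"` attribute, a QC data frame
#' listing each offending name and its frequency (`on_unmapped = "report"`).
#'
#' @param mentions mention data frame from [extract_mentions()].
#' @param schema a `dv_schema`.
#' @param on_unmapped `"error"` or `"report"`.
#' @return a record data frame: `event_id`, `narrative_id`, `role`,
#'   `canonical`, `level1`, `level2`, `level3`.
#' @export
map_records <- function(mentions, schema, on_unmapped = c("error", "report")) {
  on_unmapped <- match.arg(on_unmapped)
  base_cols <- c("event_id", "narrative_id", "role", "canonical")
  stopifnot(all(base_cols %in% names(mentions)))
  out <- mentions[base_cols]
  if (nrow(out) == 0L) {
    out$level1 <- character(); out$level2 <- character()
    out$level3 <- character()
    return(out)
  }
  mapped <- tryCatch(map_to_icd(out$canonical, schema), error = identity)
  if (inherits(mapped, "error")) {
    if (on_unmapped == "error") stop(mapped)
    ok <- vapply(out$canonical, function(cn) {
      !is.null(schema$term_map[[tolower(cn)]]) ||
        grepl(GENERIC_MARKER, cn, ignore.case = TRUE)
    }, logical(1))
    bad <- out$canonical[!ok]
    out <- out[ok, , drop = FALSE]
    mapped <- map_to_icd(out$canonical, schema)
    qc <- as.data.frame(table(bad), stringsAsFactors = FALSE)
    names(qc) <- c("canonical", "n")
    res <- cbind(out, mapped[c("level1", "level2", "level3")])
    rownames(res) <- NULL
    attr(res, "unmapped") <- qc
    return(res)
  }
  res <- cbind(out, mapped[c("level1", "level2", "level3")])
  rownames(res) <- NULL
  attr(res, "unmapped") <-
    data.frame(canonical = character(), n = integer(),
               stringsAsFactors = FALSE)
  res
}

#' Deduplicate disorder records
#'
#' Narrative-level unification: within the grouping unit each (role,
#' canonical disorder) pair is kept once. Event-level grouping unions the
#' records of all narratives of an event. Per-event role flags are computed
#' either way.
#'
#' @param records record data frame from [map_records()] (the `records`
#'   element of a previous [deduplicate()] result is also accepted, making
#'   the operation idempotent).
#' @param by `"narrative"` or `"event"`.
#' @return an object of class `dv_extractions`: a list with `records` (the
#'   deduplicated records) and `events` (one row per event with logical
#'   `poi_any`, `victim_any`, `both`).
#' @export
deduplicate <- function(records, by = c("narrative", "event")) {
  by <- match.arg(by)
  stopifnot(all(c("event_id", "role", "canonical") %in% names(records)))
  if (by == "narrative") {
    stopifnot("narrative_id" %in% names(records))
    key <- paste(records$event_id, records$narrative_id, records$role,
                 records$canonical, sep = "\r")
  } else {
    key <- paste(records$event_id, records$role, records$canonical,
                 sep = "\r")
  }
  rec <- records[!duplicated(key), , drop = FALSE]
  if (by == "event") rec$narrative_id <- NULL
  rownames(rec) <- NULL

  ev_ids <- unique(rec$event_id)
  poi_any <- vapply(ev_ids, function(e) {
    any(rec$role[rec$event_id == e] == "POI")
  }, logical(1), USE.NAMES = FALSE)
  victim_any <- vapply(ev_ids, function(e) {
    any(rec$role[rec$event_id == e] == "victim")
  }, logical(1), USE.NAMES = FALSE)
  events <- data.frame(event_id = ev_ids, poi_any = poi_any,
                       victim_any = victim_any,
                       both = poi_any & victim_any,
                       stringsAsFactors = FALSE)
  structure(list(records = rec, events = events, by = by),
            class = "dv_extractions")
}

#' @export
print.dv_extractions <- function(x, ...) {
  cat(sprintf(
    "<dv_extractions> %d unique records (%s level) across %d events\n",
    nrow(x$records), x$by, nrow(x$events)))
  cat(sprintf("  events: %d POI-only, %d victim-only, %d both\n",
              sum(x$events$poi_any & !x$events$victim_any),
              sum(x$events$victim_any & !x$events$poi_any),
              sum(x$events$both)))
  invisible(x)
}
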