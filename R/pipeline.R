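#' Run the full extraction pipeline on a corpus
#'
#' Tokenize, gazetteer-match and apply the role rules to every narrative,
#' standardize and map the extracted mentions into the ICD schema, then
#' deduplicate at narrative and event level.
#'
#' @param narratives narrative data frame (`event_id`, `narrative_id`,
#'   `text`).
#' @param gazetteers,rules,schema resources; default to the shipped set.
#' @param on_unmapped passed to [map_records()].
#' @return a list of class `dv_result`: `mentions` (raw role-attributed
#'   mentions with offsets), `narrative` and `event` (`dv_extractions`
#'   deduplicated at the respective level).
#' @export
dv_pipeline <- function(narratives,
                        gazetteers = load_gazetteers(),
                        rules = parse_rules(gazetteers = gazetteers),
                        schema = read_schema(),
                        on_unmapped = "error") {
  mentions <- extract_mentions(narratives, gazetteers, rules)
  records <- map_records(mentions, schema, on_unmapped = on_unmapped)
  structure(list(mentions = mentions,
                 narrative = deduplicate(records, by = "narrative"),
                 event = deduplicate(records, by = "event")),
            class = "dv_result")
}

#' @export
print.dv_result <- function(x, ...) {
  cat(sprintf("<dv_result> %d mentions -> %d narrative-level / %d event-level records\n",
              nrow(x$mentions), nrow(x$narrative$records),
              nrow(x$event$records)))
  invisible(x)
}
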