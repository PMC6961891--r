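#' Convert a ranking to a serializable report
#'
#' Flattens a `shift_ranking` into plain lists/data.frames: the ranked
#' candidate table, break weights with their decision-rule labels, and
#' the per-segment parameter table of the best combination (segment
#' years, r with standard error, K with standard error). The schema is
#' versioned; golden-file tests pin it.
#'
#' @param ranking A `shift_ranking` from [detect_shifts].
#' @return A named list ready for [jsonlite::write_json].
#' @export
shift_report <- function(ranking) {
  stopifnot(inherits(ranking, "shift_ranking"))
  cand <- ranking$candidates
  list(
    schema_version = "1.0",
    criterion = ranking$config$criterion,
    config = ranking$config,
    series = list(year = ranking$series$year,
                  abundance = ranking$series$abundance),
    n_scored = ranking$n_scored,
    n_pruned = ranking$n_pruned,
    n_unscorable = ranking$n_unscorable,
    best = list(
      breaks = as.integer(ranking$top_breaks),
      total_ic = cand$total_ic[1L]
    ),
    candidates = lapply(seq_len(nrow(cand)), function(i) {
      list(rank = cand$rank[i],
           breaks = as.integer(cand$breaks[[i]]),
           total_ic = cand$total_ic[i],
           delta_ic = cand$delta_ic[i],
           weight = cand$weight[i],
           in_equivalence = cand$in_equivalence[i])
    }),
    break_weights = ranking$break_table,
    segments = ranking$segments
  )
}

#' Write a JSON shift-detection report
#'
#' @param ranking A `shift_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(ranking, path) {
  jsonlite::write_json(shift_report(ranking), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(path)
}

#' Detect shifts in a CSV time series end to end
#'
#' Convenience wrapper: read, detect, optionally write the JSON report,
#' and return the ranking.
#'
#' @param csv_path Input CSV (year, abundance).
#' @param json_path Optional JSON report output path.
#' @param ... Passed to [detect_shifts].
#' @return The `shift_ranking`, invisibly.
#' @export
detect_shifts_csv <- function(csv_path, json_path = NULL, ...) {
  ranking <- detect_shifts(read_series_csv(csv_path), ...)
  if (!is.null(json_path)) write_report_json(ranking, json_path)
  invisible(ranking)
}
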