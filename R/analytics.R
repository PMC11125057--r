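#' Bundle detection results into a monitoring series
#'
#' A monitoring series is the time-ordered output of repeatedly probing one
#' tree (e.g. one 30 s recording every 15 minutes for a week).
#'
#' @param results List of `detection_result` objects from [detect()].
#' @param tree_id Label for the monitored tree.
#' @return An object of class `"monitoring_series"`.
#' @export
monitoring_series <- function(results, tree_id = "tree") {
  ok <- vapply(results, inherits, logical(1), what = "detection_result")
  if (!all(ok)) stop("results must all be detection_result objects", call. = FALSE)
  ts <- do.call(c, lapply(results, function(r) r$timestamp))
  if (length(ts) > 1L && !anyNA(ts)) {
    if (any(diff(as.numeric(ts)) < 0)) {
      stop("result timestamps must be non-decreasing", call. = FALSE)
    }
  }
  structure(list(results = results, tree_id = tree_id),
            class = "monitoring_series")
}

series_counts <- function(series) {
  vapply(series$results, function(r) r$count, integer(1))
}

#' Cumulative impulse counts over a series
#'
#' The running sum of per-recording counts; rejected recordings contribute
#' zero. Infested trees show a steadily climbing curve, healthy trees long
#' plateaus — the slope is the at-a-glance severity read-out.
#'
#' @param series A [monitoring_series].
#' @return Integer vector of cumulative counts (empty for an empty series).
#' @export
cumulative_counts <- function(series) {
  counts <- series_counts(series)
  if (length(counts) == 0L) return(integer(0))
  cumsum(counts)
}

#' Impulse activity by hour of day
#'
#' Bins every counted impulse by the local hour of its absolute timestamp
#' (recording capture time plus offset within the recording). Larvae feed
#' around the clock but typically more intensely in the hours when the sun
#' warms the trunk, so this profile is a useful biological sanity check.
#'
#' @param series A [monitoring_series].
#' @return Integer vector of 24 counts, named `"0"` to `"23"`.
#' @export
hourly_activity <- function(series) {
  counts <- rep(0L, 24L)
  names(counts) <- as.character(0:23)
  for (r in series$results) {
    if (r$count == 0L) next
    ts <- r$events$timestamp
    if (is.null(ts) || anyNA(ts)) {
      stop("hourly activity needs event timestamps (recording metadata missing)",
           call. = FALSE)
    }
    h <- as.POSIXlt(ts, tz = "UTC")$hour
    tab <- table(factor(h, levels = 0:23))
    counts <- counts + as.integer(tab)
  }
  counts
}

#' Histogram of counted-impulse durations
#'
#' @param series A [monitoring_series].
#' @param bin_width_ms Bin width in milliseconds (default 1).
#' @return A list with `breaks` (bin lower edges, ms), `counts`, and
#'   `modal_bin_ms` (lower edge of the most populated bin, `NA` when there
#'   are no events).
#' @export
duration_histogram <- function(series, bin_width_ms = 1) {
  if (bin_width_ms <= 0) stop("bin_width_ms must be > 0", call. = FALSE)
  durs <- unlist(lapply(series$results, function(r) r$events$duration_ms))
  if (length(durs) == 0L) {
    return(list(breaks = numeric(0), counts = integer(0), modal_bin_ms = NA_real_))
  }
  bins <- floor(durs / bin_width_ms)
  lo <- min(bins)
  hi <- max(bins)
  counts <- tabulate(bins - lo + 1L, nbins = hi - lo + 1L)
  breaks <- (lo:hi) * bin_width_ms
  list(breaks = breaks, counts = counts,
       modal_bin_ms = breaks[which.max(counts)])
}

#' Duration-energy pairs of counted impulses
#'
#' One `(duration_ms, energy_db)` pair per counted impulse. With several
#' larvae at different distances from the probe, the pairs cluster by
#' energy at similar durations.
#'
#' @param series A [monitoring_series].
#' @return Data frame with columns `duration_ms` and `energy_db`.
#' @export
duration_energy_pairs <- function(series) {
  parts <- lapply(series$results, function(r) {
    r$events[, c("duration_ms", "energy_db"), drop = FALSE]
  })
  out <- do.call(rbind, c(parts, list(
    data.frame(duration_ms = numeric(0), energy_db = numeric(0)))))
  rownames(out) <- NULL
  out
}

#' Classify a tree from its monitoring series
#'
#' A simple rate heuristic on the cumulative-curve slope: with fewer than
#' `min_accepted` accepted recordings the evidence is `"indeterminate"`;
#' otherwise the tree is `"infested"` when the mean impulse count per
#' accepted recording reaches `rate_threshold`, else `"healthy"`. Rejected
#' recordings carry no counting information and are excluded from the
#' denominator. Both knobs are heuristics to be tuned per deployment.
#'
#' @param series A [monitoring_series].
#' @param rate_threshold Impulses per accepted recording (default 0.5).
#' @param min_accepted Minimum accepted recordings before committing to a
#'   label (default 20).
#' @return `"infested"`, `"healthy"` or `"indeterminate"`.
#' @export
classify_tree <- function(series, rate_threshold = 0.5, min_accepted = 20L) {
  statuses <- vapply(series$results, function(r) r$status, character(1))
  accepted_n <- sum(statuses == "accepted")
  if (accepted_n < min_accepted) return("indeterminate")
  total <- sum(series_counts(series))
  if (total / accepted_n >= rate_threshold) "infested" else "healthy"
}

#' Full tree-level report
#'
#' @param series A [monitoring_series].
#' @param rate_threshold,min_accepted Passed to [classify_tree()].
#' @param bin_width_ms Passed to [duration_histogram()].
#' @return An object of class `"tree_report"`: totals, acceptance counts,
#'   impulses per accepted recording, classification, hourly activity
#'   (`NULL` when timestamps are unavailable) and the duration histogram.
#' @export
tree_report <- function(series, rate_threshold = 0.5, min_accepted = 20L,
                        bin_width_ms = 1) {
  statuses <- vapply(series$results, function(r) r$status, character(1))
  counts <- series_counts(series)
  accepted_n <- sum(statuses == "accepted")
  hourly <- tryCatch(hourly_activity(series), error = function(e) NULL)
  structure(
    list(
      tree_id = series$tree_id,
      total_impulses = sum(counts),
      accepted_n = accepted_n,
      rejected_n = sum(statuses == "rejected"),
      impulses_per_accepted_recording =
        if (accepted_n > 0L) sum(counts) / accepted_n else NA_real_,
      classification = classify_tree(series, rate_threshold, min_accepted),
      hourly_counts = hourly,
      duration_histogram = duration_histogram(series, bin_width_ms)
    ),
    class = "tree_report"
  )
}

#' @export
print.tree_report <- function(x, ...) {
  cat(sprintf("<tree_report> %s: %s\n", x$tree_id, x$classification))
  cat(sprintf("  %d impulses over %d accepted (+%d rejected) recordings (%.2f / recording)\n",
              x$total_impulses, x$accepted_n, x$rejected_n,
              x$impulses_per_accepted_recording))
  invisible(x)
}

#' Serialize a tree report
#'
#' Writes the report as JSON, and optionally the cumulative-count and
#' hourly tables as CSV for external plotting.
#'
#' @param report A `tree_report`.
#' @param series The [monitoring_series] the report came from (needed for
#'   the cumulative CSV).
#' @param json_path,cumulative_csv,hourly_csv Output paths; `NULL` skips.
#' @return `report`, invisibly.
#' @export
write_tree_report <- function(report, series = NULL, json_path = NULL,
                              cumulative_csv = NULL, hourly_csv = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(tree_id = report$tree_id,
           total_impulses = report$total_impulses,
           accepted_n = report$accepted_n,
           rejected_n = report$rejected_n,
           impulses_per_accepted_recording =
             report$impulses_per_accepted_recording,
           classification = report$classification,
           hourly_counts = report$hourly_counts,
           duration_histogram = report$duration_histogram[c("breaks", "counts")]),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(cumulative_csv)) {
    if (is.null(series)) stop("cumulative CSV needs the series", call. = FALSE)
    cum <- cumulative_counts(series)
    utils::write.csv(
      data.frame(recording = seq_along(cum), cumulative_impulses = cum),
      cumulative_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(hourly_csv) && !is.null(report$hourly_counts)) {
    utils::write.csv(
      data.frame(hour = 0:23, impulses = as.integer(report$hourly_counts)),
      hourly_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
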