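#' Build prediction/truth pairs
#'
#' @param predicted Integer vector of detector counts `y_i`.
#' @param true Integer vector of annotated counts `x_i`.
#' @param file Optional file names.
#' @param status Optional `"accepted"`/`"rejected"` per recording
#'   (default all accepted).
#' @return A data frame with columns `file`, `predicted`, `true`, `status`.
#' @export
eval_pairs <- function(predicted, true, file = NULL, status = NULL) {
  n <- length(predicted)
  if (length(true) != n) stop("predicted and true differ in length", call. = FALSE)
  if (any(predicted < 0) || any(true < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  data.frame(
    file = if (is.null(file)) sprintf("rec_%d", seq_len(n)) else as.character(file),
    predicted = as.integer(predicted),
    true = as.integer(true),
    status = if (is.null(status)) rep("accepted", n) else as.character(status),
    stringsAsFactors = FALSE
  )
}

#' Mean absolute error of impulse counts
#'
#' \eqn{\mathrm{MAE} = \sum_i |y_i - x_i| / n}, in impulses per file.
#'
#' @param pairs Data frame from [eval_pairs()] (or any frame with
#'   `predicted` and `true` columns).
#' @return MAE.
#' @export
count_mae <- function(pairs) {
  if (nrow(pairs) == 0L) stop("cannot compute MAE of zero pairs", call. = FALSE)
  mean(abs(pairs$predicted - pairs$true))
}

#' Root-mean-square error of impulse counts
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (y_i - x_i)^2 / n}}, in impulses per
#' file. More sensitive than MAE to the occasional large divergence (e.g.
#' counting applied to a rainy recording).
#'
#' @inheritParams count_mae
#' @return RMSE.
#' @export
count_rmse <- function(pairs) {
  if (nrow(pairs) == 0L) stop("cannot compute RMSE of zero pairs", call. = FALSE)
  sqrt(mean((pairs$predicted - pairs$true)^2))
}

#' Per-recording binary classification metrics
#'
#' Each recording is labeled positive ("pulses") when its count exceeds
#' zero, on both the predicted and the annotated side. Precision
#' \eqn{P = T_p / (T_p + F_p)}, recall \eqn{R = T_p / (T_p + F_n)} and
#' \eqn{F_1 = 2PR / (P + R)} are reported for both classes ("pulses" and
#' "no_pulses"), together with accuracy, per-class support, and macro /
#' micro averages. Metrics with a zero denominator are reported as 0 and
#' flagged.
#'
#' @param pairs Data frame from [eval_pairs()].
#' @param policy `"all"` evaluates every pair; `"accepted_only"` first drops
#'   pairs whose `status` is `"rejected"`.
#' @return A list with `per_class` (data frame: class, precision, recall,
#'   f1, support), `accuracy`, `macro` and `micro` average rows, `n` (pairs
#'   evaluated) and `flags` (character vector of zero-denominator notes).
#' @export
binary_metrics <- function(pairs, policy = c("all", "accepted_only")) {
  policy <- match.arg(policy)
  if (policy == "accepted_only") pairs <- pairs[pairs$status != "rejected", ]
  if (nrow(pairs) == 0L) stop("no pairs left to evaluate", call. = FALSE)

  flags <- character(0)
  prf <- function(pred_pos, true_pos, class_name) {
    tp <- sum(pred_pos & true_pos)
    fp <- sum(pred_pos & !true_pos)
    fn <- sum(!pred_pos & true_pos)
    p <- if (tp + fp == 0L) {
      flags <<- c(flags, sprintf("%s: precision denominator zero", class_name)); 0
    } else tp / (tp + fp)
    r <- if (tp + fn == 0L) {
      flags <<- c(flags, sprintf("%s: recall denominator zero", class_name)); 0
    } else tp / (tp + fn)
    f1 <- if (p + r == 0) {
      flags <<- c(flags, sprintf("%s: F1 denominator zero", class_name)); 0
    } else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
  }

  pred_pos <- pairs$predicted > 0L
  true_pos <- pairs$true > 0L
  pos <- prf(pred_pos, true_pos, "pulses")
  neg <- prf(!pred_pos, !true_pos, "no_pulses")

  per_class <- data.frame(
    class = c("no_pulses", "pulses"),
    precision = c(neg[["precision"]], pos[["precision"]]),
    recall = c(neg[["recall"]], pos[["recall"]]),
    f1 = c(neg[["f1"]], pos[["f1"]]),
    support = c(sum(!true_pos), sum(true_pos))
  )
  tp_all <- pos[["tp"]] + neg[["tp"]]
  fp_all <- pos[["fp"]] + neg[["fp"]]
  fn_all <- pos[["fn"]] + neg[["fn"]]
  micro_p <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else 0
  micro_r <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else 0
  micro_f1 <- if (micro_p + micro_r > 0) 2 * micro_p * micro_r / (micro_p + micro_r) else 0

  list(
    per_class = per_class,
    accuracy = mean(pred_pos == true_pos),
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    micro = c(precision = micro_p, recall = micro_r, f1 = micro_f1),
    n = nrow(pairs),
    flags = flags
  )
}

#' Evaluate the detector against annotations over a folder of recordings
#'
#' Runs [detect()] on every recording, joins the counts to the annotation
#' table by file name, and computes MAE, RMSE and the per-recording binary
#' metrics under one of three policies:
#' \describe{
#'   \item{reject_all}{energy gate active; rejected recordings are scored
#'     with a predicted count of 0 and every pair is evaluated.}
#'   \item{accepted_only}{energy gate active; rejected recordings are
#'     dropped before computing the metrics.}
#'   \item{no_reject}{energy gate disabled (`theta1 = Inf`); counting is
#'     applied to every recording, noisy or not.}
#' }
#'
#' @param recordings A list of [recording] objects (with metadata, so file
#'   names are known) or a character vector of WAV paths.
#' @param annotations Annotation data frame from [read_annotations()] (or
#'   equivalent with `file` and `true_count` columns).
#' @param cfg A [detector_config].
#' @param policy One of `"reject_all"`, `"accepted_only"`, `"no_reject"`.
#' @return An object of class `"eval_report"`: a list with `policy`,
#'   `pairs` (per-file table: file, predicted, true, status), `mae`,
#'   `rmse`, `binary` (see [binary_metrics()]), `n_discarded` (recordings
#'   the energy gate dropped) and `n_evaluated`.
#' @export
evaluate_folder <- function(recordings, annotations, cfg,
                            policy = c("reject_all", "accepted_only",
                                       "no_reject")) {
  policy <- match.arg(policy)
  if (is.character(recordings)) {
    recordings <- lapply(recordings, read_recording)
  }
  run_cfg <- cfg
  if (policy == "no_reject") run_cfg$theta1 <- Inf
  results <- lapply(recordings, detect, cfg = run_cfg)

  files <- vapply(results, function(r) r$file, character(1))
  if (anyNA(files)) {
    stop("all recordings need file-name metadata to join with annotations",
         call. = FALSE)
  }
  idx <- match(files, annotations$file)
  if (anyNA(idx)) {
    stop(sprintf("no annotation for file(s): %s",
                 paste(files[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  pairs <- eval_pairs(
    predicted = vapply(results, function(r) r$count, integer(1)),
    true = annotations$true_count[idx],
    file = files,
    status = vapply(results, function(r) r$status, character(1))
  )
  n_discarded <- sum(pairs$status == "rejected")
  scored <- if (policy == "accepted_only") {
    pairs[pairs$status != "rejected", ]
  } else {
    pairs
  }
  structure(
    list(policy = policy, pairs = pairs,
         mae = count_mae(scored), rmse = count_rmse(scored),
         binary = binary_metrics(scored, "all"),
         n_discarded = n_discarded, n_evaluated = nrow(scored)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> policy %s: %d evaluated, %d discarded by the energy gate\n",
              x$policy, x$n_evaluated, x$n_discarded))
  cat(sprintf("  MAE %.3f  RMSE %.3f (impulses/file)\n", x$mae, x$rmse))
  cat(sprintf("  accuracy %.3f\n", x$binary$accuracy))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the metrics as JSON and the per-file table as CSV
#' (`file,predicted,true,status`).
#'
#' @param report An `eval_report`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(policy = report$policy, mae = report$mae, rmse = report$rmse,
           accuracy = report$binary$accuracy,
           per_class = report$binary$per_class,
           macro = as.list(report$binary$macro),
           micro = as.list(report$binary$micro),
           n_discarded = report$n_discarded,
           n_evaluated = report$n_evaluated),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$pairs, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
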