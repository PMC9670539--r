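# Response rescaling, deviation-from-normative-model scoring, aggregation.

#' Rescale a raw slider coordinate to the 0-10 response scale
#'
#' Affine map of the recorded slider coordinate onto `[0, 10]`, anchored so
#' that 10 means "completely sure jar B" (matching the normative scale, which
#' is the posterior for jar B). When the bar is drawn with jar B at the left
#' end (`orientation = "B-left"`) the map is flipped.
#'
#' @param raw_coordinate Recorded coordinate(s), within `[bar_min, bar_max]`.
#' @param bar_min,bar_max Extent of the slider in raw units, `bar_min < bar_max`.
#' @param orientation `"A-left"` (default) or `"B-left"`.
#' @return Rescaled response(s) `Y` in `[0, 10]`.
#' @examples
#' rescale_response(0, 0, 600)          # 0   (sure jar A)
#' rescale_response(300, 0, 600)        # 5
#' rescale_response(0, 0, 600, "B-left")# 10
#' @export
rescale_response <- function(raw_coordinate, bar_min, bar_max,
                             orientation = c("A-left", "B-left")) {
  orientation <- match.arg(orientation)
  if (!(bar_min < bar_max)) stop("`bar_min` must be < `bar_max`", call. = FALSE)
  bad <- which(raw_coordinate < bar_min | raw_coordinate > bar_max)
  if (length(bad)) {
    stop(sprintf("raw coordinate outside bar extent [%g, %g] at index: %s",
                 bar_min, bar_max, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  y <- 10 * (raw_coordinate - bar_min) / (bar_max - bar_min)
  if (orientation == "B-left") y <- 10 - y
  y
}

#' Score responses against the normative model
#'
#' Joins trial-level responses to the task's normative posterior trajectory
#' and computes the deviation score for every trial:
#' `deviation = |Y - 10 * posterior|`. The signed difference
#' `Y - 10 * posterior` is kept as an auxiliary column for direction
#' analyses; all downstream models use the unsigned score.
#'
#' @param responses Data frame with columns `participant_id`, `group`,
#'   `jar_ratio`, `content`, `series_id`, `position`, `Y`.
#' @param task A `beads_task` the responses were collected under.
#' @param prior Prior probability of jar B.
#' @return The input with added columns `normative` (posterior in `[0, 1]`),
#'   `deviation` and `signed_deviation`.
#' @export
deviation_table <- function(responses, task, prior = 0.5) {
  .assert_cols(responses, c("participant_id", "group", "jar_ratio", "content",
                            "series_id", "position", "Y"), "`responses`")
  if (any(responses$Y < 0 | responses$Y > 10, na.rm = TRUE)) {
    stop("`Y` outside [0, 10]; rescale responses first", call. = FALSE)
  }
  norm <- do.call(rbind, lapply(task$blocks, function(blk) {
    do.call(rbind, lapply(blk$series, function(s) {
      tr <- trajectory(s, blk$p_dominant, prior)
      data.frame(jar_ratio = blk$jar_ratio, content = blk$content,
                 series_id = s$series_id, position = tr$position,
                 normative = tr$posterior, stringsAsFactors = FALSE)
    }))
  }))
  key <- function(d) paste(d$jar_ratio, d$content, d$series_id, d$position, sep = "|")
  idx <- match(key(responses), key(norm))
  if (anyNA(idx)) {
    offenders <- unique(key(responses)[is.na(idx)])
    stop("responses reference unknown task cells (jar_ratio|content|series|position): ",
         paste(utils::head(offenders, 10L), collapse = "; "), call. = FALSE)
  }
  out <- responses
  out$normative <- norm$normative[idx]
  out$signed_deviation <- out$Y - 10 * out$normative
  out$deviation <- abs(out$signed_deviation)
  out
}

.AGG_LEVELS <- c("global-condition", "series-mean", "last-position", "mirror-pair")

# mirror pairs: the two jar-ratio series of each block
.MIRROR_PAIRS <- list("60:40" = c(1L, 4L), "80:20" = c(6L, 7L))

#' Per-participant deviation aggregates
#'
#' Computes the participant-level summaries used by the correlation battery,
#' always separated by content and jar-ratio condition:
#' * `global-condition` -- mean over all series and positions of a
#'   jar-ratio x content cell;
#' * `series-mean` -- mean over the 10 positions of each series;
#' * `last-position` -- the position-10 score of each series (the trial with
#'   the most available information);
#' * `mirror-pair` -- the average of the two jar-ratio series of a block
#'   (series 1 and 4 in 60:40; series 6 and 7 in 80:20), computed as the
#'   mean of the two series means.
#'
#' Requested cells with no data are emitted with `NA` and flagged via the
#' `missing` column rather than dropped.
#'
#' @param records A deviation table from [deviation_table()].
#' @param level Aggregation level, one of the four above.
#' @return Data frame with `participant_id`, `group`, `jar_ratio`, `content`,
#'   level-specific keys (`series_id` or `pair`), `mean_deviation`,
#'   `n_trials` and `missing`.
#' @export
aggregate_deviations <- function(records, level = .AGG_LEVELS) {
  level <- match.arg(level)
  .assert_cols(records, c("participant_id", "group", "jar_ratio", "content",
                          "series_id", "position", "deviation"), "`records`")
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)

  base_keys <- c("participant_id", "group", "jar_ratio", "content")
  data <- records
  if (level == "last-position") data <- data[data$position == 10L, , drop = FALSE]
  keys <- switch(level,
    "global-condition" = base_keys,
    "series-mean" = ,
    "last-position" = c(base_keys, "series_id"),
    "mirror-pair" = c(base_keys, "series_id"))

  agg <- stats::aggregate(deviation ~ ., data = data[c(keys, "deviation")], FUN = mean)
  cnt <- stats::aggregate(deviation ~ ., data = data[c(keys, "deviation")], FUN = length)
  names(agg)[names(agg) == "deviation"] <- "mean_deviation"
  agg$n_trials <- cnt$deviation

  if (level == "mirror-pair") {
    keep <- mapply(function(jr, id) id %in% .MIRROR_PAIRS[[jr]],
                   agg$jar_ratio, agg$series_id)
    agg <- agg[keep, , drop = FALSE]
    agg$pair <- vapply(agg$jar_ratio, function(jr) {
      paste(.MIRROR_PAIRS[[jr]], collapse = "+")
    }, "", USE.NAMES = FALSE)
    m <- stats::aggregate(mean_deviation ~ participant_id + group + jar_ratio + content + pair,
                          data = agg, FUN = mean)
    n <- stats::aggregate(n_trials ~ participant_id + group + jar_ratio + content + pair,
                          data = agg, FUN = sum)
    m$n_trials <- n$n_trials
    agg <- m
    keys <- c(base_keys, "pair")
  }

  # complete the participant x cell grid; flag empty cells instead of dropping
  if (level == "mirror-pair") {
    cells <- unique(agg[c("jar_ratio", "content", "pair")])
  } else if (level %in% c("series-mean", "last-position")) {
    cells <- unique(records[c("jar_ratio", "content", "series_id")])
  } else {
    cells <- unique(records[c("jar_ratio", "content")])
  }
  ppl <- unique(records[c("participant_id", "group")])
  grid <- merge(ppl, cells, by = NULL)
  out <- merge(grid, agg, by = keys, all.x = TRUE, sort = FALSE)
  out$missing <- is.na(out$mean_deviation)
  out$n_trials[out$missing] <- 0L
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Per-participant completeness report
#'
#' @param responses A response or deviation table.
#' @return Data frame with `participant_id`, `group`, `n_trials` and
#'   `complete` (all 200 design trials present).
#' @export
completeness_report <- function(responses) {
  .assert_cols(responses, c("participant_id", "group"), "`responses`")
  cnt <- stats::aggregate(list(n_trials = responses$participant_id),
                          by = responses[c("participant_id", "group")], FUN = length)
  cnt$complete <- cnt$n_trials == 200L
  cnt[order(cnt$participant_id), , drop = FALSE]
}
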