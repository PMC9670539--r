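# End-to-end orchestration and file I/O contracts.

.RESPONSE_COLS <- c("participant_id", "group", "jar_ratio", "content",
                    "series_id", "position", "Y")

#' Configure a pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort and simulate responses) or
#'   `"real"` (read response and participant files).
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param responses_path,participants_path Input CSV paths (real mode).
#' @param out_dir Output directory; created if absent.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it via [derive_seed()].
#' @param alpha Significance level used for flagging (never for filtering).
#' @param adjust Multiplicity adjustment for contrast/correlation tables:
#'   `"none"` (default) or `"holm"`.
#' @param corstr Working correlation for the marginal models.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), cohort = cohort_config(),
                       responses_path = NULL, participants_path = NULL,
                       out_dir = tempfile("beads_run_"), seed = 1L,
                       alpha = 0.05, adjust = "none", corstr = "exchangeable") {
  mode <- match.arg(mode)
  if (mode == "real" && (is.null(responses_path) || is.null(participants_path))) {
    stop("real-data mode requires `responses_path` and `participants_path`", call. = FALSE)
  }
  structure(list(mode = mode, cohort = cohort, responses_path = responses_path,
                 participants_path = participants_path, out_dir = out_dir,
                 seed = as.integer(seed), alpha = alpha, adjust = adjust,
                 corstr = corstr),
            class = "run_config")
}

#' Read and validate a response file
#'
#' Reads a long-format delimited response table and validates every record,
#' collecting violations (unknown group label, position outside 1-10, `Y`
#' outside 0-10, missing fields) with their line numbers instead of failing
#' on the first. Any violation aborts with the full list.
#'
#' @param path CSV file with header columns `participant_id`, `group`,
#'   `jar_ratio`, `content`, `series_id`, `position`, `Y`.
#' @return Typed response data frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop(sprintf("response file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(d, .RESPONSE_COLS, sprintf("response file %s", path))
  line <- seq_len(nrow(d)) + 1L       # header is line 1
  bad <- character(0)
  flag <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      ln <- line[which(cond)]
      bad <<- c(bad, sprintf("%s at line(s) %s", msg,
                             paste(utils::head(ln, 10L), collapse = ", ")))
    }
  }
  flag(!(d$group %in% c("patient", "control")), "unknown group label")
  flag(!(d$jar_ratio %in% .JAR_RATIOS), "unknown jar ratio")
  flag(!(d$content %in% .CONTENTS), "unknown content")
  flag(is.na(d$position) | d$position < 1 | d$position > 10 |
         d$position != round(d$position), "position outside 1-10")
  flag(is.na(d$Y) | d$Y < 0 | d$Y > 10, "Y outside [0, 10]")
  flag(is.na(d$series_id) | d$series_id != round(d$series_id), "bad series id")
  if (length(bad)) {
    stop(sprintf("invalid response file %s:\n  %s", path,
                 paste(bad, collapse = "\n  ")), call. = FALSE)
  }
  d$series_id <- as.integer(d$series_id)
  d$position <- as.integer(d$position)
  d
}

#' Write a table as CSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.data_dictionary <- function() {
  c("Data dictionary",
    "===============",
    "responses.csv / deviations.csv (one row per trial)",
    "  participant_id : participant code (P## patients, C## controls)",
    "  group          : patient | control",
    "  jar_ratio      : 80:20 | 60:40 (majority proportion of each jar)",
    "  content        : neutral (beads) | emotional (faces)",
    "  series_id      : series 1-7 (canonical composition map)",
    "  position       : draw index within the series, 1-10",
    "  Y              : slider response rescaled to [0,10]; 10 = certain jar B",
    "  normative      : ideal-observer posterior P(jar B | draws 1..position)",
    "  signed_deviation: Y - 10*normative",
    "  deviation      : |Y - 10*normative|, the deviation score",
    "aggregate tables (per participant)",
    "  mean_deviation : mean deviation at the stated aggregation level",
    "  n_trials       : trials entering the mean; 0 and missing=TRUE for empty cells",
    "participants.csv",
    "  clinical scores: PANSS subscales (items 1-7), PANSS_P1 delusions item,",
    "    PSYRATS_D total and D6 disruption item (0-4), PSYRATS_H, CPZ mg/day",
    "  w_*, prior_bias, sigma_*, lapse : latent generative observer parameters",
    "    (synthetic cohorts only)")
}

#' Run the full pipeline
#'
#' Executes every stage in order -- build task, simulate (or ingest)
#' responses, score, aggregate, fit both jar-ratio marginal models, contrast
#' tables, correlation battery, demographics -- writing every intermediate
#' artifact plus a data dictionary and a JSON manifest (inputs, seeds, file
#' checksums, stage timings) to `out_dir`, so a run is exactly reproducible
#' from its config and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`task`, `cohort`,
#'   `responses`, `deviations`, `aggregates`, `models`, `contrasts`,
#'   `correlations`, `demographics`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), ts, units = "secs")), 3)
    out
  }

  task <- stage("task", build_canonical_task(seed = config$seed))
  write_task(task, file.path(config$out_dir, "task.yaml"))

  if (config$mode == "synthetic") {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- derive_seed(config$seed, "cohort-master")
    cohort <- stage("cohort", generate_cohort(cohort_cfg))
    responses <- stage("simulate",
                       simulate_responses(cohort, task,
                                          seed = derive_seed(config$seed, "simulate")))
  } else {
    responses <- stage("ingest", read_responses(config$responses_path))
    cohort <- stage("ingest-participants",
                    utils::read.csv(config$participants_path, stringsAsFactors = FALSE))
  }
  write_table(cohort, file.path(config$out_dir, "participants.csv"))
  write_table(responses, file.path(config$out_dir, "responses.csv"))

  deviations <- stage("score", deviation_table(responses, task))
  write_table(deviations, file.path(config$out_dir, "deviations.csv"))
  write_table(completeness_report(responses),
              file.path(config$out_dir, "completeness.csv"))

  aggregates <- stage("aggregate", {
    stats::setNames(lapply(.AGG_LEVELS, function(l) aggregate_deviations(deviations, l)),
                    .AGG_LEVELS)
  })
  for (l in names(aggregates)) {
    write_table(aggregates[[l]],
                file.path(config$out_dir, sprintf("aggregate_%s.csv", gsub("-", "_", l))))
  }

  models <- stage("models", {
    lapply(stats::setNames(.JAR_RATIOS, .JAR_RATIOS), function(jr) {
      fit_marginal_model(deviations, jr, corstr = config$corstr)
    })
  })
  for (jr in names(models)) {
    write_table(models[[jr]]$term_table,
                file.path(config$out_dir,
                          sprintf("terms_%s.csv", gsub(":", "_", jr))))
  }
  contrasts <- stage("contrasts", {
    lapply(models, ls_means_contrasts, adjust = config$adjust)
  })
  for (jr in names(contrasts)) {
    write_table(contrasts[[jr]],
                file.path(config$out_dir,
                          sprintf("contrasts_%s.csv", gsub(":", "_", jr))))
  }
  correlations <- stage("correlations", {
    has_clinical <- all(c("PANSS_P1", "PSYRATS_D", "PSYRATS_D6") %in% names(cohort))
    if (has_clinical) correlation_battery(deviations, cohort, adjust = config$adjust)
    else NULL
  })
  if (!is.null(correlations)) {
    write_table(correlations, file.path(config$out_dir, "correlations.csv"))
  }
  demographics <- stage("demographics", demographics_tests(cohort))
  write_table(demographics, file.path(config$out_dir, "demographics.csv"))
  writeLines(.data_dictionary(), file.path(config$out_dir, "data_dictionary.txt"))

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    mode = config$mode,
    master_seed = config$seed,
    stage_seeds = list(task = config$seed,
                       cohort = derive_seed(config$seed, "cohort-master"),
                       simulate = derive_seed(config$seed, "simulate")),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("beadstask")),
    options = list(alpha = config$alpha, adjust = config$adjust,
                   corstr = config$corstr),
    n_trials_scored = nrow(deviations),
    stage_timings_s = timings,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(task = task, cohort = cohort, responses = responses,
                 deviations = deviations, aggregates = aggregates,
                 models = models, contrasts = contrasts,
                 correlations = correlations, demographics = demographics,
                 manifest = manifest, out_dir = config$out_dir))
}
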