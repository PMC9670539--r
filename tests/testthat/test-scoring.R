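test_that("slider rescaling maps the bar onto [0, 10] with B at 10", {
  expect_equal(rescale_response(0, 0, 600), 0)
  expect_equal(rescale_response(300, 0, 600), 5)
  expect_equal(rescale_response(600, 0, 600), 10)
  expect_equal(rescale_response(0, 0, 600, "B-left"), 10)
  expect_equal(rescale_response(450, 0, 600, "B-left"), 2.5)
  expect_error(rescale_response(-1, 0, 600), "outside bar extent")
  expect_error(rescale_response(1, 5, 3), "bar_min")
})

test_that("the ideal responder scores zero deviation on all 200 trials", {
  task <- canonical_task()
  resp <- ideal_responses(task)        # normative values from the brute-force oracle
  dev <- deviation_table(resp, task)
  expect_equal(nrow(dev), 200L)
  expect_lt(max(dev$deviation), 1e-12)
})

test_that("deviation is |Y - 10 * posterior| with the documented worked value", {
  task <- canonical_task()
  # 0:100 series in the 60:40 block: position 2 always has counts (2, 0)
  resp <- data.frame(participant_id = "P01", group = "patient",
                     jar_ratio = "60:40", content = "neutral",
                     series_id = 5L, position = 2L, Y = 3.0,
                     stringsAsFactors = FALSE)
  dev <- deviation_table(resp, task)
  expect_equal(dev$normative, 2.25 / 3.25, tolerance = 1e-12)
  expect_equal(dev$deviation, abs(3 - 10 * 2.25 / 3.25), tolerance = 1e-12)
  expect_equal(dev$signed_deviation, 3 - 10 * 2.25 / 3.25, tolerance = 1e-12)

  # Y = 10 against a 50:50 cell gives deviation 5
  r2 <- resp; r2$series_id <- 3L; r2$position <- 10L; r2$Y <- 10
  expect_equal(deviation_table(r2, task)$deviation, 5, tolerance = 1e-12)

  r3 <- resp; r3$series_id <- 99L
  expect_error(deviation_table(r3, task), "unknown task cells")
  r4 <- resp; r4$Y <- 11
  expect_error(deviation_table(r4, task), "outside \\[0, 10\\]")
})

test_that("deviation is invariant under symbol relabelling with Y flipped", {
  task <- canonical_task()
  cfg <- small_cohort_config(seed = 5)
  resp <- simulate_responses(generate_cohort(cfg), task, seed = 6)
  dev <- deviation_table(resp, task)

  # swap the two symbols everywhere in the task and flip responses to 10 - Y
  swapped <- task
  swaps <- list(neutral = c(red = "green", green = "red"),
                emotional = c(happy = "angry", angry = "happy"))
  for (bi in seq_along(swapped$blocks)) {
    sw <- swaps[[swapped$blocks[[bi]]$content]]
    for (si in seq_along(swapped$blocks[[bi]]$series)) {
      s <- swapped$blocks[[bi]]$series[[si]]
      swapped$blocks[[bi]]$series[[si]]$draws <- unname(sw[s$draws])
      swapped$blocks[[bi]]$series[[si]]$declared_ratio <- rev(s$declared_ratio)
    }
  }
  flipped <- resp
  flipped$Y <- 10 - resp$Y
  dev2 <- deviation_table(flipped, swapped)
  expect_equal(dev2$deviation, dev$deviation, tolerance = 1e-10)
})

test_that("aggregates hit all four granularities and conserve mass", {
  task <- canonical_task()
  resp <- simulate_responses(generate_cohort(small_cohort_config(seed = 2)),
                             task, seed = 3)
  dev <- deviation_table(resp, task)

  glob <- aggregate_deviations(dev, "global-condition")
  ser <- aggregate_deviations(dev, "series-mean")
  last <- aggregate_deviations(dev, "last-position")
  pair <- aggregate_deviations(dev, "mirror-pair")

  expect_equal(nrow(glob), 16 * 4)          # 16 participants x 4 ratio-content cells
  expect_equal(nrow(ser), 16 * 20)          # 5 series per ratio x 2 contents
  expect_true(all(last$n_trials[!last$missing] == 1))

  # mass conservation: trial-count-weighted series means reproduce the global mean
  for (i in seq_len(nrow(glob))) {
    sub <- ser[ser$participant_id == glob$participant_id[i] &
               ser$jar_ratio == glob$jar_ratio[i] &
               ser$content == glob$content[i], ]
    expect_equal(sum(sub$mean_deviation * sub$n_trials) / sum(sub$n_trials),
                 glob$mean_deviation[i], tolerance = 1e-12)
  }

  # mirror pair = arithmetic mean of the two jar-ratio series means
  for (i in seq_len(nrow(pair))) {
    ids <- as.integer(strsplit(pair$pair[i], "+", fixed = TRUE)[[1]])
    sub <- ser[ser$participant_id == pair$participant_id[i] &
               ser$jar_ratio == pair$jar_ratio[i] &
               ser$content == pair$content[i] & ser$series_id %in% ids, ]
    expect_equal(pair$mean_deviation[i], mean(sub$mean_deviation), tolerance = 1e-12)
  }
  expect_identical(sort(unique(pair$pair)), c("1+4", "6+7"))
})

test_that("mirror-pair averaging on a constructed two-series fixture", {
  rec <- expand.grid(position = 1:10, series_id = c(1L, 4L),
                     KEEP.OUT.ATTRS = FALSE)
  rec$participant_id <- "P01"; rec$group <- "patient"
  rec$jar_ratio <- "60:40"; rec$content <- "neutral"
  rec$deviation <- ifelse(rec$series_id == 1L, 1.0, 3.0)
  out <- aggregate_deviations(rec, "mirror-pair")
  expect_equal(out$mean_deviation, 2.0)
})

test_that("empty cells are flagged, never silently dropped", {
  task <- canonical_task()
  resp <- simulate_responses(generate_cohort(small_cohort_config(seed = 4)),
                             task, seed = 4)
  dev <- deviation_table(resp, task)
  drop_id <- dev$participant_id[1]
  dev <- dev[!(dev$participant_id == drop_id & dev$content == "emotional"), ]
  glob <- aggregate_deviations(dev, "global-condition")
  gone <- glob[glob$participant_id == drop_id & glob$content == "emotional", ]
  expect_equal(nrow(gone), 2L)
  expect_true(all(gone$missing))
  expect_true(all(gone$n_trials == 0))
  expect_false(any(glob$missing[glob$participant_id != drop_id]))

  rep <- completeness_report(dev)
  expect_false(rep$complete[rep$participant_id == drop_id])
  expect_true(all(rep$complete[rep$participant_id != drop_id]))
})

test_that("expected deviation grows with distance from normative weighting", {
  task <- canonical_task()
  dev_mean <- function(w) {
    cohort <- data.frame(participant_id = "X1", group = "control",
                         w_neutral = w, w_emotional = w, prior_bias = 0,
                         sigma_neutral = 0, sigma_emotional = 0, lapse = 0,
                         stringsAsFactors = FALSE)
    resp <- simulate_responses(cohort, task, seed = 1)
    mean(deviation_table(resp, task)$deviation)
  }
  expect_equal(dev_mean(1), 0, tolerance = 1e-12)
  # monotone non-decreasing in |w - 1| on each side of 1
  expect_true(all(diff(vapply(c(1, 0.8, 0.6, 0.4, 0.2), dev_mean, 0)) >= 0))
  expect_true(all(diff(vapply(c(1, 1.2, 1.4, 1.6, 1.8), dev_mean, 0)) >= 0))
})
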