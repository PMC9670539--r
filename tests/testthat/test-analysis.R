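# Fixture: one simulated deviation table reused across model tests.
analysis_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      task <- canonical_task()
      co <- generate_cohort(cohort_config(n_patients = 15L, n_controls = 16L, seed = 7))
      resp <- simulate_responses(co, task, seed = 7)
      cache <<- list(dev = deviation_table(resp, task), cohort = co, task = task)
    }
    cache
  }
})

test_that("with independence working correlation the solver matches OLS plus
           cluster-robust sandwich covariance", {
  skip_if_not_installed("sandwich")
  fx <- analysis_fixture()
  fit <- fit_marginal_model(fx$dev, "60:40", corstr = "independence")

  d <- fx$dev[fx$dev$jar_ratio == "60:40", ]
  d$group <- factor(d$group, levels = c("control", "patient"))
  d$series <- factor(d$series_id)
  d$content <- factor(d$content, levels = c("neutral", "emotional"))
  d$position_c <- d$position - 5.5
  d <- d[order(d$participant_id), ]
  lmfit <- lm(deviation ~ group * (series + content + position_c)^2, data = d,
              contrasts = list(group = "contr.sum", series = "contr.sum",
                               content = "contr.sum"))
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)), tolerance = 1e-8)
  V <- sandwich::vcovCL(lmfit, cluster = d$participant_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-6)
})

test_that("exchangeable working correlation is estimated and inference stays
           robust to it on a balanced design", {
  fx <- analysis_fixture()
  ind <- fit_marginal_model(fx$dev, "60:40", corstr = "independence")
  exch <- fit_marginal_model(fx$dev, "60:40", corstr = "exchangeable")
  expect_true(exch$converged)
  expect_gt(exch$alpha, -1)
  # balanced clusters: identical regressor blocks make GLS coincide with OLS,
  # and the sandwich covariance is then identical too
  expect_equal(exch$coefficients, ind$coefficients, tolerance = 1e-8)
  expect_equal(exch$vcov, ind$vcov, tolerance = 1e-8)
})

test_that("term-level Wald table is well-formed", {
  fx <- analysis_fixture()
  fit <- fit_marginal_model(fx$dev, "80:20")
  tt <- fit$term_table
  expect_setequal(
    tt$term,
    c("group", "series", "content", "position_c", "series:content",
      "series:position_c", "content:position_c", "group:series",
      "group:content", "group:position_c", "group:series:content",
      "group:series:position_c", "group:content:position_c"))
  expect_true(all(tt$wald_chisq >= 0))
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  expect_equal(tt$df[tt$term == "group"], 1L)
  expect_equal(tt$df[tt$term == "series"], 4L)
  expect_equal(tt$df[tt$term == "group:series:content"], 4L)
})

test_that("degenerate inputs fail loudly", {
  fx <- analysis_fixture()
  flat <- fx$dev
  flat$deviation <- 1.0
  expect_error(fit_marginal_model(flat, "60:40"), "zero variance")

  solo <- fx$dev[fx$dev$participant_id %in% c("P01", "P02", "C01"), ]
  expect_error(fit_marginal_model(solo, "60:40"), "at least 2 clusters")

  patonly <- fx$dev[fx$dev$group == "patient", ]
  expect_error(fit_marginal_model(patonly, "60:40"), "at least 2 clusters")
})

test_that("LS-means contrasts are internally consistent and signed correctly", {
  fx <- analysis_fixture()
  fit <- fit_marginal_model(fx$dev, "80:20")
  ct <- ls_means_contrasts(fit)
  expect_equal(nrow(ct), 10L)                       # 5 series x 2 contents
  expect_equal(ct$diff, ct$control_mean - ct$patient_mean, tolerance = 1e-12)
  # two-sided consistency: 95% CI excludes 0 exactly when p < 0.05
  expect_identical(ct$ci_lower > 0 | ct$ci_upper < 0, ct$p < 0.05)
  # generating model makes patients worse: significant cells favour controls
  expect_true(all(ct$diff[ct$significant] < 0))
  # CI construction brackets the difference
  expect_true(all(ct$ci_lower < ct$diff & ct$diff < ct$ci_upper))

  holm <- ls_means_contrasts(fit, adjust = "holm")
  expect_true(all(holm$p >= ct$p - 1e-15))
})

test_that("a single-group fit cannot be contrasted", {
  fx <- analysis_fixture()
  fit <- fit_marginal_model(fx$dev, "60:40")
  fit$groups_present <- "patient"       # as after a patient-only fit
  expect_error(ls_means_contrasts(fit), "single group")
})

test_that("demographic worked examples reproduce the published statistics", {
  # sex: 46.7% of 30 patients and 43.8% of 32 controls are male
  sex <- chisq_2x2(matrix(c(14, 16, 14, 18), 2, byrow = TRUE))
  expect_equal(round(sex$chi_squared, 3), 0.053)
  expect_equal(round(sex$p, 2), 0.82)
  # hand closed form N(ad - bc)^2 / row/col products, to 1e-10
  hand <- 62 * (14 * 18 - 16 * 14)^2 / (30 * 32 * 28 * 34)
  expect_lt(abs(sex$chi_squared - hand), 1e-10)

  # age: controls 32.3 (10.9, n=32) vs patients 37.0 (14.2, n=30);
  # the summary statistics are themselves rounded, so match to print precision
  age <- welch_t_summary(32.3, 10.9, 32, 37.0, 14.2, 30)
  expect_lt(abs(age$t - (-1.45)), 0.01)
  expect_lt(abs(age$p - 0.15), 0.01)
})

test_that("summary-statistic Welch t agrees with t.test on raw data", {
  set.seed(13)
  x <- rnorm(25, 50, 9)
  y <- rnorm(31, 46, 12)
  ref <- t.test(x, y, var.equal = FALSE)
  ws <- welch_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_lt(abs(ws$t - unname(ref$statistic)), 1e-10)
  expect_lt(abs(ws$df - unname(ref$parameter)), 1e-10)
  expect_lt(abs(ws$p - ref$p.value), 1e-10)
})

test_that("demographics_tests runs the right tests in the right direction", {
  fx <- analysis_fixture()
  dt <- demographics_tests(fx$cohort)
  expect_setequal(dt$variable, c("sex", "age"))
  expect_true(all(dt$p >= 0 & dt$p <= 1))
  # identical groups: both statistics collapse to zero
  same <- data.frame(participant_id = c(sprintf("P%02d", 1:4), sprintf("C%02d", 1:4)),
                     group = rep(c("patient", "control"), each = 4),
                     age = rep(c(30, 40, 50, 60), 2),
                     sex = rep(c("male", "male", "female", "female"), 2),
                     stringsAsFactors = FALSE)
  dt0 <- demographics_tests(same)
  expect_equal(dt0$value, c(0, 0), tolerance = 1e-12)
  expect_error(demographics_tests(same[same$group == "patient", ]), "both groups")
})

test_that("symptom correlations recover exact and degenerate cases", {
  fx <- analysis_fixture()
  agg <- aggregate_deviations(fx$dev, "global-condition")
  pat <- fx$cohort[fx$cohort$group == "patient", ]

  # aggregate perfectly linear in PANSS-P1 -> r = 1 in every cell
  rigged <- agg
  sel <- rigged$group == "patient"
  rigged$mean_deviation[sel] <-
    2 + 3 * pat$PANSS_P1[match(rigged$participant_id[sel], pat$participant_id)]
  res <- symptom_correlations(rigged, fx$cohort, measures = "PANSS_P1")
  expect_equal(res$r, rep(1, nrow(res)), tolerance = 1e-12)

  # zero-variance aggregate is flagged, not computed
  flat <- agg
  flat$mean_deviation <- 1
  res0 <- symptom_correlations(flat, fx$cohort, measures = "PANSS_P1")
  expect_true(all(res0$flag == "zero-variance"))
  expect_true(all(is.na(res0$r)))

  # battery covers measures x cells across all four levels
  bat <- correlation_battery(fx$dev, fx$cohort)
  expect_setequal(unique(bat$level),
                  c("global-condition", "series-mean", "last-position", "mirror-pair"))
  expect_equal(nrow(bat), 3 * (4 + 20 + 20 + 4))
  expect_true(all(bat$n[bat$flag == ""] == 15))
})
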