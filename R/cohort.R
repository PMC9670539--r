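# Synthetic cohort: participants, clinical scores, latent observer
# parameters, and simulated trial-level responses.

#' Configure a synthetic cohort
#'
#' Defaults emulate a 30-patient / 32-control beads-task study: group sizes,
#' age and sex distributions, clinical-score marginals (truncated normals
#' within instrument ranges), and the latent biased-observer parameters that
#' generate behaviour. Patients under-weight evidence (`w` mean 0.6 vs 0.9
#' in controls); the emotional content condition applies to BOTH groups as a
#' small decrement to `w` plus an increment to response noise `sigma`
#' (emotional faces pull processing resources away from the probability
#' estimate, which mostly adds noise). Patients' delusion scores are linked
#' to their latent parameters through a Gaussian copula: PANSS-P1 to the
#' neutral-condition evidence weight and PSYRATS-D6 to the
#' emotional-condition weight, with negative sign so that higher symptom
#' load means lower `w` and hence larger deviation.
#'
#' @param n_patients,n_controls Group sizes.
#' @param age Named list (`patient`, `control`) of `c(mean, sd)` in years.
#' @param prop_male Named vector of male proportions per group.
#' @param w,sigma Named lists (`patient`, `control`) of `c(mean, sd)` for the
#'   evidence weight and the neutral-condition noise SD (0-10 scale).
#' @param prior_bias Named vector of additive log-odds biases per group.
#' @param lapse Named vector of lapse rates per group.
#' @param content_w_decrement Drop in `w` in the emotional condition (both
#'   groups).
#' @param content_sigma_increment Added noise SD in the emotional condition
#'   (both groups).
#' @param clinical Data frame of patient clinical-score marginals with
#'   columns `measure`, `mean`, `sd`, `min`, `max`.
#' @param linkage Named vector of latent correlations: `p1_w`
#'   (PANSS-P1 with neutral `w`), `d6_w_emotional` (PSYRATS-D6 with emotional
#'   `w`), `w_neutral_emotional` (stability of `w` across contents) and
#'   `p1_d6` (between the two symptom measures). All in (-1, 1) and jointly
#'   positive definite.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 30L, n_controls = 32L,
                          age = list(patient = c(mean = 37.0, sd = 14.2),
                                     control = c(mean = 32.3, sd = 10.9)),
                          prop_male = c(patient = 0.467, control = 0.438),
                          w = list(patient = c(mean = 0.6, sd = 0.15),
                                   control = c(mean = 0.9, sd = 0.08)),
                          prior_bias = c(patient = 0, control = 0),
                          sigma = list(patient = c(mean = 1, sd = 0),
                                       control = c(mean = 1, sd = 0)),
                          lapse = c(patient = 0, control = 0),
                          content_w_decrement = 0.02,
                          content_sigma_increment = 0.75,
                          clinical = default_clinical_marginals(),
                          linkage = c(p1_w = -0.4, d6_w_emotional = -0.39,
                                      w_neutral_emotional = 0.6, p1_d6 = 0.3),
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
              age = age, prop_male = prop_male, w = w, prior_bias = prior_bias,
              sigma = sigma, lapse = lapse,
              content_w_decrement = content_w_decrement,
              content_sigma_increment = content_sigma_increment,
              clinical = clinical, linkage = linkage, seed = as.integer(seed))
  if (any(abs(cfg$linkage[c("p1_w", "d6_w_emotional", "w_neutral_emotional", "p1_d6")]) >= 1)) {
    stop("linkage correlations must lie in (-1, 1)", call. = FALSE)
  }
  for (g in c("patient", "control")) {
    if (cfg$w[[g]]["sd"] < 0 || cfg$sigma[[g]]["sd"] < 0) {
      stop("parameter SDs must be >= 0", call. = FALSE)
    }
  }
  # fail early on an infeasible latent correlation matrix
  .latent_corr(cfg$linkage)
  structure(cfg, class = "cohort_config")
}

#' Default clinical-score marginals for patients
#'
#' Truncated-normal marginals within instrument ranges (PANSS subscale items
#' 1-7, PSYRATS items 0-4). PANSS-P1 (the delusions item) and PSYRATS-D6
#' (disruption to life) are the measures tied to latent behaviour.
#'
#' @return Data frame with columns `measure`, `mean`, `sd`, `min`, `max`.
#' @export
default_clinical_marginals <- function() {
  data.frame(
    measure = c("PANSS_positive", "PANSS_negative", "PANSS_general", "PANSS_P1",
                "PSYRATS_D", "PSYRATS_D6", "PSYRATS_H", "CPZ", "duration_illness"),
    mean = c(19.3, 16.7, 36.0, 4.5, 14.7, 3.0, 15.5, 471.6, 10.7),
    sd   = c(4.0, 5.8, 4.8, 1.2, 3.0, 1.0, 11.1, 271.7, 11.8),
    min  = c(7, 7, 16, 1, 0, 0, 0, 0, 0),
    max  = c(49, 49, 112, 7, 24, 4, 44, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

# latent correlation matrix over (w_neutral, w_emotional, PANSS_P1, PSYRATS_D6)
.latent_corr <- function(linkage) {
  r <- matrix(0, 4, 4, dimnames = rep(list(c("w_n", "w_e", "p1", "d6")), 2))
  diag(r) <- 1
  r["w_n", "w_e"] <- r["w_e", "w_n"] <- linkage[["w_neutral_emotional"]]
  r["w_n", "p1"] <- r["p1", "w_n"] <- linkage[["p1_w"]]
  r["w_e", "d6"] <- r["d6", "w_e"] <- linkage[["d6_w_emotional"]]
  r["p1", "d6"] <- r["d6", "p1"] <- linkage[["p1_d6"]]
  # implied cross-correlations, so the matrix stays coherent and near-PD:
  # w_e picks up p1 through w_n, and w_n picks up d6 through w_e
  r["w_e", "p1"] <- r["p1", "w_e"] <- linkage[["p1_w"]] * linkage[["w_neutral_emotional"]]
  r["w_n", "d6"] <- r["d6", "w_n"] <- linkage[["d6_w_emotional"]] * linkage[["w_neutral_emotional"]]
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) {
    stop("infeasible linkage: latent correlation matrix is not positive definite",
         call. = FALSE)
  }
  list(R = r, chol = ch)
}

.qtrunc <- function(u, mean, sd, min, max) {
  truncnorm::qtruncnorm(u, a = min, b = max, mean = mean, sd = sd)
}

#' Generate a synthetic cohort
#'
#' Draws demographics, patients' clinical scores, and per-participant latent
#' observer parameters from the configured distributions, reproducibly from
#' the config seed. Patients' PANSS-P1 and PSYRATS-D6 scores are coupled to
#' their evidence weights via a Gaussian copula, so clinical marginals are
#' preserved exactly while the latent correlations hit their targets in
#' expectation. Controls carry no clinical scores and near-normative
#' parameters.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `group`, `age`, `sex`, clinical-score columns (NA for controls), and
#'   latent parameters `w_neutral`, `w_emotional`, `prior_bias`,
#'   `sigma_neutral`, `sigma_emotional`, `lapse`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  lat <- .latent_corr(config$linkage)
  cl <- config$clinical
  .with_seed(derive_seed(config$seed, "cohort"), {
    n_p <- config$n_patients; n_c <- config$n_controls
    n <- n_p + n_c
    group <- rep(c("patient", "control"), c(n_p, n_c))
    id <- sprintf("%s%02d", ifelse(group == "patient", "P", "C"),
                  c(seq_len(n_p), seq_len(n_c)))
    age <- c(rnorm(n_p, config$age$patient["mean"], config$age$patient["sd"]),
             rnorm(n_c, config$age$control["mean"], config$age$control["sd"]))
    age <- round(pmax(age, 18), 1)
    sex <- ifelse(c(runif(n_p) < config$prop_male[["patient"]],
                    runif(n_c) < config$prop_male[["control"]]), "male", "female")

    # patients: copula over (w_neutral, w_emotional, PANSS_P1, PSYRATS_D6)
    z <- matrix(rnorm(n_p * 4), n_p, 4) %*% lat$chol
    colnames(z) <- colnames(lat$R)
    wp <- config$w$patient
    w_n_pat <- pmax(wp["mean"] + wp["sd"] * z[, "w_n"], 0)
    w_e_pat <- pmax(wp["mean"] + wp["sd"] * z[, "w_e"] - config$content_w_decrement, 0)
    clin <- matrix(NA_real_, n, nrow(cl), dimnames = list(NULL, cl$measure))
    for (j in seq_len(nrow(cl))) {
      u <- switch(cl$measure[j],
                  PANSS_P1 = pnorm(z[, "p1"]),
                  PSYRATS_D6 = pnorm(z[, "d6"]),
                  runif(n_p))
      clin[seq_len(n_p), j] <- .qtrunc(u, cl$mean[j], cl$sd[j], cl$min[j], cl$max[j])
    }

    # controls: near-normative parameters, no clinical scores; emotional w
    # shares the same across-content correlation structure as patients
    wc <- config$w$control
    rho <- config$linkage[["w_neutral_emotional"]]
    z_wn <- rnorm(n_c)
    z_we <- rho * z_wn + sqrt(1 - rho^2) * rnorm(n_c)
    w_n_ctl <- pmax(wc["mean"] + wc["sd"] * z_wn, 0)
    w_e_ctl <- pmax(wc["mean"] + wc["sd"] * z_we - config$content_w_decrement, 0)

    sg_p <- config$sigma$patient; sg_c <- config$sigma$control
    sigma_n <- pmax(c(rnorm(n_p, sg_p["mean"], sg_p["sd"]),
                      rnorm(n_c, sg_c["mean"], sg_c["sd"])), 0)
    sigma_e <- sigma_n + config$content_sigma_increment

    out <- data.frame(participant_id = id, group = group, age = age, sex = sex,
                      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(cl))) out[[cl$measure[j]]] <- clin[, j]
    out$w_neutral <- c(w_n_pat, w_n_ctl)
    out$w_emotional <- c(w_e_pat, w_e_ctl)
    out$prior_bias <- config$prior_bias[match(group, names(config$prior_bias))]
    out$sigma_neutral <- sigma_n
    out$sigma_emotional <- sigma_e
    out$lapse <- config$lapse[match(group, names(config$lapse))]
    rownames(out) <- NULL
    attr(out, "config") <- config
    out
  })
}

#' Simulate trial-level responses for a cohort
#'
#' Generates one slider response per participant and task trial (200 trials
#' each under the canonical design) from each participant's content-specific
#' biased-observer parameters. Output schema is identical to a real-data
#' response file, so simulated files pass the same reader and validator.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param task A `beads_task`.
#' @param seed Integer seed (independent of the cohort seed).
#' @param prior Prior probability of jar B.
#' @return Long data frame: `participant_id`, `group`, `jar_ratio`,
#'   `content`, `series_id`, `position`, `Y`.
#' @export
simulate_responses <- function(cohort, task, seed = 1L, prior = 0.5) {
  .assert_cols(cohort, c("participant_id", "group", "w_neutral", "w_emotional",
                         "prior_bias", "sigma_neutral", "sigma_emotional", "lapse"),
               "`cohort`")
  trials <- do.call(rbind, lapply(task$blocks, function(blk) {
    do.call(rbind, lapply(blk$series, function(s) {
      tr <- trajectory(s, blk$p_dominant, prior)
      data.frame(jar_ratio = blk$jar_ratio, content = blk$content,
                 series_id = s$series_id, position = tr$position,
                 log_odds = tr$log_odds, stringsAsFactors = FALSE)
    }))
  }))
  n_t <- nrow(trials)
  n <- nrow(cohort)
  # participant-major expansion keeps the draw order stable
  idx_p <- rep(seq_len(n), each = n_t)
  idx_t <- rep(seq_len(n_t), times = n)
  emo <- trials$content[idx_t] == "emotional"
  w <- ifelse(emo, cohort$w_emotional[idx_p], cohort$w_neutral[idx_p])
  sg <- ifelse(emo, cohort$sigma_emotional[idx_p], cohort$sigma_neutral[idx_p])
  b <- cohort$prior_bias[idx_p]
  lp <- cohort$lapse[idx_p]
  m <- 10 / (1 + exp(-(w * trials$log_odds[idx_t] + b)))
  y <- .with_seed(derive_seed(seed, "responses"), {
    yy <- pmin(pmax(m + rnorm(n * n_t, 0, sg), 0), 10)
    is_lapse <- runif(n * n_t) < lp
    yy[is_lapse] <- runif(sum(is_lapse), 0, 10)
    yy
  })
  out <- data.frame(participant_id = cohort$participant_id[idx_p],
                    group = cohort$group[idx_p],
                    jar_ratio = trials$jar_ratio[idx_t],
                    content = trials$content[idx_t],
                    series_id = trials$series_id[idx_t],
                    position = trials$position[idx_t],
                    Y = y, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
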