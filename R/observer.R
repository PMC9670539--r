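# Ideal-observer posteriors and the parametric biased-responder model.

.logistic <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

#' Cumulative log-odds for jar B
#'
#' With mirrored jars whose majority proportion is `p_dominant`, every
#' jar-B-dominant draw adds `log(p/q)` to the log-odds of jar B and every
#' jar-A-dominant draw subtracts it, so the evidence after any set of draws
#' is `logit(prior) + (n_b - n_a) * log(p/q)`.
#'
#' @param n_b,n_a Counts of jar-B-dominant and jar-A-dominant draws
#'   (vectorized).
#' @param p_dominant Majority proportion of each jar, in (0.5, 1].
#' @param prior Prior probability of jar B, in (0, 1).
#' @return Numeric vector of log-odds (`Inf`/`-Inf` allowed when
#'   `p_dominant = 1`).
#' @export
log_odds_jar_b <- function(n_b, n_a, p_dominant, prior = 0.5) {
  if (any(prior <= 0 | prior >= 1)) stop("`prior` must lie in (0, 1)", call. = FALSE)
  if (any(p_dominant <= 0.5 | p_dominant > 1)) {
    stop("`p_dominant` must lie in (0.5, 1]", call. = FALSE)
  }
  .logit(prior) + (n_b - n_a) * log(p_dominant / (1 - p_dominant))
}

#' Exact Bayesian posterior for jar B
#'
#' The normative ("ideal observer") probability that the draws came from jar
#' B, given the counts of each symbol. Order does not matter: the posterior
#' depends on the draws only through `(n_b, n_a)`.
#'
#' @inheritParams log_odds_jar_b
#' @return Posterior probabilities in `[0, 1]`. With `p_dominant = 1` any
#'   mixed count is impossible under both jars and the count difference
#'   forces the answer to 0, 0.5 or 1.
#' @examples
#' posterior_jar_b(1, 0, 0.8)   # single draw, uniform prior: 0.8
#' posterior_jar_b(5, 5, 0.8)   # balanced evidence: 0.5
#' posterior_jar_b(2, 0, 0.6)   # 1.5^2 / (1 + 1.5^2)
#' @export
posterior_jar_b <- function(n_b, n_a, p_dominant, prior = 0.5) {
  if (any(n_b < 0) || any(n_a < 0) || any(n_b != round(n_b)) || any(n_a != round(n_a))) {
    stop("`n_b` and `n_a` must be non-negative integers", call. = FALSE)
  }
  lo <- log_odds_jar_b(n_b, n_a, p_dominant, prior)
  out <- .logistic(lo)
  # p = 1: log(p/q) is +Inf; a zero count difference carries no evidence
  if (any(p_dominant == 1)) out[(n_b - n_a) == 0] <- prior
  out
}

#' Normative posterior trajectory of a series
#'
#' Computes `P(jar B | draws 1..k)` for `k = 1..10` for one series, using the
#' mirrored-jar likelihoods for that block's ratio.
#'
#' @param series A `series_spec` (see [build_canonical_task()]).
#' @param p_dominant Majority proportion of the block's jars; defaults to the
#'   value implied by the series' jar-ratio condition.
#' @param prior Prior probability of jar B.
#' @return Data frame with one row per position: `series_id`, `position`,
#'   `symbol`, `n_b`, `n_a`, `log_odds`, `posterior`.
#' @export
trajectory <- function(series, p_dominant = NULL, prior = 0.5) {
  if (!inherits(series, "series_spec")) stop("`series` must be a series_spec", call. = FALSE)
  if (is.null(p_dominant)) p_dominant <- .ratio_p(series$jar_ratio_condition)
  sym <- .SYMBOLS[[series$content]]
  if (!all(series$draws %in% sym)) {
    stop(sprintf("series %d contains symbols outside the jar alphabet: %s",
                 series$series_id,
                 paste(setdiff(series$draws, sym), collapse = ", ")), call. = FALSE)
  }
  is_b <- series$draws == sym["B"]
  n_b <- cumsum(is_b)
  n_a <- cumsum(!is_b)
  data.frame(series_id = series$series_id, position = seq_along(series$draws),
             symbol = series$draws, n_b = n_b, n_a = n_a,
             log_odds = log_odds_jar_b(n_b, n_a, p_dominant, prior),
             posterior = posterior_jar_b(n_b, n_a, p_dominant, prior),
             stringsAsFactors = FALSE)
}

#' Biased-observer response parameters
#'
#' A four-parameter distortion of the ideal observer, used to synthesize
#' participant behaviour. On the 0-10 slider scale the mean response at
#' cumulative log-odds `L` is `10 * logistic(w * L + b)`:
#' * `w` -- evidence weight (1 = normative; `w < 1` conservative updating,
#'   `w > 1` over-adjustment);
#' * `b` -- additive prior bias on the log-odds scale;
#' * `sigma` -- Gaussian response noise SD on the 0-10 scale, applied after
#'   the logistic and clipped to the slider range;
#' * `lapse` -- probability of an off-task response, uniform on `[0, 10]`.
#'
#' `observer_params()` with defaults reproduces the ideal observer exactly.
#'
#' @param w,b,sigma,lapse See above.
#' @return An `observer_params` list.
#' @export
observer_params <- function(w = 1, b = 0, sigma = 0, lapse = 0) {
  if (w < 0) stop("`w` must be >= 0", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (lapse < 0 || lapse > 1) stop("`lapse` must lie in [0, 1]", call. = FALSE)
  structure(list(w = w, b = b, sigma = sigma, lapse = lapse),
            class = "observer_params")
}

#' Simulate one series of slider responses
#'
#' Per position, with probability `lapse` the response is uniform on
#' `[0, 10]`; otherwise it is
#' `clip(10 * logistic(w * L_k + b) + eps, 0, 10)` with
#' `eps ~ Normal(0, sigma^2)` and `L_k` the normative cumulative log-odds at
#' position `k`. Fully reproducible from `seed`.
#'
#' @param traj A trajectory data frame from [trajectory()].
#' @param params An [observer_params()].
#' @param seed Integer seed.
#' @return Numeric vector of responses on `[0, 10]`, one per position.
#' @export
biased_response <- function(traj, params, seed = 1L) {
  stopifnot(inherits(params, "observer_params"))
  m <- 10 * .logistic(params$w * traj$log_odds + params$b)
  .with_seed(seed, {
    n <- length(m)
    y <- pmin(pmax(m + rnorm(n, 0, params$sigma), 0), 10)
    if (params$lapse > 0) {
      is_lapse <- runif(n) < params$lapse
      y[is_lapse] <- runif(sum(is_lapse), 0, 10)
    }
    y
  })
}

#' Expected absolute deviation of a noisy clipped response
#'
#' Closed-form `E |clip(m + eps, 0, 10) - t|` for `eps ~ Normal(0, sigma^2)`,
#' where `m` is the deterministic biased response and `t = 10 * posterior` is
#' the normative target. Used as the analytic oracle for simulation-based
#' checks of the deviation score; reduces to `|m - t|` at `sigma = 0`.
#'
#' @param m Mean response(s) on the 0-10 scale (vectorized).
#' @param t Normative target(s) on the 0-10 scale.
#' @param sigma Noise SD.
#' @param lapse Lapse probability; lapses are uniform on `[0, 10]`, with mean
#'   absolute deviation `(t^2 + (10 - t)^2) / 20`.
#' @return Expected absolute deviation(s).
#' @export
expected_abs_deviation <- function(m, t, sigma, lapse = 0) {
  n <- max(length(m), length(t))
  m <- rep_len(m, n); t <- rep_len(t, n)
  core <- if (sigma == 0) {
    abs(m - t)
  } else {
    mu <- m - t
    # clipped tails collapse onto the slider ends
    tails <- t * pnorm((0 - m) / sigma) + (10 - t) * (1 - pnorm((10 - m) / sigma))
    seg <- function(l, h, sgn) {      # integral of sgn * x, X ~ N(mu, sigma^2), over (l, h)
      zl <- (l - mu) / sigma; zh <- (h - mu) / sigma
      sgn * (mu * (pnorm(zh) - pnorm(zl)) - sigma * (dnorm(zh) - dnorm(zl)))
    }
    lo <- -t; hi <- 10 - t            # response-minus-target at the clip bounds
    tails + seg(lo, pmin(0, hi), -1) + seg(pmax(0, lo), hi, 1)
  }
  lapse_dev <- (t^2 + (10 - t)^2) / 20
  (1 - lapse) * core + lapse * lapse_dev
}

#' Expected per-trial deviation profile of a task under given parameters
#'
#' Evaluates the closed-form expected absolute deviation at every trial of a
#' task for a biased observer, optionally with content-specific parameters.
#' This is the analytic counterpart of simulating responses and scoring them,
#' and serves as an independent oracle in recovery checks.
#'
#' @param task A `beads_task`.
#' @param params Either one [observer_params()] used for all blocks, or a
#'   named list with elements `neutral` and `emotional`.
#' @param prior Prior probability of jar B.
#' @return Data frame: `jar_ratio`, `content`, `series_id`, `position`,
#'   `posterior`, `expected_deviation`.
#' @export
expected_deviation_profile <- function(task, params, prior = 0.5) {
  if (inherits(params, "observer_params")) {
    params <- list(neutral = params, emotional = params)
  }
  rows <- lapply(task$blocks, function(blk) {
    pp <- params[[blk$content]]
    do.call(rbind, lapply(blk$series, function(s) {
      tr <- trajectory(s, blk$p_dominant, prior)
      m <- 10 * .logistic(pp$w * tr$log_odds + pp$b)
      data.frame(jar_ratio = blk$jar_ratio, content = blk$content,
                 series_id = s$series_id, position = tr$position,
                 posterior = tr$posterior,
                 expected_deviation = expected_abs_deviation(
                   m, 10 * tr$posterior, pp$sigma, pp$lapse),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
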