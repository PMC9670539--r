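# Shared fixtures and independent oracles.

# Brute-force Bayes posterior from explicit joint likelihoods (the oracle the
# logistic-form implementation is checked against). Vectorized over counts.
brute_posterior <- function(n_b, n_a, p, prior = 0.5) {
  q <- 1 - p
  lb <- p^n_b * q^n_a * prior
  la <- q^n_b * p^n_a * (1 - prior)
  lb / (lb + la)
}

# one canonical task, built once per test run
canonical_task <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_canonical_task(seed = 1)
    cache
  }
})

# A perfect (ideal-observer) responder's 200-trial response table, with the
# normative values computed by the brute-force oracle, independent of the
# package's trajectory code.
ideal_responses <- function(task, participant_id = "C01", group = "control") {
  rows <- lapply(task$blocks, function(blk) {
    sym <- if (blk$content == "neutral") c(A = "red", B = "green")
           else c(A = "happy", B = "angry")
    do.call(rbind, lapply(blk$series, function(s) {
      isb <- s$draws == sym[["B"]]
      nb <- cumsum(isb)
      na <- cumsum(!isb)
      post <- brute_posterior(nb, na, blk$p_dominant)
      data.frame(participant_id = participant_id, group = group,
                 jar_ratio = blk$jar_ratio, content = blk$content,
                 series_id = s$series_id, position = 1:10, Y = 10 * post,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small cohort for cheap end-to-end tests
small_cohort_config <- function(...) {
  cohort_config(n_patients = 8L, n_controls = 8L, ...)
}
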