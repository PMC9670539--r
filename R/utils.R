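# Seed plumbing shared by every stochastic stage.

#' Derive a stage seed from a master seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the master seed and the stage name, so stages can
#' be re-run in isolation and adding replicates to one stage never perturbs
#' another. The derivation is a small multiplicative string hash folded into
#' the positive 32-bit integer range.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"task-design"`, `"cohort"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "responses")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(master) %% 2147480009 * 7919 + h) %% 2147480009)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# random stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
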