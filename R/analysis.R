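# Population-averaged analysis layer: marginal (GEE-style) linear models of
# the deviation score with exchangeable working correlation and robust
# sandwich covariance, least-squares means and group contrasts, symptom
# correlations, and demographic comparisons.
#
# The estimating-equation solver is implemented here directly (Gaussian
# identity link). For an exchangeable working correlation R(alpha) the
# cluster inverse has the closed form
#   R^{-1} = 1/(1-alpha) * [ I - alpha/(1 + (m-1) alpha) * J ],
# so all cluster algebra reduces to per-cluster column sums, which keeps 500
# simulation replicates cheap.

.MODEL_RHS <- "group * (series + content + position_c)^2"

.prep_model_frame <- function(deviations, jar_ratio) {
  .assert_cols(deviations, c("participant_id", "group", "jar_ratio", "content",
                             "series_id", "position", "deviation"), "`deviations`")
  d <- deviations[deviations$jar_ratio == jar_ratio, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no records for jar ratio %s", jar_ratio), call. = FALSE)
  d$group <- factor(d$group, levels = c("control", "patient"))
  d$series <- factor(d$series_id)
  d$content <- factor(d$content, levels = c("neutral", "emotional"))
  d$position_c <- d$position - 5.5    # centred so "main" effects average over positions
  d <- d[order(d$participant_id), , drop = FALSE]
  d
}

#' Fit a population-averaged model of the deviation score
#'
#' Fits a marginal linear model of `deviation` on Group, Series, Content and
#' Position (numeric, centred at 5.5) including all two- and three-way
#' interactions involving Group, clustered by participant, with an
#' exchangeable working correlation and robust (sandwich) standard errors.
#' Each jar-ratio condition is analysed separately. Factors use sum-to-zero
#' contrasts so the Group term is the balanced average group effect.
#' Term-level Wald chi-squared tests use the robust covariance.
#'
#' @param deviations A deviation table from [deviation_table()].
#' @param jar_ratio `"60:40"` or `"80:20"`; the subset analysed.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param tol,max_iter Convergence tolerance and iteration cap for the
#'   estimating-equation loop.
#' @return A `beads_gee` object: coefficients, robust and model-based
#'   covariances, the working-correlation estimate `alpha`, scale `phi`,
#'   term-level Wald table, convergence diagnostics, and the factor
#'   structure needed for [ls_means_contrasts()].
#' @export
fit_marginal_model <- function(deviations, jar_ratio = c("60:40", "80:20"),
                               corstr = c("exchangeable", "independence"),
                               tol = 1e-10, max_iter = 50L) {
  jar_ratio <- match.arg(jar_ratio)
  corstr <- match.arg(corstr)
  d <- .prep_model_frame(deviations, jar_ratio)
  if (any(table(unique(d[c("participant_id", "group")])$group) < 2L)) {
    stop("need at least 2 clusters (participants) per group", call. = FALSE)
  }
  if (stats::var(d$deviation) == 0) {
    stop("degenerate outcome: deviation has zero variance", call. = FALSE)
  }
  contr <- list(group = "contr.sum", series = "contr.sum", content = "contr.sum")
  ff <- stats::as.formula(paste("deviation ~", .MODEL_RHS))
  mf <- stats::model.frame(ff, data = d)
  terms_obj <- attr(mf, "terms")
  X <- stats::model.matrix(terms_obj, mf, contrasts.arg = contr)
  y <- stats::model.response(mf)
  cl <- factor(d$participant_id)
  p <- ncol(X)
  N <- nrow(X)
  n_cl <- nlevels(cl)
  m_i <- as.integer(table(cl))

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- solve(XtX, Xty)             # OLS start
  alpha <- 0
  phi <- NA_real_
  converged <- FALSE
  iter <- 0L
  max_m <- max(m_i)
  repeat {
    iter <- iter + 1L
    e <- as.numeric(y - X %*% beta)
    phi <- sum(e^2) / (N - p)
    if (corstr == "exchangeable") {
      cs_e <- rowsum(e, cl)           # per-cluster residual sums
      cs_e2 <- rowsum(e^2, cl)
      num <- sum(cs_e^2 - cs_e2) / 2
      den <- (sum(m_i * (m_i - 1)) / 2 - p) * phi
      alpha_new <- num / den
      alpha_new <- min(max(alpha_new, -1 / (max_m - 1) + 1e-6), 0.99)
    } else alpha_new <- 0
    g <- alpha_new / (1 + (m_i - 1) * alpha_new)   # per-cluster J-weight
    S <- rowsum(X, cl)                             # n_cl x p cluster sums
    sy <- rowsum(y, cl)
    A <- (XtX - crossprod(S, g * S)) / (1 - alpha_new)
    bvec <- (Xty - crossprod(S, g * sy)) / (1 - alpha_new)
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    alpha <- alpha_new
    if (delta < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  e <- as.numeric(y - X %*% beta)
  g <- alpha / (1 + (m_i - 1) * alpha)
  S <- rowsum(X, cl)
  A <- (XtX - crossprod(S, g * S)) / (1 - alpha)
  A_inv <- solve(A)
  # sandwich: meat = sum_i (X_i' R^{-1} e_i)(...)'
  z <- (e - (g * rowsum(e, cl))[as.integer(cl)]) / (1 - alpha)
  U <- rowsum(X * z, cl)
  meat <- crossprod(U)
  vcov_rob <- A_inv %*% meat %*% A_inv
  vcov_naive <- phi * A_inv
  dimnames(vcov_rob) <- dimnames(vcov_naive) <- list(colnames(X), colnames(X))
  beta <- drop(beta); names(beta) <- colnames(X)

  fit <- structure(list(
    coefficients = beta, vcov = vcov_rob, vcov_naive = vcov_naive,
    alpha = alpha, phi = phi, corstr = corstr,
    n_clusters = n_cl, n_obs = N, jar_ratio = jar_ratio,
    converged = converged, iterations = iter,
    terms = terms_obj, contrasts = attr(X, "contrasts"),
    xlevels = stats::.getXlevels(terms_obj, mf),
    assign = attr(X, "assign"),
    groups_present = levels(droplevels(d$group))
  ), class = "beads_gee")
  if (!converged) {
    warning(sprintf("estimating equations did not converge in %d iterations (last step %.3g)",
                    iter, delta), call. = FALSE)
  }
  fit$term_table <- .wald_term_table(fit)
  fit
}

# robust Wald chi-squared per model term
.wald_term_table <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  out <- lapply(seq_along(labels), function(k) {
    idx <- which(fit$assign == k)
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    chi2 <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    data.frame(term = labels[k], wald_chisq = chi2, df = length(idx),
               p = stats::pchisq(chi2, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.beads_gee <- function(x, digits = 3, ...) {
  cat(sprintf("Marginal model of deviation, jar ratio %s\n", x$jar_ratio))
  cat(sprintf("  %d observations in %d clusters; working correlation %s (alpha = %.3f), scale %.3f\n",
              x$n_obs, x$n_clusters, x$corstr, x$alpha, x$phi))
  if (!x$converged) cat("  WARNING: not converged\n")
  cat("\nWald tests (robust covariance):\n")
  tt <- x$term_table
  tt$wald_chisq <- round(tt$wald_chisq, 1)
  tt$p <- signif(tt$p, 2)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Least-squares means and group contrasts
#'
#' Model-based mean deviation per Group x Series x Content cell, with
#' Position held at its midpoint (5.5) and balanced weights over the
#' factors, plus the control-minus-patient difference per cell with robust
#' SE, two-sided p and 95% CI.
#'
#' @param fit A `beads_gee` from [fit_marginal_model()].
#' @param adjust `"none"` (default, matching the unadjusted reporting
#'   convention) or `"holm"` for a Holm correction over the contrast table.
#' @return Data frame with one row per content x series cell: group means
#'   and SEs, `diff` (control - patient), `se_diff`, `p`, `ci_lower`,
#'   `ci_upper`, and `significant` at the 0.05 level.
#' @export
ls_means_contrasts <- function(fit, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "beads_gee"))
  if (length(fit$groups_present) < 2L) {
    stop("model was fitted on a single group; no group contrast possible", call. = FALSE)
  }
  grid <- expand.grid(group = factor(c("control", "patient"),
                                     levels = fit$xlevels$group),
                      series = factor(fit$xlevels$series, levels = fit$xlevels$series),
                      content = factor(fit$xlevels$content, levels = fit$xlevels$content),
                      KEEP.OUT.ATTRS = FALSE)
  grid$position_c <- 0
  Xg <- stats::model.matrix(stats::delete.response(fit$terms), grid,
                            contrasts.arg = fit$contrasts)
  est <- drop(Xg %*% fit$coefficients)
  se <- sqrt(rowSums((Xg %*% fit$vcov) * Xg))
  grid$mean <- est
  grid$se <- se
  cells <- unique(grid[c("series", "content")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- grid$series == cells$series[i] & grid$content == cells$content[i]
    gc <- grid[sel & grid$group == "control", ]
    gp <- grid[sel & grid$group == "patient", ]
    cvec <- Xg[which(sel & grid$group == "control"), ] -
            Xg[which(sel & grid$group == "patient"), ]
    se_d <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    diff <- gc$mean - gp$mean
    z <- diff / se_d
    data.frame(content = as.character(cells$content[i]),
               series_id = as.integer(as.character(cells$series[i])),
               control_mean = gc$mean, control_se = gc$se,
               patient_mean = gp$mean, patient_se = gp$se,
               diff = diff, se_diff = se_d,
               p = 2 * stats::pnorm(-abs(z)),
               ci_lower = diff - stats::qnorm(0.975) * se_d,
               ci_upper = diff + stats::qnorm(0.975) * se_d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Correlations between clinical delusion measures and deviation aggregates
#'
#' Pearson correlations, on patients only, between clinical measures and
#' per-participant deviation aggregates (any level produced by
#' [aggregate_deviations()]), computed per aggregate cell (jar ratio x
#' content x series/pair where applicable). Pairs with fewer than 3
#' complete observations or zero variance are flagged rather than dropped.
#'
#' @param aggregates An aggregate table from [aggregate_deviations()], or a
#'   named list of such tables (the battery), in which case results are
#'   stacked with a `level` column.
#' @param participants A cohort/participant table containing
#'   `participant_id` and the clinical measure columns.
#' @param measures Character vector of clinical measure column names.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame: `level`, `measure`, `jar_ratio`, `content`, `cell`,
#'   `r`, `p`, `n`, `flag`.
#' @export
symptom_correlations <- function(aggregates, participants,
                                 measures = c("PANSS_P1", "PSYRATS_D", "PSYRATS_D6"),
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(aggregates)) {
    lvl <- attr(aggregates, "level")
    aggregates <- stats::setNames(list(aggregates),
                                  if (is.null(lvl)) "aggregate" else lvl)
  }
  .assert_cols(participants, c("participant_id", measures), "`participants`")
  pat <- participants[participants$group == "patient", , drop = FALSE]
  if (nrow(pat) == 0L) stop("no patients in `participants`", call. = FALSE)
  out <- list()
  for (lvl in names(aggregates)) {
    agg <- aggregates[[lvl]]
    agg <- agg[agg$group == "patient" & !agg$missing, , drop = FALSE]
    cell_cols <- intersect(c("series_id", "pair"), names(agg))
    key_cols <- c("jar_ratio", "content", cell_cols)
    cells <- unique(agg[key_cols])
    for (i in seq_len(nrow(cells))) {
      sel <- rep(TRUE, nrow(agg))
      for (kc in key_cols) sel <- sel & agg[[kc]] == cells[[kc]][i]
      sub <- agg[sel, , drop = FALSE]
      x <- sub$mean_deviation[match(pat$participant_id, sub$participant_id)]
      for (ms in measures) {
        yv <- pat[[ms]]
        ok <- stats::complete.cases(x, yv)
        n_ok <- sum(ok)
        flag <- ""
        r <- p <- NA_real_
        if (n_ok < 3L) {
          flag <- "insufficient-n"
        } else if (stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) {
          flag <- "zero-variance"
        } else {
          ct <- stats::cor.test(x[ok], yv[ok], method = "pearson",
                                alternative = "two.sided")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        out[[length(out) + 1L]] <- data.frame(
          level = lvl, measure = ms,
          jar_ratio = cells$jar_ratio[i], content = cells$content[i],
          cell = if (length(cell_cols)) paste(vapply(cell_cols, function(kc)
            as.character(cells[[kc]][i]), ""), collapse = "/") else "all",
          r = r, p = p, n = n_ok, flag = flag, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  rownames(out) <- NULL
  out
}

#' Build and correlate the full aggregate battery
#'
#' Convenience wrapper: computes all four aggregation levels from a deviation
#' table and runs [symptom_correlations()] on the stack.
#'
#' @inheritParams symptom_correlations
#' @param deviations A deviation table from [deviation_table()].
#' @return See [symptom_correlations()].
#' @export
correlation_battery <- function(deviations, participants,
                                measures = c("PANSS_P1", "PSYRATS_D", "PSYRATS_D6"),
                                adjust = c("none", "holm")) {
  battery <- stats::setNames(
    lapply(.AGG_LEVELS, function(l) aggregate_deviations(deviations, l)),
    .AGG_LEVELS)
  symptom_correlations(battery, participants, measures, adjust)
}

#' Demographic comparisons between groups
#'
#' Sex: Pearson chi-squared on the 2x2 contingency table without continuity
#' correction. Age: Welch two-sample t-test (unequal variances), reported as
#' control minus patient.
#'
#' @param participants Participant table with `participant_id`, `group`,
#'   `age`, `sex`.
#' @return Data frame with `variable`, `statistic`, `value`, `df`, `p`.
#' @export
demographics_tests <- function(participants) {
  .assert_cols(participants, c("group", "age", "sex"), "`participants`")
  if (length(unique(participants$group)) < 2L) {
    stop("both groups must be present", call. = FALSE)
  }
  tab <- table(participants$group, participants$sex)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  a_c <- participants$age[participants$group == "control"]
  a_p <- participants$age[participants$group == "patient"]
  tt <- stats::t.test(a_c, a_p, var.equal = FALSE)
  data.frame(
    variable = c("sex", "age"),
    statistic = c("chi_squared", "welch_t"),
    value = c(unname(chi$statistic), unname(tt$statistic)),
    df = c(unname(chi$parameter), unname(tt$parameter)),
    p = c(chi$p.value, tt$p.value),
    stringsAsFactors = FALSE
  )
}

#' Welch t statistic from summary statistics
#'
#' Closed-form Welch (unequal-variance) two-sample t from group means, SDs
#' and sizes, with Welch-Satterthwaite degrees of freedom. The statistic is
#' `(mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' # age comparison from published group summaries (controls vs patients)
#' welch_t_summary(32.3, 10.9, 32, 37.0, 14.2, 30)
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared for a 2x2 table, no continuity correction
#'
#' @param counts 2x2 matrix of counts.
#' @return List with `chi_squared`, `df`, `p`.
#' @examples
#' chisq_2x2(matrix(c(14, 16, 14, 18), 2, byrow = TRUE))
#' @export
chisq_2x2 <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2L, 2L)))
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi_squared = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
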