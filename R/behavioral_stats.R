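# Subject-level dissociation statistics: pairwise correlations between
# retrieval success, precision and vividness, and two-predictor
# standardized regressions predicting each measure from the other two.
#
# For standardized variables the regression quantities have closed forms in
# the sample correlations:
#   R^2   = (r_y1^2 + r_y2^2 - 2 r_y1 r_y2 r_12) / (1 - r_12^2)
#   beta_j = (r_yj - r_yk r_12) / (1 - r_12^2)
#   t_j   = beta_j * sqrt( (n - 3) (1 - r_12^2) / (1 - R^2) )
#   F     = (R^2 / 2) / ((1 - R^2) / (n - 3)),  df = (2, n - 3)

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `r`, `p` (two-tailed, t transform with n - 2 df), `n`,
#'   and `se_z` (the Fisher-z standard error `1/sqrt(n - 3)`).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       se_z = 1 / sqrt(length(x) - 3))
}

#' Multiple R-squared from three pairwise correlations
#'
#' Variance in the outcome explained by two standardized predictors, given
#' the outcome-predictor correlations `r_y1`, `r_y2` and the
#' inter-predictor correlation `r_12`.
#'
#' @param r_y1,r_y2 Correlations of the outcome with predictors 1 and 2.
#' @param r_12 Correlation between the two predictors (|r_12| < 1).
#' @return R-squared.
#' @export
r2_from_correlations <- function(r_y1, r_y2, r_12) {
  if (abs(r_12) >= 1) stop("predictors are collinear (|r_12| = 1)", call. = FALSE)
  (r_y1^2 + r_y2^2 - 2 * r_y1 * r_y2 * r_12) / (1 - r_12^2)
}

#' Standardized two-predictor regression block from correlations
#'
#' Computes the full regression block (R-squared, F with its df,
#' standardized betas with t and two-tailed p per predictor, unexplained
#' variance) from the three pairwise correlations and the sample size.
#'
#' @param r_y1,r_y2 Outcome-predictor correlations.
#' @param r_12 Inter-predictor correlation.
#' @param n Number of observations (>= 4).
#' @param names Optional length-2 character vector of predictor names.
#' @return List: `r2`, `unexplained` (= 1 - r2), `f`, `df` (c(2, n - 3)),
#'   `p_f`, and per-predictor `beta`, `t`, `p` (named vectors).
#' @export
regression_from_correlations <- function(r_y1, r_y2, r_12, n,
                                         names = c("x1", "x2")) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (abs(r_12) >= 1)
    stop(sprintf("predictors '%s' and '%s' are collinear", names[1], names[2]),
         call. = FALSE)
  r2 <- r2_from_correlations(r_y1, r_y2, r_12)
  beta <- c((r_y1 - r_y2 * r_12), (r_y2 - r_y1 * r_12)) / (1 - r_12^2)
  df2 <- n - 3
  tval <- beta * sqrt(df2 * (1 - r_12^2) / (1 - r2))
  pval <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
  f <- (r2 / 2) / ((1 - r2) / df2)
  names(beta) <- names(tval) <- names(pval) <- names
  list(r2 = r2, unexplained = 1 - r2, f = f, df = c(2, df2),
       p_f = pf(f, 2, df2, lower.tail = FALSE),
       beta = beta, t = tval, p = pval, n = n)
}

#' Standardized two-predictor regression from data
#'
#' Computes the sample correlations and applies
#' [regression_from_correlations]; equivalent to an ordinary least-squares
#' fit on z-scored variables.
#'
#' @param y Outcome vector.
#' @param x1,x2 Predictor vectors.
#' @param names Optional predictor names (defaults to the argument names).
#' @return A regression block as in [regression_from_correlations].
#' @export
standardized_regression <- function(y, x1, x2, names = NULL) {
  if (is.null(names))
    names <- c(deparse(substitute(x1)), deparse(substitute(x2)))
  n <- length(y)
  if (n < 4 || length(x1) != n || length(x2) != n)
    stop("need equal-length vectors with n >= 4", call. = FALSE)
  if (sd(y) == 0 || sd(x1) == 0 || sd(x2) == 0)
    stop("constant vector: correlations undefined", call. = FALSE)
  regression_from_correlations(cor(y, x1), cor(y, x2), cor(x1, x2), n, names)
}

#' Build the success/precision/vividness dissociation report
#'
#' From per-subject summaries (one row per subject with columns
#' `retrieval_success`, `precision`, `vividness`), computes all three
#' pairwise correlations and the three standardized regressions predicting
#' each measure from the other two, with the unexplained variance per
#' outcome.
#'
#' @param summaries Data frame of subject summaries (>= 4 subjects).
#' @return A `dissociation_report`: `correlations` (list of pearson_r
#'   results keyed `success_precision`, `success_vividness`,
#'   `precision_vividness`) and `regressions` (list keyed by outcome).
#' @export
build_dissociation_report <- function(summaries) {
  need <- c("retrieval_success", "precision", "vividness")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(summaries) < 4) stop("need >= 4 subjects", call. = FALSE)
  s <- summaries$retrieval_success
  p <- summaries$precision
  v <- summaries$vividness
  cors <- list(success_precision = pearson_r(s, p),
               success_vividness = pearson_r(s, v),
               precision_vividness = pearson_r(p, v))
  regs <- list(
    success = standardized_regression(s, v, p,
                                      names = c("vividness", "precision")),
    precision = standardized_regression(p, v, s,
                                        names = c("vividness", "success")),
    vividness = standardized_regression(v, s, p,
                                        names = c("success", "precision")))
  structure(list(correlations = cors, regressions = regs,
                 n_subjects = nrow(summaries)),
            class = "dissociation_report")
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat(sprintf("Dissociation report (n = %d subjects)\n", x$n_subjects))
  cat("Pairwise correlations:\n")
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %-20s r = %6.3f  p = %.4f\n", nm, co$r, co$p))
  }
  cat("Regressions (outcome ~ other two, standardized):\n")
  for (nm in names(x$regressions)) {
    rg <- x$regressions[[nm]]
    cat(sprintf("  %-10s R2 = %.3f  F(%d,%d) = %.2f  p = %.4f  unexplained = %.1f%%\n",
                nm, rg$r2, rg$df[1], rg$df[2], rg$f, rg$p_f,
                100 * rg$unexplained))
    for (pr in names(rg$beta))
      cat(sprintf("    %-12s beta = %.3f  t(%d) = %.2f  p = %.4f\n",
                  pr, rg$beta[pr], rg$df[2], rg$t[pr], rg$p[pr]))
  }
  invisible(x)
}

#' Per-subject summaries from a trial table and vividness ratings
#'
#' Fits the target + uniform mixture (`M2_VM_UNIF`) to each subject's
#' errors and joins the subject's mean vividness, producing the triplet of
#' subject-level measures that enters [build_dissociation_report].
#'
#' @param trials Trial table with `subject`, `target_deg`, `response_deg`.
#' @param ratings Data frame with `subject` and `vividness` columns.
#' @param n_starts,seed,mu_mode Passed to [fit_model].
#' @return Data frame: `subject`, `retrieval_success` (p_target),
#'   `precision` (kappa), `vividness` (mean rating).
#' @export
subject_summaries <- function(trials, ratings, n_starts = 10, seed = NULL,
                              mu_mode = "fixed") {
  subjects <- sort(unique(trials$subject))
  out <- lapply(seq_along(subjects), function(i) {
    sj <- subjects[i]
    es <- error_set_from_trials(trials[trials$subject == sj, ])
    fit <- fit_model(es, "M2_VM_UNIF", n_starts = n_starts,
                     seed = if (is.null(seed)) NULL else seed + i,
                     mu_mode = mu_mode)
    data.frame(subject = sj, retrieval_success = fit$p_target,
               precision = fit$kappa,
               vividness = mean(ratings$vividness[ratings$subject == sj]))
  })
  do.call(rbind, out)
}
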