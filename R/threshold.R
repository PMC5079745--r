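# Model-derived success cutoff, trial classification, and trial-level
# precision.
#
# Under the target + uniform mixture, the posterior probability that an
# error x came from the von Mises (target) component is
#   P(target | x) = pT f_vM(x; kappa) / [pT f_vM(x; kappa) + (1 - pT)/360].
# The success cutoff is the |x| at which this posterior falls to alpha
# (default 5%), which has the closed form
#   cos(x * pi/180) = ln( (alpha/(1-alpha)) * ((1-pT)/pT) * I0(kappa) ) / kappa.

#' Posterior probability that an error came from the target component
#'
#' @param x Signed error(s), degrees.
#' @param p_target Mixture proportion of the von Mises component.
#' @param kappa Concentration of the von Mises component.
#' @return Posterior responsibility of the target component at `x`.
#' @export
target_posterior <- function(x, p_target, kappa) {
  num <- p_target * vonmises_pdf(x, 0, kappa)
  num / (num + (1 - p_target) / 360)
}

#' Derive the success cutoff from pooled mixture parameters
#'
#' Solves for the error magnitude at which the posterior probability of the
#' target component reaches `alpha`. Degenerate regimes: if the posterior
#' never drops to `alpha` the cutoff is 180 (every error is classed
#' successful); if it is below `alpha` everywhere the cutoff is 0.
#'
#' @param p_target Pooled target proportion, strictly inside (0, 1).
#' @param kappa Pooled concentration, > 0.
#' @param alpha Posterior level (default 0.05).
#' @return A `threshold_spec`: `cutoff_deg` (exact solution),
#'   `cutoff_rounded` (nearest integer degree, the display form), `alpha`,
#'   and the parameters used.
#' @export
derive_cutoff <- function(p_target, kappa, alpha = 0.05) {
  if (!is.finite(p_target) || p_target <= 0 || p_target >= 1)
    stop("p_target must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  rhs <- (log(alpha / (1 - alpha)) + log((1 - p_target) / p_target) +
            bessel_i0(kappa, log = TRUE)) / kappa
  cutoff <- if (rhs > 1) 0 else if (rhs < -1) 180 else acos(rhs) * 180 / pi
  structure(list(cutoff_deg = cutoff,
                 cutoff_rounded = round(cutoff),
                 alpha = alpha, p_target = p_target, kappa = kappa),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "success cutoff: +/- %.3f deg (displayed as %d) at posterior level %.3f\n",
    x$cutoff_deg, x$cutoff_rounded, x$alpha))
  cat(sprintf("  from pooled fit: p_target = %.3f, kappa = %.3f\n",
              x$p_target, x$kappa))
  invisible(x)
}

#' Classify trials as successful and attach trial-level precision
#'
#' A trial is successful iff `|error| <= cutoff` (boundary inclusive).
#' Precision is `180 - |error|` degrees, defined only for successful trials
#' (`NA` otherwise), so it ranges over `[180 - cutoff, 180]`. Trials flagged
#' `omitted` are classified `NA`.
#'
#' @param trials Data frame with an `error` column (signed degrees) and
#'   optionally an `omitted` logical column.
#' @param spec A `threshold_spec` from [derive_cutoff], or a single numeric
#'   cutoff in degrees.
#' @param use_rounded Classify against the integer-rounded cutoff instead of
#'   the exact solution (default FALSE).
#' @return `trials` with added columns `success` (logical) and `precision`.
#' @export
classify_trials <- function(trials, spec, use_rounded = FALSE) {
  cutoff <- if (inherits(spec, "threshold_spec")) {
    if (use_rounded) spec$cutoff_rounded else spec$cutoff_deg
  } else as.numeric(spec)
  if (!"error" %in% names(trials))
    stop("trial table lacks an 'error' column", call. = FALSE)
  omitted <- if ("omitted" %in% names(trials)) trials$omitted else
    rep(FALSE, nrow(trials))
  abs_err <- abs(trials$error)
  success <- abs_err <= cutoff
  success[omitted] <- NA
  precision <- ifelse(!is.na(success) & success, 180 - abs_err, NA_real_)
  trials$success <- success
  trials$precision <- precision
  trials
}

#' Per-subject success rates
#'
#' @param classified Output of [classify_trials] with a `subject` column.
#' @return Data frame with one row per subject (`subject`, `n_trials`,
#'   `success_rate`); the mean and SD across subjects are attached as
#'   attributes `mean` and `sd`. Omitted trials are excluded; a subject
#'   with no classifiable trials is dropped with a warning.
#' @export
subject_success_rate <- function(classified) {
  if (!all(c("subject", "success") %in% names(classified)))
    stop("need 'subject' and 'success' columns (run classify_trials first)",
         call. = FALSE)
  keep <- !is.na(classified$success)
  dropped <- setdiff(unique(classified$subject),
                     unique(classified$subject[keep]))
  if (length(dropped))
    warning("subject(s) with no classifiable trials excluded: ",
            paste(dropped, collapse = ", "))
  d <- classified[keep, ]
  agg <- aggregate(success ~ subject, data = d, FUN = mean)
  ntr <- aggregate(success ~ subject, data = d, FUN = length)
  out <- data.frame(subject = agg$subject, n_trials = ntr$success,
                    success_rate = agg$success)
  attr(out, "mean") <- mean(out$success_rate)
  attr(out, "sd") <- sd(out$success_rate)
  out
}
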