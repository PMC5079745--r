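# Mixture models of continuous-report recall errors and their EM fitting.
#
# Three nested models for the signed error x (degrees, (-180, 180]):
#   M1_VM:         f(x) = vM(x; mu, kappa)
#   M2_VM_UNIF:    f(x) = pT * vM(x; mu, kappa) + pU / 360
#   M3_VM_UNIF_NT: f(x) = pT * vM + pU / 360
#                         + (pN / m) * sum_j vM(x - delta_j; mu, kappa)
# where delta_j are the wrapped offsets of the m non-target objects' feature
# values from the target value. The non-target component shares kappa and mu
# with the target component.

MODEL_IDS <- c("M1_VM", "M2_VM_UNIF", "M3_VM_UNIF_NT")

#' Construct an error set
#'
#' Bundles signed recall errors with, optionally, the per-trial wrapped
#' offsets of the non-target objects' feature values (needed by the swap
#' model `M3_VM_UNIF_NT`).
#'
#' @param errors Signed errors in degrees, `(-180, 180]`.
#' @param nontarget_offsets Optional numeric matrix, one row per trial, one
#'   column per non-target object; each entry a wrapped offset in degrees.
#' @return An object of class `error_set`.
#' @export
error_set <- function(errors, nontarget_offsets = NULL) {
  if (any(!is.finite(errors))) stop("errors must be finite", call. = FALSE)
  if (any(errors <= -180 | errors > 180))
    stop("errors must lie in (-180, 180]", call. = FALSE)
  if (!is.null(nontarget_offsets)) {
    nontarget_offsets <- as.matrix(nontarget_offsets)
    if (nrow(nontarget_offsets) != length(errors))
      stop("nontarget_offsets must have one row per trial", call. = FALSE)
  }
  structure(list(errors = as.numeric(errors),
                 nontarget_offsets = nontarget_offsets),
            class = "error_set")
}

#' Build an error set from a trial table
#'
#' @param trials Data frame with columns `target_deg`, `response_deg` and,
#'   optionally, `nontarget1_deg`, `nontarget2_deg`.
#' @return An `error_set`; non-target offsets are included when the
#'   non-target columns are present.
#' @export
error_set_from_trials <- function(trials) {
  need <- c("target_deg", "response_deg")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  err <- wrap_error(trials$response_deg, trials$target_deg)
  off <- NULL
  if (all(c("nontarget1_deg", "nontarget2_deg") %in% names(trials))) {
    off <- cbind(wrap_error(trials$nontarget1_deg, trials$target_deg),
                 wrap_error(trials$nontarget2_deg, trials$target_deg))
  }
  error_set(err, off)
}

# Per-trial mixture density (per degree). params: list(p_target, p_uniform,
# p_nontarget, kappa, mu).
mixture_density <- function(model_id, params, data) {
  model_id <- match.arg(model_id, MODEL_IDS)
  x <- data$errors
  mu <- if (is.null(params$mu)) 0 else params$mu
  dens <- params$p_target * vonmises_pdf(x, mu, params$kappa)
  if (model_id != "M1_VM")
    dens <- dens + params$p_uniform / 360
  if (model_id == "M3_VM_UNIF_NT") {
    off <- data$nontarget_offsets
    if (is.null(off) || ncol(off) == 0)
      stop("M3_VM_UNIF_NT requires non-target offsets", call. = FALSE)
    m <- ncol(off)
    nt <- 0
    for (j in seq_len(m))
      nt <- nt + vonmises_pdf(wrap_error(wrap_angle(x - off[, j]), 0),
                              mu, params$kappa)
    dens <- dens + params$p_nontarget / m * nt
  }
  dens
}

#' Negative log-likelihood of a mixture model
#'
#' @param model_id One of `"M1_VM"`, `"M2_VM_UNIF"`, `"M3_VM_UNIF_NT"`.
#' @param params List with `kappa`, `mu` (default 0), and the mixture
#'   weights appropriate to the model (`p_target`, `p_uniform`,
#'   `p_nontarget`); weights absent from a model are taken as 0.
#' @param data An [error_set].
#' @return The negative log-likelihood (natural log).
#' @export
neg_log_lik <- function(model_id, params, data) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (length(data$errors) == 0) stop("empty error set", call. = FALSE)
  params <- complete_params(model_id, params)
  -sum(log(mixture_density(model_id, params, data)))
}

complete_params <- function(model_id, params) {
  if (is.null(params$mu)) params$mu <- 0
  if (model_id == "M1_VM") { params$p_target <- 1; params$p_uniform <- 0; params$p_nontarget <- 0 }
  if (model_id == "M2_VM_UNIF") {
    if (is.null(params$p_uniform)) params$p_uniform <- 1 - params$p_target
    params$p_nontarget <- 0
  }
  if (model_id == "M3_VM_UNIF_NT" && is.null(params$p_nontarget))
    params$p_nontarget <- 1 - params$p_target - params$p_uniform
  params
}

# One EM run from a given start. Returns params + nll trace.
em_run <- function(model_id, data, start, mu_free, tol = 1e-6, max_iter = 500) {
  x <- data$errors
  n <- length(x)
  off <- data$nontarget_offsets
  m <- if (model_id == "M3_VM_UNIF_NT") ncol(off) else 0
  p <- complete_params(model_id, start)
  nll <- neg_log_lik(model_id, p, data)
  trace <- nll
  converged <- FALSE
  xr <- x * pi / 180
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities
    fT <- p$p_target * vonmises_pdf(x, p$mu, p$kappa)
    fU <- if (model_id == "M1_VM") 0 else rep(p$p_uniform / 360, n)
    fN <- NULL
    tot <- fT + fU
    if (m > 0) {
      fN <- matrix(0, n, m)
      for (j in seq_len(m))
        fN[, j] <- p$p_nontarget / m *
          vonmises_pdf(wrap_error(wrap_angle(x - off[, j]), 0), p$mu, p$kappa)
      tot <- tot + rowSums(fN)
    }
    tot[tot <= 0] <- .Machine$double.xmin
    rT <- fT / tot
    rU <- if (model_id == "M1_VM") rep(0, n) else fU / tot
    rN <- if (m > 0) fN / tot else NULL
    # M-step: weights
    if (model_id != "M1_VM") {
      p$p_target <- mean(rT)
      p$p_uniform <- mean(rU)
      p$p_nontarget <- if (m > 0) mean(rowSums(rN)) else 0
      # renormalize against accumulated rounding
      s <- p$p_target + p$p_uniform + p$p_nontarget
      p$p_target <- p$p_target / s; p$p_uniform <- p$p_uniform / s
      p$p_nontarget <- p$p_nontarget / s
    }
    # M-step: kappa (and mu if free) from responsibility-weighted resultant
    C <- sum(rT * cos(xr)); S <- sum(rT * sin(xr)); W <- sum(rT)
    if (m > 0) {
      for (j in seq_len(m)) {
        dj <- wrap_error(wrap_angle(x - off[, j]), 0) * pi / 180
        C <- C + sum(rN[, j] * cos(dj)); S <- S + sum(rN[, j] * sin(dj))
        W <- W + sum(rN[, j])
      }
    }
    if (W > 0) {
      if (mu_free) {
        p$mu <- atan2(S, C) * 180 / pi
        R <- sqrt(C^2 + S^2) / W
      } else {
        R <- max(C / W, 0)  # mu pinned at 0: only the cosine moment counts
      }
      p$kappa <- if (R >= 1) KAPPA_MAX else suppressWarnings(a1_inv(R))
    }
    nll_new <- neg_log_lik(model_id, p, data)
    trace <- c(trace, nll_new)
    if (abs(nll - nll_new) < tol) { converged <- TRUE; nll <- nll_new; break }
    nll <- nll_new
  }
  list(params = p, nll = nll, trace = trace, converged = converged)
}

random_start <- function(model_id) {
  kappa <- exp(runif(1, log(0.5), log(50)))
  k_wts <- switch(model_id, M1_VM = 1, M2_VM_UNIF = 2, M3_VM_UNIF_NT = 3)
  w <- rgamma(k_wts, 1)
  w <- w / sum(w)
  list(p_target = w[1],
       p_uniform = if (k_wts >= 2) w[2] else 0,
       p_nontarget = if (k_wts >= 3) w[3] else 0,
       kappa = kappa, mu = 0)
}

#' Fit a recall-error mixture model by EM
#'
#' Expectation-maximisation with multiple random starts: mixture weights are
#' Dirichlet-random, the concentration is drawn log-uniformly in `[0.5, 50]`,
#' and the best (lowest negative log-likelihood) solution wins, ties broken
#' by the lowest start index. The response-bias mean `mu` is fixed at 0 by
#' default (`mu_mode = "fixed"`); with `mu_mode = "free"` it is estimated as
#' the responsibility-weighted circular mean and counts as an extra free
#' parameter in AIC/BIC.
#'
#' @param data An [error_set] (>= 10 trials).
#' @param model_id One of `"M1_VM"`, `"M2_VM_UNIF"`, `"M3_VM_UNIF_NT"`.
#' @param n_starts Number of random starts (default 10).
#' @param seed Optional integer seed controlling the starts.
#' @param mu_mode `"fixed"` (mu = 0, the default) or `"free"`.
#' @param tol Convergence tolerance on the change in negative
#'   log-likelihood (default 1e-6).
#' @param max_iter Iteration cap per start (default 500).
#' @param extra_inits Optional list of parameter lists used as additional
#'   deterministic starts (e.g. a nested model's solution).
#' @return A `mixture_fit` object: parameter estimates, `log_lik`, `aic`,
#'   `bic`, `n_trials`, `converged`, `n_starts_used`, and the per-iteration
#'   negative log-likelihood trace (`nll_trace`) of the winning start.
#' @export
fit_model <- function(data, model_id, n_starts = 10, seed = NULL,
                      mu_mode = c("fixed", "free"), tol = 1e-6,
                      max_iter = 500, extra_inits = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  mu_mode <- match.arg(mu_mode)
  if (length(data$errors) < 10) stop("need >= 10 trials", call. = FALSE)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (model_id == "M3_VM_UNIF_NT" &&
      (is.null(data$nontarget_offsets) || ncol(data$nontarget_offsets) == 0))
    stop("M3_VM_UNIF_NT requires non-target offsets in the error set",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu_free <- mu_mode == "free"
  starts <- lapply(seq_len(n_starts), function(i) random_start(model_id))
  starts <- c(starts, extra_inits)
  best <- NULL
  for (s in starts) {
    run <- em_run(model_id, data, s, mu_free, tol, max_iter)
    if (is.null(best) || run$nll < best$nll - 1e-12) best <- run
  }
  if (!best$converged)
    warning("no EM start converged within the iteration cap; returning the best solution found")
  k <- switch(model_id, M1_VM = 1, M2_VM_UNIF = 2, M3_VM_UNIF_NT = 3) +
    as.integer(mu_free)
  n <- length(data$errors)
  ll <- -best$nll
  p <- best$params
  structure(list(
    model_id = model_id,
    p_target = p$p_target, p_uniform = p$p_uniform,
    p_nontarget = p$p_nontarget,
    kappa = p$kappa, mu = p$mu,
    log_lik = ll, n_params = k,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    n_trials = n, converged = best$converged,
    n_starts_used = length(starts), nll_trace = best$trace,
    mu_mode = mu_mode), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d, %s mu)\n", x$model_id, x$n_trials, x$mu_mode))
  cat(sprintf("  p_target = %.4f  p_uniform = %.4f  p_nontarget = %.4f\n",
              x$p_target, x$p_uniform, x$p_nontarget))
  cat(sprintf("  kappa = %.3f  mu = %.2f deg\n", x$kappa, x$mu))
  cat(sprintf("  logLik = %.3f  AIC = %.2f  BIC = %.2f  converged: %s\n",
              x$log_lik, x$aic, x$bic, x$converged))
  invisible(x)
}

#' Fit and compare the three recall-error models
#'
#' Fits `M1_VM`, `M2_VM_UNIF` and (when non-target offsets are present)
#' `M3_VM_UNIF_NT` to the same error set and tabulates AIC/BIC. Each model
#' additionally receives the next-simpler model's solution (with a small
#' mass on the new component) as a deterministic extra start, so the
#' log-likelihoods respect the nesting order at the optima.
#'
#' @inheritParams fit_model
#' @return A `model_comparison`: named list of fits, pairwise `delta_aic`
#'   and `delta_bic` matrices, and `winner_aic` / `winner_bic` model ids.
#' @export
compare_models <- function(data, n_starts = 10, seed = NULL,
                           mu_mode = c("fixed", "free")) {
  mu_mode <- match.arg(mu_mode)
  has_nt <- !is.null(data$nontarget_offsets) &&
    ncol(data$nontarget_offsets) > 0
  models <- if (has_nt) MODEL_IDS else MODEL_IDS[1:2]
  fits <- list()
  prev <- NULL
  for (i in seq_along(models)) {
    mid <- models[i]
    extra <- NULL
    if (!is.null(prev)) {
      # two deterministic nested starts: the simpler model's optimum with
      # exactly zero mass on the new component (EM keeps it at zero, so the
      # bigger model can never fall below the nested optimum), and a copy
      # with a small seed mass so the new component can grow
      at_prev <- list(p_target = prev$p_target, p_uniform = prev$p_uniform,
                      p_nontarget = prev$p_nontarget,
                      kappa = prev$kappa, mu = prev$mu)
      seeded <- at_prev
      seeded$p_target <- seeded$p_target * (1 - 1e-3)
      if (mid == "M2_VM_UNIF")
        seeded$p_uniform <- seeded$p_uniform + 1e-3 * prev$p_target
      if (mid == "M3_VM_UNIF_NT")
        seeded$p_nontarget <- seeded$p_nontarget + 1e-3 * prev$p_target
      extra <- list(at_prev, seeded)
    }
    fits[[mid]] <- fit_model(data, mid, n_starts = n_starts,
                             seed = if (is.null(seed)) NULL else seed + i,
                             mu_mode = mu_mode, extra_inits = extra)
    prev <- fits[[mid]]
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  structure(list(
    fits = fits,
    delta_aic = outer(aic, aic, `-`),
    delta_bic = outer(bic, bic, `-`),
    winner_aic = names(which.min(aic)),
    winner_bic = names(which.min(bic))), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(
    model = names(x$fits),
    logLik = vapply(x$fits, `[[`, numeric(1), "log_lik"),
    k = vapply(x$fits, `[[`, numeric(1), "n_params"),
    AIC = vapply(x$fits, `[[`, numeric(1), "aic"),
    BIC = vapply(x$fits, `[[`, numeric(1), "bic"))
  print(tab, row.names = FALSE)
  cat(sprintf("winner: AIC -> %s, BIC -> %s\n", x$winner_aic, x$winner_bic))
  invisible(x)
}

#' Serialize a fit or comparison to JSON
#'
#' @param x A `mixture_fit` or `model_comparison`.
#' @param path Output file.
#' @export
write_fit_json <- function(x, path) {
  strip <- function(f) f[setdiff(names(f), "nll_trace")]
  obj <- if (inherits(x, "mixture_fit")) strip(unclass(x))
  else {
    y <- unclass(x)
    y$fits <- lapply(y$fits, function(f) strip(unclass(f)))
    y$delta_aic <- as.data.frame(y$delta_aic)
    y$delta_bic <- as.data.frame(y$delta_bic)
    y
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
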