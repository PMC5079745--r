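# Fixture generators shared across test files. All draws are seeded by the
# caller so fixtures are reproducible.

# Errors from the target + uniform mixture (generative model M2).
make_m2_errors <- function(n, p_target = 0.62, kappa = 10.05, seed = 1) {
  set.seed(seed)
  comp <- runif(n) < p_target
  err <- ifelse(comp, sample_vonmises(n, 0, kappa), runif(n, -180, 180))
  wrap_error(wrap_angle(err), 0)
}

# An error set with plausible non-target offsets (two per trial, at least
# 62.04 degrees from the target and from each other).
make_error_set_with_offsets <- function(n, p_target = 0.62, kappa = 10.05,
                                        seed = 1) {
  err <- make_m2_errors(n, p_target, kappa, seed)
  off <- cbind(runif(n, 70, 170), -runif(n, 70, 170))
  error_set(err, off)
}

# Independent density oracle: von Mises density per degree written from the
# definition, not via the package's vonmises_pdf.
oracle_dvm <- function(x, mu, kappa) {
  exp(kappa * cos((x - mu) * pi / 180)) / (360 * besselI(kappa, 0))
}

# Independent mixture NLL oracle by direct per-trial summation.
oracle_nll <- function(params, errors, offsets = NULL) {
  pT <- params$p_target; pU <- params$p_uniform
  pN <- if (is.null(params$p_nontarget)) 0 else params$p_nontarget
  mu <- if (is.null(params$mu)) 0 else params$mu
  total <- 0
  for (i in seq_along(errors)) {
    d <- pT * oracle_dvm(errors[i], mu, params$kappa) + pU / 360
    if (pN > 0) {
      m <- ncol(offsets)
      for (j in seq_len(m)) {
        dd <- (errors[i] - offsets[i, j]) %% 360
        if (dd > 180) dd <- dd - 360
        d <- d + pN / m * oracle_dvm(dd, mu, params$kappa)
      }
    }
    total <- total - log(d)
  }
  total
}
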