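# Angle arithmetic and von Mises numerics. All public interfaces are in
# degrees; radians appear only inside trig calls.

#' Maximum admissible von Mises concentration
#'
#' Concentration estimates are capped at this value to prevent divergence on
#' near-degenerate data (all errors identical).
#' @export
KAPPA_MAX <- 500

#' Normalize angles into [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`.
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("angles must be finite numeric values", call. = FALSE)
  x %% 360
}

#' Signed circular difference between response and target
#'
#' Computes `response - target` mapped into the half-open interval
#' `(-180, 180]`, the canonical signed recall error. The boundary case of a
#' 180-degree difference is represented as +180, never -180.
#'
#' @param response,target Numeric vectors of angles in degrees, `[0, 360)`.
#' @return Signed errors in degrees, in `(-180, 180]`.
#' @examples
#' wrap_error(10, 350)  # +20: wraps across 0
#' wrap_error(350, 10)  # -20
#' wrap_error(180, 0)   # +180, the boundary convention
#' @export
wrap_error <- function(response, target) {
  if (any(!is.finite(response)) || any(!is.finite(target)))
    stop("wrap_error: inputs must be finite", call. = FALSE)
  d <- (response - target) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Modified Bessel function of the first kind, order zero
#'
#' Thin wrapper around [base::besselI] returning `I0(kappa)`; use
#' `log = TRUE` for the log value (computed via the exponentially scaled
#' Bessel function, stable up to very large concentrations).
#'
#' @param kappa Non-negative concentration.
#' @param log Return the natural log of `I0`?
#' @export
bessel_i0 <- function(kappa, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  if (log) kappa + base::log(besselI(kappa, 0, expon.scaled = TRUE))
  else besselI(kappa, 0)
}

#' von Mises density on the degree scale
#'
#' Density per degree of the von Mises distribution with mean `mu` and
#' concentration `kappa`:
#' `f(x) = exp(kappa * cos((x - mu) * pi / 180)) / (360 * I0(kappa))`.
#' Integrates to 1 over any 360-degree interval; `kappa = 0` is the uniform
#' circular density 1/360.
#'
#' @param x Signed errors (degrees).
#' @param mu Mean direction (degrees), default 0.
#' @param kappa Concentration, `>= 0`.
#' @return Density per degree.
#' @export
vonmises_pdf <- function(x, mu = 0, kappa) {
  if (any(!is.finite(x)) || !is.finite(mu)) stop("non-finite input", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be finite and >= 0", call. = FALSE)
  d <- wrap_error(wrap_angle(x), wrap_angle(mu)) * pi / 180
  # scaled form exp(kappa*(cos(d)-1)) / (360 * I0e(kappa)) avoids overflow
  exp(kappa * (cos(d) - 1)) / (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mean resultant length of the von Mises distribution
#'
#' `a1(kappa) = I1(kappa) / I0(kappa)`, the expected resultant length;
#' strictly increasing from 0 at `kappa = 0` towards 1.
#'
#' @param kappa Non-negative concentration.
#' @export
a1 <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Invert the mean resultant length to a concentration
#'
#' Solves `a1(kappa) = R` using the standard three-regime closed-form
#' approximation refined by Newton steps, so that `a1_inv(a1(k))` recovers
#' `k` to high accuracy. `R >= 1` (degenerate, all angles identical) returns
#' [KAPPA_MAX] with a warning.
#'
#' @param R Resultant length in `[0, 1)`.
#' @return Concentration in `[0, KAPPA_MAX]`.
#' @export
a1_inv <- function(R) {
  if (length(R) != 1 || !is.finite(R) || R < 0)
    stop("R must be a single finite value >= 0", call. = FALSE)
  if (R >= 1) {
    warning("resultant length >= 1; returning the concentration ceiling")
    return(KAPPA_MAX)
  }
  if (R == 0) return(0)
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  # Newton refinement: d a1/d kappa = 1 - a1/kappa - a1^2
  for (i in 1:8) {
    Ak <- a1(k)
    dA <- 1 - Ak / k - Ak^2
    if (!is.finite(dA) || dA <= 0) break
    step <- (Ak - R) / dA
    k <- k - step
    if (k <= 0) { k <- 1e-8 }
    if (abs(step) < 1e-10) break
  }
  min(max(k, 0), KAPPA_MAX)
}

#' Draw von Mises samples (degrees)
#'
#' Rejection sampler of Best and Fisher (1979). `kappa = 0` falls back to
#' uniform draws on the circle. Reproducible when `seed` is given; otherwise
#' consumes the current RNG stream.
#'
#' @param n Number of samples.
#' @param mu Mean direction in degrees (default 0).
#' @param kappa Concentration, `>= 0`.
#' @param seed Optional integer seed.
#' @return Signed angles in `(-180, 180]` relative to 0 (i.e. centred
#'   samples shifted by `mu` and re-wrapped).
#' @export
sample_vonmises <- function(n, mu = 0, kappa, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be finite and >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (kappa == 0) {
    theta <- runif(n, -pi, pi)
  } else {
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    theta <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- n - got
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      nok <- sum(ok)
      if (nok > 0) {
        theta[(got + 1):(got + nok)] <-
          sign(u3[ok] - 0.5) * acos(f[ok])
        got <- got + nok
      }
    }
  }
  wrap_error(wrap_angle(theta * 180 / pi + mu), 0)
}
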