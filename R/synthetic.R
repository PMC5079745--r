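# Synthetic continuous-report memory experiments.
#
# Emulates a scanned object-feature memory task: 48 displays of 3 objects,
# each object defined by a color, an orientation and a location on circular
# 0-360 spaces with a minimum within-display separation per feature; 8
# blocks of 6 displays; per display 2 of the 3 objects are tested on all 3
# features (6 judgments); a 0-100 vividness rating precedes the feature
# judgments. Subject heterogeneity in retrieval success, precision and
# vividness is generated from a Gaussian copula so the three measures
# correlate across subjects.

#' Default population parameters of the synthetic cohort
#'
#' Across-subject means and SDs of the target proportion (logit-normal),
#' concentration (log-normal) and mean vividness (normal, clamped to
#' 0-100), plus the within-subject SD of single vividness ratings.
#' @return Named list of population parameters.
#' @export
default_population <- function() {
  list(p_target_mean = 0.62, p_target_sd = 0.16,
       kappa_mean = 10.05, kappa_sd = 3.41,
       vividness_mean = 48.23, vividness_sd = 15.83,
       vividness_within_sd = 20)
}

#' Default experiment design
#'
#' @param n_subjects Number of subjects (default 20).
#' @param missing_block Optional list(subject=, block=) marking one
#'   subject's block as excluded (default: subject 1 loses block 1,
#'   emulating a lost first scan run).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(n_subjects = 20,
                              missing_block = list(subject = 1, block = 1)) {
  structure(list(
    n_subjects = n_subjects, n_blocks = 8, displays_per_block = 6,
    objects_per_display = 3, tested_objects = 2,
    features = c("color", "orientation", "location"),
    min_feature_distance = 62.04,
    missing_block = missing_block), class = "experiment_design")
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Generate stimulus displays under a minimum feature separation
#'
#' Feature values for each object are drawn uniformly on `[0, 360)`,
#' rejection-sampled (per display and feature independently) until all
#' same-feature pairwise circular distances within a display are at least
#' `min_dist`.
#'
#' @param n_displays Number of displays (default 48).
#' @param n_objects Objects per display (default 3).
#' @param min_dist Minimum pairwise circular distance in degrees
#'   (default 62.04).
#' @param features Feature names.
#' @param seed Optional integer seed.
#' @return Data frame: `display`, `object`, one column per feature.
#' @export
generate_displays <- function(n_displays = 48, n_objects = 3,
                              min_dist = 62.04,
                              features = c("color", "orientation", "location"),
                              seed = NULL) {
  if (n_objects * min_dist >= 360)
    stop("infeasible: n_objects * min_dist must be < 360", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_feature <- function() {
    repeat {
      v <- runif(n_objects, 0, 360)
      if (n_objects < 2) return(v)
      pairs <- combn(n_objects, 2)
      if (all(circ_dist(v[pairs[1, ]], v[pairs[2, ]]) >= min_dist)) return(v)
    }
  }
  out <- expand.grid(object = seq_len(n_objects),
                     display = seq_len(n_displays))[, c("display", "object")]
  for (f in features) out[[f]] <- NA_real_
  for (d in seq_len(n_displays)) {
    rows <- out$display == d
    for (f in features) out[[f]][rows] <- draw_feature()
  }
  out
}

#' Check a feature-order schedule against the counterbalancing rules
#'
#' @param schedule Character matrix, one row per slot, 3 columns (question
#'   positions 1-3), entries feature names.
#' @param max_run Maximum number of consecutive slots a feature may occupy
#'   the same position (default 4).
#' @return TRUE if every permutation of the three features appears equally
#'   often and no positional run exceeds `max_run`; FALSE otherwise.
#' @export
check_schedule <- function(schedule, max_run = 4) {
  perms <- apply(schedule, 1, paste, collapse = "-")
  counts <- table(perms)
  if (length(counts) != 6 || length(unique(counts)) != 1) return(FALSE)
  for (pos in 1:3) {
    r <- rle(schedule[, pos])
    if (any(r$lengths > max_run)) return(FALSE)
  }
  TRUE
}

#' Counterbalanced feature-order schedule
#'
#' Assigns one of the 6 permutations of (color, orientation, location) to
#' each retrieval slot so that each permutation occurs equally often and no
#' feature is tested at the same question position more than 4 slots in a
#' row. Generated by rejection shuffling with a retry cap; if the cap is
#' hit the RNG is advanced and a second pass attempted before erroring.
#'
#' @param n_slots Number of object-test slots; must be divisible by 6.
#' @param features The three feature names.
#' @param seed Optional integer seed.
#' @param max_tries Shuffles attempted per pass (default 1000).
#' @return Character matrix `n_slots` x 3 (question positions).
#' @export
feature_order_schedule <- function(n_slots,
                                   features = c("color", "orientation", "location"),
                                   seed = NULL, max_tries = 1000) {
  if (n_slots %% 6 != 0) stop("n_slots must be divisible by 6", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  pool <- rep(seq_len(6), each = n_slots / 6)
  for (pass in 1:2) {
    for (i in seq_len(max_tries)) {
      ord <- sample(pool)
      sched <- matrix(features[perms[ord, ]], ncol = 3)
      if (check_schedule(sched)) return(sched)
    }
  }
  stop("could not build a valid schedule within the retry cap", call. = FALSE)
}

# Moment-match a logit-normal to a target mean/sd by quadrature + optim.
logitnorm_match <- function(mean, sd) {
  moments <- function(mu, sigma) {
    g <- function(z) plogis(mu + sigma * z) * dnorm(z)
    m1 <- integrate(g, -10, 10)$value
    g2 <- function(z) plogis(mu + sigma * z)^2 * dnorm(z)
    m2 <- integrate(g2, -10, 10)$value
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- optim(c(qlogis(mean), log(1)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate subject-level generative models via a Gaussian copula
#'
#' Draws a latent trivariate standard normal with pairwise correlation
#' `target_corr` and maps the three coordinates to the subject measures:
#' target proportion through a moment-matched logit-normal, concentration
#' through a moment-matched log-normal, and mean vividness through a normal
#' clamped to `[0, 100]`. The copula induces the across-subject
#' correlations between success, precision and vividness that the
#' dissociation analysis measures.
#'
#' @param n_subjects Number of subjects.
#' @param population Population parameters (see [default_population]).
#' @param target_corr Common latent pairwise correlation (default 0.5); may
#'   also be a full 3x3 correlation matrix. Must be positive definite.
#' @param seed Optional integer seed.
#' @return Data frame: `subject`, `p_target`, `kappa`, `vividness_mean`,
#'   plus the latent traits `z_success`, `z_precision`, `z_vividness`.
#' @export
generate_subject_models <- function(n_subjects,
                                    population = default_population(),
                                    target_corr = 0.5, seed = NULL) {
  R <- if (is.matrix(target_corr)) target_corr else {
    m <- matrix(target_corr, 3, 3); diag(m) <- 1; m
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("target correlation matrix is not positive definite",
                         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n_subjects * 3), n_subjects, 3) %*% chol(R)
  # marginal maps, moment-matched to the population mean/SD
  pt <- if (population$p_target_sd > 0) {
    lm_ <- logitnorm_match(population$p_target_mean, population$p_target_sd)
    plogis(lm_$mu + lm_$sigma * z[, 1])
  } else rep(population$p_target_mean, n_subjects)
  kp <- if (population$kappa_sd > 0) {
    s2 <- log(1 + population$kappa_sd^2 / population$kappa_mean^2)
    exp(log(population$kappa_mean) - s2 / 2 + sqrt(s2) * z[, 2])
  } else rep(population$kappa_mean, n_subjects)
  vv <- pmin(pmax(population$vividness_mean +
                    population$vividness_sd * z[, 3], 0), 100)
  data.frame(subject = seq_len(n_subjects), p_target = pt,
             kappa = pmin(kp, KAPPA_MAX), vividness_mean = vv,
             z_success = z[, 1], z_precision = z[, 2], z_vividness = z[, 3])
}

#' Simulate continuous-report responses for a cohort
#'
#' For each subject, block, display, tested object and feature, draws the
#' signed error from the subject's generative mixture: with probability
#' `p_target` a von Mises deviation around the target value; otherwise a
#' uniform guess (`"M2"`), or — under `"M3"` — a von Mises deviation around
#' one of the two non-target objects' feature values with probability
#' `p_nontarget`. Blocks flagged missing in the design are dropped.
#'
#' @param design An [experiment_design].
#' @param subject_models Output of [generate_subject_models].
#' @param displays Output of [generate_displays]; generated (from `seed`)
#'   when NULL.
#' @param model_id Generative model: `"M1"`, `"M2"` (default) or `"M3"`.
#' @param p_nontarget Non-target (swap) probability under `"M3"`
#'   (default 0.1), taken out of the non-target+uniform mass.
#' @param seed Optional integer seed.
#' @return Trial table: `subject`, `block`, `display`, `object`, `feature`,
#'   `question_pos`, `target_deg`, `response_deg`, `error`,
#'   `nontarget1_deg`, `nontarget2_deg`, `omitted`.
#' @export
simulate_responses <- function(design, subject_models, displays = NULL,
                               model_id = c("M2", "M1", "M3"),
                               p_nontarget = 0.1, seed = NULL) {
  model_id <- match.arg(model_id)
  if (!is.null(seed)) set.seed(seed)
  feats <- design$features
  if (is.null(displays))
    displays <- generate_displays(
      design$n_blocks * design$displays_per_block,
      design$objects_per_display, design$min_feature_distance, feats)
  n_disp <- max(displays$display)
  # which 2 of the 3 objects are tested: fixed per display, same for all
  # subjects
  tested <- lapply(seq_len(n_disp), function(d)
    sort(sample(design$objects_per_display, design$tested_objects)))
  block_of <- rep(seq_len(design$n_blocks), each = design$displays_per_block)
  n_slots <- design$n_blocks * design$displays_per_block * design$tested_objects
  rows <- vector("list", design$n_subjects)
  for (sj in seq_len(design$n_subjects)) {
    sm <- subject_models[subject_models$subject == sj, ]
    sched <- feature_order_schedule(n_slots, feats)
    slot <- 0L
    recs <- vector("list", n_slots * 3L)
    ri <- 0L
    for (d in seq_len(n_disp)) {
      b <- block_of[d]
      skip <- !is.null(design$missing_block) &&
        sj == design$missing_block$subject && b == design$missing_block$block
      for (obj in tested[[d]]) {
        slot <- slot + 1L
        if (skip) next
        others <- setdiff(seq_len(design$objects_per_display), obj)
        drow <- displays[displays$display == d, ]
        for (qp in 1:3) {
          f <- sched[slot, qp]
          tgt <- drow[[f]][drow$object == obj]
          nt <- c(drow[[f]][drow$object == others[1]],
                  drow[[f]][drow$object == others[2]])
          u <- runif(1)
          err <- if (model_id == "M1" || u < sm$p_target) {
            sample_vonmises(1, 0, sm$kappa)
          } else if (model_id == "M3" &&
                     u < sm$p_target + p_nontarget) {
            wrap_error(wrap_angle(nt[sample(2, 1)] - tgt +
                                    sample_vonmises(1, 0, sm$kappa)), 0)
          } else {
            runif(1, -180, 180)
          }
          err <- wrap_error(wrap_angle(err), 0)
          ri <- ri + 1L
          recs[[ri]] <- data.frame(
            subject = sj, block = b, display = d, object = obj,
            feature = f, question_pos = qp, target_deg = tgt,
            response_deg = wrap_angle(tgt + err), error = err,
            nontarget1_deg = nt[1], nontarget2_deg = nt[2],
            omitted = FALSE)
        }
      }
    }
    rows[[sj]] <- do.call(rbind, recs[seq_len(ri)])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-display vividness ratings
#'
#' One rating per subject and display: the subject's mean vividness plus
#' normal noise, clamped to `[0, 100]` and quantized to the 100-point
#' response grid. Blocks flagged missing in the design are dropped.
#'
#' @param design An [experiment_design].
#' @param subject_models Output of [generate_subject_models].
#' @param seed Optional integer seed.
#' @return Data frame: `subject`, `block`, `display`, `vividness`.
#' @export
simulate_vividness <- function(design, subject_models, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  within_sd <- subject_models$vividness_within_sd
  if (is.null(within_sd)) within_sd <- default_population()$vividness_within_sd
  n_disp <- design$n_blocks * design$displays_per_block
  block_of <- rep(seq_len(design$n_blocks), each = design$displays_per_block)
  out <- expand.grid(display = seq_len(n_disp),
                     subject = seq_len(design$n_subjects))[, c("subject", "display")]
  out$block <- block_of[out$display]
  if (!is.null(design$missing_block))
    out <- out[!(out$subject == design$missing_block$subject &
                   out$block == design$missing_block$block), ]
  mu <- subject_models$vividness_mean[match(out$subject,
                                            subject_models$subject)]
  out$vividness <- round(pmin(pmax(mu + rnorm(nrow(out), 0, within_sd[1]),
                                   0), 100))
  rownames(out) <- NULL
  out[, c("subject", "block", "display", "vividness")]
}

#' Simulate a complete experiment
#'
#' Convenience wrapper chaining display generation, subject models,
#' responses and vividness ratings with sub-seeds derived from one master
#' seed.
#'
#' @param design An [experiment_design].
#' @param population Population parameters (see [default_population]).
#' @param target_corr Latent trait correlation (default 0.5).
#' @param model_id Generative model id (default `"M2"`).
#' @param seed Master integer seed.
#' @return List: `design`, `displays`, `subject_models`, `trials`,
#'   `ratings`, `seed`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                population = default_population(),
                                target_corr = 0.5, model_id = "M2",
                                seed = 1) {
  displays <- generate_displays(
    design$n_blocks * design$displays_per_block,
    design$objects_per_display, design$min_feature_distance,
    design$features, seed = seed)
  models <- generate_subject_models(design$n_subjects, population,
                                    target_corr, seed = seed + 1)
  models$vividness_within_sd <- population$vividness_within_sd
  trials <- simulate_responses(design, models, displays, model_id,
                               seed = seed + 2)
  ratings <- simulate_vividness(design, models, seed = seed + 3)
  list(design = design, displays = displays, subject_models = models,
       trials = trials, ratings = ratings, seed = seed)
}
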