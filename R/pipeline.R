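# End-to-end pipeline: simulate -> fit -> compare -> threshold -> classify
# -> summarize -> report, plus the fMRI-style event-table export.

#' Default pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory (created if missing); NULL writes
#'   nothing to disk.
#' @param ... Overrides for any default field: `n_subjects`, `target_corr`,
#'   `model_id`, `n_starts`, `alpha`, `mu_mode`, `use_rounded_cutoff`,
#'   `export_events`, `population`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, ...) {
  cfg <- list(seed = seed, out_dir = out_dir, n_subjects = 20,
              target_corr = 0.5, model_id = "M2", n_starts = 10,
              alpha = 0.05, mu_mode = "fixed", use_rounded_cutoff = FALSE,
              export_events = FALSE, population = default_population())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$n_starts >= 1,
            cfg$n_subjects >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a trial table from CSV
#'
#' @param path CSV with columns `subject`, `block`, `display`, `object`,
#'   `feature`, `target_deg`, `response_deg` (and optionally the non-target
#'   columns). The signed `error` column is recomputed if absent.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "target_deg", "response_deg")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"error" %in% names(tr))
    tr$error <- wrap_error(tr$response_deg, tr$target_deg)
  tr
}

write_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ITI jitter in seconds: shifted-exponential approximation of the task's
# Poisson-like 400-2800 ms fixation, mean near 961 ms.
sample_iti <- function(n) {
  x <- 0.4 + rexp(n, 1 / 0.5611)
  while (any(x > 2.8)) {
    bad <- x > 2.8
    x[bad] <- 0.4 + rexp(sum(bad), 1 / 0.5611)
  }
  x
}

#' Build an fMRI-style event table from classified trials
#'
#' One encoding event per display (duration 12 s, parametric modulator =
#' number of its subsequently successfully retrieved features, 0-6), one
#' vividness event per display (8 s, modulator = rating 0-100), one event
#' per successful feature judgment under its feature's regressor (6 s,
#' modulator = trial precision), and one shared `feature_unsuccessful`
#' event type for unsuccessful judgments (no modulator). Modulators are
#' mean-centered within event type (`modulator_centered`). Onsets are laid
#' out sequentially within subject and block with jittered inter-trial
#' intervals.
#'
#' @param classified Trial table after [classify_trials] (needs `success`
#'   and `precision`).
#' @param ratings Vividness table (`subject`, `display`, `vividness`).
#' @param seed Optional seed for the ITI jitter.
#' @return Data frame: `subject`, `block`, `display`, `onset`, `duration`,
#'   `trial_type`, `modulator`, `modulator_centered`.
#' @export
build_event_table <- function(classified, ratings, seed = NULL) {
  if (!all(c("success", "precision") %in% names(classified)))
    stop("trials are not classified; run classify_trials first", call. = FALSE)
  if (any(is.na(classified$success) & !classified$omitted))
    stop("trial lacking classification", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); ri <- 0L
  add <- function(subject, block, display, onset, duration, type, mod) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(subject = subject, block = block,
                              display = display, onset = onset,
                              duration = duration, trial_type = type,
                              modulator = mod)
  }
  for (sj in sort(unique(classified$subject))) {
    t_sj <- classified[classified$subject == sj, ]
    for (b in sort(unique(t_sj$block))) {
      tb <- t_sj[t_sj$block == b, ]
      disp <- sort(unique(tb$display))
      clock <- 0
      for (d in disp) {  # encoding phase
        td <- tb[tb$display == d, ]
        n_succ <- sum(td$success, na.rm = TRUE)
        add(sj, b, d, clock, 12, "encoding", n_succ)
        clock <- clock + 12 + sample_iti(1)
      }
      clock <- clock + 10  # delay before retrieval
      for (d in disp) {  # retrieval phase
        td <- tb[tb$display == d, ]
        viv <- ratings$vividness[ratings$subject == sj &
                                   ratings$display == d]
        add(sj, b, d, clock, 8, "vividness",
            if (length(viv)) viv[1] else NA_real_)
        clock <- clock + 8 + sample_iti(1)
        ord <- order(td$object, td$question_pos)
        for (i in ord) {
          type <- if (isTRUE(td$success[i]))
            paste0("feature_", td$feature[i]) else "feature_unsuccessful"
          mod <- if (isTRUE(td$success[i])) td$precision[i] else NA_real_
          add(sj, b, td$display[i], clock, 6, type, mod)
          clock <- clock + 6 + sample_iti(1)
        }
      }
    }
  }
  ev <- do.call(rbind, rows)
  centered <- ave(ev$modulator, ev$trial_type,
                  FUN = function(v) if (all(is.na(v))) v else v - mean(v, na.rm = TRUE))
  ev$modulator_centered <- centered
  rownames(ev) <- NULL
  ev
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates an experiment, fits and compares the error-mixture models on
#' the pooled errors, derives the posterior success cutoff from the pooled
#' target + uniform fit, classifies trials, fits each subject's mixture,
#' and computes the success/precision/vividness dissociation report.
#' Writes all tables (CSV/TSV) and fitted objects (JSON) to
#' `config$out_dir` when set.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list bundle: `config`, `sim`, `pooled_fit`,
#'   `comparison`, `threshold`, `classified`, `success_rates`,
#'   `summaries`, `report`, and `events` (when exported).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) message(sprintf(
    "[recallmix %6.1fs] %s", proc.time()[["elapsed"]] - t0,
    sprintf(fmt, ...)))
  say("simulate: %d subjects, seed %d", config$n_subjects, config$seed)
  sim <- simulate_experiment(
    design = experiment_design(n_subjects = config$n_subjects),
    population = config$population, target_corr = config$target_corr,
    model_id = config$model_id, seed = config$seed)
  say("simulated %d trials, %d vividness ratings",
      nrow(sim$trials), nrow(sim$ratings))

  pooled <- error_set_from_trials(sim$trials)
  say("fit: pooled M2_VM_UNIF on all errors")
  pooled_fit <- fit_model(pooled, "M2_VM_UNIF", n_starts = config$n_starts,
                          seed = config$seed + 100, mu_mode = config$mu_mode)
  say("pooled fit: p_target = %.3f, kappa = %.2f",
      pooled_fit$p_target, pooled_fit$kappa)
  comparison <- compare_models(pooled, n_starts = config$n_starts,
                               seed = config$seed + 200,
                               mu_mode = config$mu_mode)
  say("model comparison winner: AIC %s, BIC %s",
      comparison$winner_aic, comparison$winner_bic)

  thr <- derive_cutoff(pooled_fit$p_target, pooled_fit$kappa, config$alpha)
  say("success cutoff: %.2f deg (rounded %d)", thr$cutoff_deg,
      thr$cutoff_rounded)
  classified <- classify_trials(sim$trials, thr,
                                use_rounded = config$use_rounded_cutoff)
  rates <- subject_success_rate(classified)
  say("mean success rate: %.1f%%", 100 * attr(rates, "mean"))

  if (config$n_subjects < 8)
    warning("small cohort (n < 8): dissociation statistics will be unstable")
  say("fit: per-subject M2_VM_UNIF")
  summaries <- subject_summaries(sim$trials, sim$ratings,
                                 n_starts = config$n_starts,
                                 seed = config$seed + 300,
                                 mu_mode = config$mu_mode)
  report <- NULL
  if (config$n_subjects >= 4) {
    report <- build_dissociation_report(summaries)
    say("report: success R2 = %.3f", report$regressions$success$r2)
  } else {
    warning("fewer than 4 subjects: dissociation report skipped")
  }

  events <- NULL
  if (config$export_events) {
    events <- build_event_table(classified, sim$ratings,
                                seed = config$seed + 400)
    say("event table: %d rows", nrow(events))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_table(sim$trials, p("trials.csv"))
    write_table(sim$ratings, p("vividness.csv"))
    write_table(classified, p("trials_classified.csv"))
    write_table(rates, p("success_rates.csv"))
    write_table(summaries, p("subject_summaries.csv"))
    write_fit_json(pooled_fit, p("pooled_fit.json"))
    write_fit_json(comparison, p("model_comparison.json"))
    jsonlite::write_json(unclass(thr), p("threshold.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report))
      jsonlite::write_json(report_to_list(report), p("dissociation_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(events)) write_table(events, p("events.tsv"), sep = "\t")
    cfg <- unclass(config)
    jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("outputs written to %s", config$out_dir)
  }
  invisible(list(config = config, sim = sim, pooled_fit = pooled_fit,
                 comparison = comparison, threshold = thr,
                 classified = classified, success_rates = rates,
                 summaries = summaries, report = report, events = events))
}

report_to_list <- function(report) {
  list(n_subjects = report$n_subjects,
       correlations = report$correlations,
       regressions = lapply(report$regressions, function(rg)
         list(r2 = rg$r2, unexplained = rg$unexplained, f = rg$f,
              df = rg$df, p_f = rg$p_f, beta = as.list(rg$beta),
              t = as.list(rg$t), p = as.list(rg$p))))
}
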