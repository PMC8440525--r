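#' Study configuration for a full condition analysis
#'
#' @param schedule An `ssvep_schedule` for the condition.
#' @param n_harmonics Harmonics per analysis (default 4).
#' @param exclude_base_harmonics Whether the deviant harmonic set skips
#'   base multiples (required for alternation designs where every even
#'   deviant harmonic is a base harmonic).
#' @param preproc A [preproc_config()].
#' @param n_components_deviant,n_components_base Components analyzed for
#'   the deviant (2) and base (1) analyses.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @param rank_k Optional RCA rank override.
#' @return A list of class `ssvep_study_config`.
#' @export
study_config <- function(schedule, n_harmonics = 4L,
                         exclude_base_harmonics =
                           schedule$items_per_deviant == 2L,
                         preproc = preproc_config(),
                         n_components_deviant = 2L,
                         n_components_base = 1L,
                         alpha = 0.05, rank_k = NULL) {
  stopifnot(inherits(schedule, "ssvep_schedule"))
  structure(as.list(environment()), class = "ssvep_study_config")
}

preprocess_condition <- function(recordings, cfg) {
  lapply(recordings, preprocess, cfg = cfg$preproc)
}

condition_coefficients <- function(epochs_list, freqs) {
  lapply(epochs_list, spectral_coefficients, freqs = freqs)
}

# run one RCA analysis (base or deviant) on a list of per-recording
# coefficient objects; returns model + group stats
analyze_harmonic_set <- function(coeffs_list, harmonics, n_components,
                                 alpha, rank_k, family_size) {
  trials <- build_feature_trials(coeffs_list)
  model <- train_rca(trials, n_components = n_components, rank_k = rank_k)
  model <- align_signs(model, trials)
  projected <- project(trials, model)
  group <- group_component_response(projected)
  n_h <- length(group$freqs)
  tests <- expand.grid(component = seq_len(n_components),
                       harmonic = group$freqs)
  tests$statistic <- NA_real_; tests$p <- NA_real_
  for (r in seq_len(nrow(tests))) {
    hi <- match(tests$harmonic[r], group$freqs)
    t2 <- hotelling_t2_zero(group$means[, tests$component[r], hi])
    tests$statistic[r] <- t2$statistic
    tests$p[r] <- t2$p
  }
  tests$p_fdr <- fdr_adjust(tests$p, m = family_size)
  tests$significant <- tests$p_fdr <= alpha
  list(model = model, trials = trials, projected = projected, group = group,
       tests = tests, harmonics = harmonics)
}

latency_per_component <- function(analysis, n_components) {
  lapply(seq_len(n_components), function(cc) {
    sig <- vapply(analysis$group$freqs, function(f) {
      row <- analysis$tests$component == cc & analysis$tests$harmonic == f
      any(analysis$tests$significant[row])
    }, TRUE)
    estimate_component_latency(analysis$group, cc, sig)
  })
}

# circular RC1-vs-RC2 phase comparison at harmonics significant in both,
# FDR over that family; latency differences in ms (positive = RC2 later)
compare_rc_phases <- function(analysis, alpha) {
  tests <- analysis$tests
  freqs <- analysis$group$freqs
  both_sig <- vapply(freqs, function(f) {
    all(vapply(1:2, function(cc) {
      any(tests$significant[tests$component == cc & tests$harmonic == f])
    }, TRUE))
  }, TRUE)
  sel <- which(both_sig)
  if (!length(sel) || max(analysis$model$n_components, 0) < 2) {
    return(data.frame(harmonic = numeric(0), mean_diff_rad = numeric(0),
                      latency_diff_ms = numeric(0), p = numeric(0),
                      p_fdr = numeric(0), significant = logical(0)))
  }
  out <- data.frame(harmonic = freqs[sel], mean_diff_rad = NA_real_,
                    latency_diff_ms = NA_real_, p = NA_real_)
  for (i in seq_along(sel)) {
    hi <- sel[i]
    ph1 <- wrap_pi(Arg(analysis$group$means[, 1, hi]))
    ph2 <- wrap_pi(Arg(analysis$group$means[, 2, hi]))
    ct <- circular_phase_test(ph1, ph2)
    out$mean_diff_rad[i] <- ct$mean_diff
    # delay lowers phase: a later RC2 has d = ph2 - ph1 < 0
    out$latency_diff_ms[i] <- phase_diff_to_latency(-ct$mean_diff,
                                                    freqs[hi])
    out$p[i] <- ct$p
  }
  out$p_fdr <- fdr_adjust(out$p, m = nrow(out))
  out$significant <- out$p_fdr <= alpha
  out
}

#' Run the full analysis for one condition
#'
#' Executes, in order: preprocessing, spectral coefficient extraction,
#' base-harmonic RCA (1 component, FDR family = harmonics), deviant
#' harmonic RCA (2 components, FDR family = harmonics x components),
#' projection, per-subject averaging, Hotelling T2 with FDR, latency
#' estimation for the deviant components, and circular RC1-versus-RC2
#' phase comparison at harmonics significant in both components.
#'
#' @param recordings List of `ssvep_recording` (one condition).
#' @param config An [study_config()].
#' @return A list of class `ssvep_condition_result`: `base`, `deviant`
#'   (each with model, tests, group), `latency` (list per deviant
#'   component), `phase_comparison`, `provenance`.
#' @export
run_condition <- function(recordings, config) {
  stopifnot(inherits(config, "ssvep_study_config"), length(recordings) >= 1)
  sched <- config$schedule
  epochs_list <- preprocess_condition(recordings, config)
  base_h <- enumerate_harmonics(sched$base_hz, sched$base_hz,
                                config$n_harmonics)
  dev_h <- enumerate_harmonics(sched$deviant_hz, sched$base_hz,
                               config$n_harmonics,
                               exclude_base = config$exclude_base_harmonics)
  base_co <- condition_coefficients(epochs_list, base_h)
  dev_co <- condition_coefficients(epochs_list, dev_h)
  base <- analyze_harmonic_set(
    base_co, base_h, config$n_components_base, config$alpha, config$rank_k,
    family_size = config$n_harmonics * config$n_components_base)
  deviant <- analyze_harmonic_set(
    dev_co, dev_h, config$n_components_deviant, config$alpha, config$rank_k,
    family_size = config$n_harmonics * config$n_components_deviant)
  latency <- latency_per_component(deviant, config$n_components_deviant)
  phase_cmp <- compare_rc_phases(deviant, config$alpha)
  prov <- list(
    n_recordings = length(recordings),
    n_rejected_pairs = sum(vapply(epochs_list, function(e)
      e$provenance$n_rejected_pairs, 1)),
    n_repaired = sum(vapply(epochs_list, function(e)
      length(e$provenance$repaired %||% integer(0)), 1)),
    condition_id = recordings[[1]]$condition_id)
  structure(list(base = base, deviant = deviant, latency = latency,
                 phase_comparison = phase_cmp, provenance = prov,
                 config = config),
            class = "ssvep_condition_result")
}

#' Joint-condition analysis in a shared component space
#'
#' Trains one RCA model on the pooled deviant-harmonic trials of several
#' conditions, then projects each condition through the shared filters so
#' amplitudes, phases and latencies are directly comparable.
#'
#' @param recordings_by_condition Named list: condition id -> list of
#'   `ssvep_recording`.
#' @param config An [study_config()] (schedules must share the feature
#'   layout: same number of harmonics).
#' @return A list of class `ssvep_joint_result`: `model`, and per
#'   condition `group`, `tests`, `latency`.
#' @export
run_joint <- function(recordings_by_condition, config) {
  stopifnot(length(recordings_by_condition) >= 2)
  sched <- config$schedule
  dev_h <- enumerate_harmonics(sched$deviant_hz, sched$base_hz,
                               config$n_harmonics,
                               exclude_base = config$exclude_base_harmonics)
  trials_by_cond <- lapply(recordings_by_condition, function(recs) {
    epochs_list <- preprocess_condition(recs, config)
    build_feature_trials(condition_coefficients(epochs_list, dev_h))
  })
  model <- train_joint(trials_by_cond,
                       n_components = config$n_components_deviant,
                       rank_k = config$rank_k)
  model <- align_signs(model, trials_by_cond[[1]])
  per_cond <- lapply(trials_by_cond, function(trials) {
    projected <- project(trials, model)
    group <- group_component_response(projected)
    tests <- expand.grid(component = seq_len(config$n_components_deviant),
                         harmonic = group$freqs)
    tests$statistic <- NA_real_; tests$p <- NA_real_
    for (r in seq_len(nrow(tests))) {
      hi <- match(tests$harmonic[r], group$freqs)
      t2 <- hotelling_t2_zero(group$means[, tests$component[r], hi])
      tests$statistic[r] <- t2$statistic
      tests$p[r] <- t2$p
    }
    tests$p_fdr <- fdr_adjust(
      tests$p, m = config$n_harmonics * config$n_components_deviant)
    tests$significant <- tests$p_fdr <= config$alpha
    analysis <- list(group = group, tests = tests, model = model)
    latency <- lapply(seq_len(config$n_components_deviant), function(cc) {
      sig <- vapply(group$freqs, function(f) {
        any(tests$significant[tests$component == cc & tests$harmonic == f])
      }, TRUE)
      estimate_component_latency(group, cc, sig)
    })
    list(group = group, tests = tests, latency = latency)
  })
  structure(list(model = model, conditions = per_cond, harmonics = dev_h),
            class = "ssvep_joint_result")
}

#' Write a machine-readable report for a condition analysis
#'
#' Emits `tests.csv` (all T2 results), `latency.csv`, `topographies.csv`
#' (forward models for base and deviant analyses),
#' `phase_comparison.csv`, and `provenance.json`. Re-running with the same
#' inputs yields byte-identical tables.
#'
#' @param result An `ssvep_condition_result`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the provenance block.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir, seed = NA) {
  stopifnot(inherits(result, "ssvep_condition_result"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  tests <- rbind(cbind(analysis = "base", result$base$tests),
                 cbind(analysis = "deviant", result$deviant$tests))
  p <- file.path(dir, "tests.csv")
  utils::write.csv(tests, p, row.names = FALSE); paths <- c(paths, p)
  lat <- do.call(rbind, lapply(seq_along(result$latency), function(cc) {
    l <- result$latency[[cc]]
    data.frame(component = cc, tau_ms = l$tau_ms, se_ms = l$se_ms,
               harmonics_used = paste(l$harmonics_used, collapse = ";"),
               estimable = l$estimable)
  }))
  p <- file.path(dir, "latency.csv")
  utils::write.csv(lat, p, row.names = FALSE); paths <- c(paths, p)
  topo_long <- function(analysis, A) {
    do.call(rbind, lapply(seq_len(ncol(A)), function(cc)
      data.frame(analysis = analysis, component = cc,
                 sensor = seq_len(nrow(A)), weight = A[, cc])))
  }
  topo <- rbind(topo_long("base", result$base$model$A),
                topo_long("deviant", result$deviant$model$A))
  p <- file.path(dir, "topographies.csv")
  utils::write.csv(topo, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "phase_comparison.csv")
  utils::write.csv(result$phase_comparison, p, row.names = FALSE)
  paths <- c(paths, p)
  prov <- c(result$provenance,
            list(seed = seed,
                 reliability_deviant = result$deviant$model$reliability,
                 reliability_base = result$base$model$reliability))
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
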