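#' Default pipeline configuration
#'
#' @param n_subjects Cohort size for simulation commands.
#' @param variant Generating model variant.
#' @param models Model variants to fit / compare.
#' @param preset Task preset.
#' @param seed Master seed; every random stage derives its seed from
#'   it.
#' @param out_dir Output directory for artifacts.
#' @param symptom_slope Planted symptom association (see
#'   [cohort_spec()]).
#' @param fit Fitting settings: `tol`, `max_iter`, `n_starts`.
#' @param bms BMS settings: `alpha0`, `n_samples`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 15,
                            variant = "value_2w",
                            models = c("perceptual", "value_1w", "value_2w"),
                            preset = "fmri",
                            seed = 1L,
                            out_dir = tempfile("avoidgen-run-"),
                            symptom_slope = 0,
                            fit = list(tol = 0.01, max_iter = 32,
                                       n_starts = 8),
                            bms = list(alpha0 = 1, n_samples = 1e6)) {
  structure(list(n_subjects = n_subjects, variant = variant,
                 models = models, preset = preset, seed = as.integer(seed),
                 out_dir = out_dir, symptom_slope = symptom_slope,
                 fit = fit, bms = bms),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys raise a validation error naming them.
#'
#' @param path Path to a JSON file of configuration overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run a pipeline command
#'
#' Thin orchestration over the package's functions, writing tabular
#' artifacts as CSV and structured results as JSON into
#' `config$out_dir` along with a manifest (seed, package version,
#' settings).
#'
#' Commands: `"simulate"` (synthetic study CSVs), `"fit"` (per-model
#' group-fit JSON + latent-trace CSV), `"compare"` (BMS JSON from the
#' fit artifacts), `"recover"` (simulate + fit + compare + recovery
#' report), `"stats"` (behavioural summaries, QC report, regression
#' table), `"rsa"` (planted-pattern distance table).
#'
#' @param command One of simulate, fit, compare, recover, stats, rsa.
#' @param config A [pipeline_config()] (or path to a JSON config).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "compare",
                                     "recover", "stats", "rsa"),
                         config = pipeline_config()) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(command,
         simulate = pipe_simulate(config),
         fit = pipe_fit(config),
         compare = pipe_compare(config),
         recover = pipe_recover(config),
         stats = pipe_stats(config),
         rsa = pipe_rsa(config))
  manifest <- list(command = command,
                   seed = config$seed,
                   package = "avoidgen",
                   version = as.character(utils::packageVersion("avoidgen")),
                   config = unclass(config)[setdiff(names(config), "out_dir")],
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

pipe_study <- function(config) {
  generate_study(cohort_spec(config$n_subjects, config$variant,
                             symptom_slope = config$symptom_slope,
                             preset = config$preset,
                             master_seed = config$seed))
}

pipe_simulate <- function(config) {
  study <- pipe_study(config)
  trials <- dplyr::bind_rows(study$sessions)
  utils::write.csv(trials[, c("subject_id", "block", "trial", "stimulus",
                              "role", "rho", "scheduled_outcome", "avoided",
                              "outcome")],
                   file.path(config$out_dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$params, file.path(config$out_dir, "params_true.csv"),
                   row.names = FALSE)
  utils::write.csv(study$subjects, file.path(config$out_dir, "subjects.csv"),
                   row.names = FALSE)
  design <- study$design
  jsonlite::write_json(
    list(theta = design$theta,
         reinforcement_rate = design$reinforcement_rate,
         avoid_cost = design$avoid_cost, n_blocks = design$n_blocks,
         stimuli = design$stimuli),
    file.path(config$out_dir, "design.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(study)
}

#' Read sessions written by the simulate command
#'
#' @param path Path to a `sessions.csv` artifact.
#' @return A named list of per-subject session tibbles.
#' @export
read_sessions_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("Missing input: ", path))
  trials <- tibble::as_tibble(utils::read.csv(path))
  split(trials, trials$subject_id)
}

pipe_fit <- function(config) {
  study <- pipe_simulate(config)
  design <- study$design
  for (m in config$models) {
    gf <- fit_population(study$sessions, model_spec(m), design,
                         tol = config$fit$tol,
                         max_iter = config$fit$max_iter,
                         n_starts = config$fit$n_starts,
                         seed = config$seed)
    write_group_fit(gf, study,
                    file.path(config$out_dir, paste0("groupfit_", m, ".json")))
    traces <- purrr::imap_dfr(study$sessions, function(sess, s) {
      tr <- rl_loglik(gf$posteriors[[s]]$params, gf$spec, sess, design,
                      trace = TRUE)$trace
      tr$subject_id <- sess$subject_id[1]
      tr
    })
    utils::write.csv(traces[, c("subject_id", "trial", "p_shock", "pe",
                                "alpha")],
                     file.path(config$out_dir, paste0("trace_", m, ".csv")),
                     row.names = FALSE)
  }
  invisible(study)
}

write_group_fit <- function(gf, study, path) {
  design <- study$design
  subj <- lapply(seq_along(gf$posteriors), function(s) {
    p <- gf$posteriors[[s]]
    list(subject_id = study$sessions[[s]]$subject_id[1],
         estimates = as.list(tidy_params(p)),
         posterior_variances = as.list(p$param_vars),
         free_energy = p$free_energy,
         initial_free_energy = gf$initial_free_energy[s],
         predictive_accuracy = predictive_accuracy(p, study$sessions[[s]],
                                                   gf$spec, design),
         bayes_p_random = bayes_p_random(p))
  })
  jsonlite::write_json(
    list(variant = gf$spec$variant,
         prior = gf$prior,
         iteration_log = gf$f_log,
         converged = gf$converged,
         subjects = subj),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

tidy_params <- function(posterior) {
  nm <- names(posterior$latent_mean)
  setNames(lapply(nm, function(p) posterior$params[[p]]), nm)
}

pipe_compare <- function(config) {
  paths <- file.path(config$out_dir,
                     paste0("groupfit_", config$models, ".json"))
  if (!all(file.exists(paths))) pipe_fit(config)
  lev <- sapply(config$models, function(m) {
    gf <- jsonlite::read_json(file.path(config$out_dir,
                                        paste0("groupfit_", m, ".json")),
                              simplifyVector = FALSE)
    vapply(gf$subjects, `[[`, numeric(1), "initial_free_energy")
  })
  res <- rfx_bms(lev, alpha0 = config$bms$alpha0,
                 n_samples = config$bms$n_samples, seed = config$seed)
  jsonlite::write_json(
    list(models = names(res$dirichlet_alpha),
         dirichlet_alpha = unname(res$dirichlet_alpha),
         expected_frequencies = unname(res$expected_frequencies),
         exceedance_probabilities = unname(res$exceedance_probabilities),
         n_mc_samples = res$n_mc_samples, seed = res$seed),
    file.path(config$out_dir, "bms.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res
}

pipe_recover <- function(config) {
  study <- pipe_fit(config)
  res <- pipe_compare(config)
  gf <- jsonlite::read_json(
    file.path(config$out_dir, paste0("groupfit_", config$variant, ".json")),
    simplifyVector = FALSE)
  report <- list(generating_variant = config$variant,
                 bms_best = names(res$exceedance_probabilities)[
                   which.max(res$exceedance_probabilities)],
                 exceedance_probabilities =
                   as.list(res$exceedance_probabilities))
  for (p in names(study$params)[-1]) {
    if (!startsWith(p, "latent_") && p != "subject") {
      est <- vapply(gf$subjects, function(s)
        s$estimates[[p]] %||% NA_real_, numeric(1))
      if (!anyNA(est)) {
        report[[paste0("spearman_", p)]] <-
          cor(study$params[[p]], est, method = "spearman")
      }
    }
  }
  jsonlite::write_json(report, file.path(config$out_dir, "recovery.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

pipe_stats <- function(config) {
  study <- pipe_study(config)
  design <- study$design
  summaries <- purrr::imap_dfr(study$sessions, function(sess, s) {
    sm <- avoidance_summary(sess, design)
    out <- sm$by_role
    out$subject_id <- sess$subject_id[1]
    out$peak_shift <- peak_shift_index(sm, design)
    out
  })
  utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)
  qc <- qc_filter(dplyr::bind_rows(study$sessions))
  utils::write.csv(qc$excluded, file.path(config$out_dir, "qc_excluded.csv"),
                   row.names = FALSE)
  subj <- study$subjects
  subj$z_sigma_a <- as.numeric(scale(subj$log_sigma_a_est))
  fit <- precision_weighted_regression(
    subj, z_sigma_a ~ symptom + age_z + gender, "sigma_a_precision")
  utils::write.csv(tidy(fit), file.path(config$out_dir, "regression.csv"),
                   row.names = FALSE)
  invisible(list(summaries = summaries, qc = qc, regression = fit))
}

pipe_rsa <- function(config) {
  # planted-convergence demonstration dataset: GS moves toward CS+ late
  p <- 40
  base <- withr_seed(config$seed, {
    matrix(rnorm(3 * p), 3, p,
           dimnames = list(c("CS_PLUS", "GS", "CS_MINUS"), NULL))
  })
  early <- base
  late <- base
  late["GS", ] <- (base["GS", ] + base["CS_PLUS", ]) / 2
  ds <- generate_patterns(list(early = early, late = late),
                          noise_sd = 0.5, seed = config$seed + 1L)
  ds <- noise_normalize(ds)
  pairs <- utils::combn(rownames(base), 2, simplify = FALSE)
  tab <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(cond_a = pr[1], cond_b = pr[2],
                   cv_ldc = cv_ldc(ds, pr)$value,
                   change = distance_change(ds, pr))
  })
  utils::write.csv(tab, file.path(config$out_dir, "rsa_distances.csv"),
                   row.names = FALSE)
  invisible(tab)
}
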