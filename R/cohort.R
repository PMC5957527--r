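#' Specify a synthetic cohort
#'
#' Describes a population of avoidance-learning agents for simulation
#' and recovery studies: the generating model variant, the group
#' distribution of its free parameters (Gaussian on the latent scale),
#' an optional planted association between the aversive generalization
#' width and a symptom score, and the task preset.
#'
#' Default group means (on the natural scale) are kappa 0.5, eta 0.3,
#' beta 5, bias 0.4 and — for the two-width variant — sigma_a 0.75,
#' sigma_n 0.03, echoing typical group estimates for this task; the
#' one-width variant defaults to sigma 0.3. Default dispersions follow
#' the group SDs reported for this task where available (sigma_a
#' +/- 0.29, sigma_n +/- 0.03, bias +/- 0.14; log-normal SDs are
#' moment-matched on the natural scale), with latent SD 0.5 for kappa
#' and eta and 0.25 for log-beta where no dispersion is printed.
#'
#' @param n_subjects Cohort size.
#' @param variant Generating model variant (see [model_spec()]).
#' @param group_means Named natural-scale parameter means (overrides
#'   the defaults above).
#' @param group_sds Named latent-scale SDs (defaults: 0.5 for kappa,
#'   eta and log-widths, 0.25 for log-beta, 0.15 for bias).
#' @param symptom_slope Standardised slope linking z(log sigma_a) to
#'   the symptom score (default 0: no association).
#' @param symptom_noise_sd Residual SD of the symptom score; `NULL`
#'   (default) sets `sqrt(1 - slope^2)` so the score itself has unit
#'   variance.
#' @param preset Task preset, `"fmri"` or `"amt"` (see
#'   [design_preset()]).
#' @param master_seed Single seed from which every subject-level seed
#'   is derived.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        variant = c("value_2w", "value_1w", "perceptual"),
                        group_means = NULL, group_sds = NULL,
                        symptom_slope = 0, symptom_noise_sd = NULL,
                        preset = c("fmri", "amt"),
                        master_seed = 1L) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  spec <- model_spec(variant)
  nm <- spec$free_parameter_names

  mean_default <- c(kappa = 0.5, eta = 0.3, beta = 5, bias = 0.4,
                    sigma = 0.3, sigma_a = 0.75, sigma_n = 0.03)
  # log-normal latent SDs moment-matched to natural-scale group SDs:
  # s = sqrt(log(1 + (sd/mean)^2))
  sd_default <- c(kappa = 0.5, eta = 0.5, beta = 0.25, bias = 0.14,
                  sigma = 0.5,
                  sigma_a = sqrt(log(1 + (0.29 / 0.752)^2)),
                  sigma_n = sqrt(log(1 + (0.03 / 0.028)^2)))
  means <- mean_default
  means[names(group_means)] <- group_means
  sds <- sd_default
  sds[names(group_sds)] <- group_sds
  if (any(sds[nm] <= 0)) abort("Group SDs must be positive.")

  latent_means <- vapply(nm, function(p) {
    switch(param_transform(p),
           logistic = qlogis(means[[p]]),
           log = log(means[[p]]),
           identity = means[[p]])
  }, numeric(1))

  structure(list(
    n_subjects = as.integer(n_subjects),
    variant = variant,
    model_spec = spec,
    latent_means = latent_means,
    latent_sds = sds[nm],
    symptom_slope = symptom_slope,
    symptom_noise_sd = symptom_noise_sd %||%
      sqrt(max(0, 1 - symptom_slope^2)),
    preset = preset,
    master_seed = as.integer(master_seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects | variant:", x$variant,
      "| preset:", x$preset, "\n")
  print(tibble::tibble(parameter = names(x$latent_means),
                       latent_mean = unname(x$latent_means),
                       latent_sd = unname(x$latent_sds)))
  invisible(x)
}

#' Draw per-subject parameters for a cohort
#'
#' Latent parameters are sampled from the group Gaussians and mapped
#' through the fitting transforms, so the generating process matches
#' the assumptions of the hierarchical fit.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `subject`, one natural-scale column per
#'   parameter, and matching `latent_*` columns.
#' @export
sample_cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- names(spec$latent_means)
  withr_seed(spec$master_seed, {
    lat <- sapply(nm, function(p)
      rnorm(spec$n_subjects, spec$latent_means[[p]], spec$latent_sds[[p]]))
    lat <- matrix(lat, nrow = spec$n_subjects,
                  dimnames = list(NULL, nm))
    nat <- sapply(nm, function(p) {
      switch(param_transform(p),
             logistic = plogis(lat[, p]),
             log = exp(lat[, p]),
             identity = lat[, p])
    })
    nat <- matrix(nat, nrow = spec$n_subjects,
                  dimnames = list(NULL, nm))
    out <- tibble::as_tibble(nat)
    out$subject <- seq_len(spec$n_subjects)
    latents <- tibble::as_tibble(lat)
    names(latents) <- paste0("latent_", nm)
    dplyr::bind_cols(out[, c("subject", nm)], latents)
  })
}

# deterministic per-subject sub-seed below 2^31
derive_seed <- function(master_seed, subject, stream = 0L) {
  (master_seed * 1009L + subject * 7919L + stream * 104729L) %% 2000000011L
}

#' Generate a full synthetic study
#'
#' Emulates the behavioural arm of the study end to end: per subject a
#' pseudorandom trial sequence (task preset), a simulated behavioural
#' session from that subject's generating parameters, same/different
#' discrimination data from a per-subject psychometric observer, and a
#' subject table carrying a symptom score with the planted association
#' to the aversive generalization width plus heteroscedastic parameter
#' "estimates" with their precisions for the precision-weighted
#' regression stage.
#'
#' @param spec A [cohort_spec()].
#' @param sessions Simulate behavioural sessions? Disable for large
#'   cohorts when only the subject-level table (parameters, symptom
#'   scores, precisions) is needed.
#' @param discrimination Simulate perceptual discrimination data?
#' @return A `synthetic_study`: `params` (true parameters),
#'   `sessions` (list of session tibbles), `discrimination` (list of
#'   level tibbles), `subjects` (subject-level table), `design`,
#'   `model_spec`, `cohort_spec`.
#' @export
generate_study <- function(spec, sessions = TRUE, discrimination = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  design <- design_preset(spec$preset)
  params <- sample_cohort_params(spec)
  nm <- names(spec$latent_means)
  mspec <- spec$model_spec

  session_list <- if (sessions) vector("list", spec$n_subjects)
  discrim_list <- if (discrimination) vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    if (sessions) {
      sq <- generate_sequence(design,
                              seed = derive_seed(spec$master_seed, s, 1L))
      ap <- do.call(agent_params, as.list(params[s, nm]))
      session_list[[s]] <- simulate_agent(
        ap, mspec, sq, design,
        seed = derive_seed(spec$master_seed, s, 2L))$session
      session_list[[s]]$subject_id <- sprintf("S%03d", s)
    }
    if (discrimination) {
      # per-subject psychometric observer around the task's calibration
      ps <- withr_seed(derive_seed(spec$master_seed, s, 3L), {
        c(alpha = rnorm(1, 0.05, 0.01),
          beta = exp(rnorm(1, log(0.02), 0.2)),
          lapse = runif(1, 0, 0.04))
      })
      discrim_list[[s]] <- simulate_discrimination(
        ps[["alpha"]], ps[["beta"]], ps[["lapse"]],
        seed = derive_seed(spec$master_seed, s, 4L))
    }
  }

  subjects <- withr_seed(derive_seed(spec$master_seed, 0L, 5L), {
    n <- spec$n_subjects
    has_sigma <- "sigma_a" %in% nm
    z_true <- if (has_sigma) {
      as.numeric(scale(params$latent_sigma_a))
    } else rep(0, n)
    est_sd <- runif(n, 0.1, 0.3)
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      symptom = spec$symptom_slope * z_true +
        rnorm(n, 0, spec$symptom_noise_sd),
      log_sigma_a_true = if (has_sigma) params$latent_sigma_a else NA_real_,
      log_sigma_a_est = if (has_sigma)
        params$latent_sigma_a + rnorm(n, 0, est_sd) else NA_real_,
      sigma_a_precision = 1 / est_sd^2,
      age_z = rnorm(n),
      gender = rbinom(n, 1, 0.5)
    )
  })

  structure(list(params = params, sessions = session_list,
                 discrimination = discrim_list, subjects = subjects,
                 design = design, model_spec = mspec, cohort_spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", x$cohort_spec$n_subjects, "subjects |",
      x$cohort_spec$variant, "|", x$cohort_spec$preset, "preset\n")
  invisible(x)
}

#' Generate a synthetic multivariate pattern dataset
#'
#' Gaussian noise around per-condition mean patterns, optionally
#' switching between an early and a late mean (runs 1-2 vs the rest)
#' to plant a known representational distance change. Residual rows
#' for noise normalisation are drawn from the same noise distribution.
#'
#' @param means Condition x voxel matrix of mean patterns (with row
#'   names), or a list `list(early = , late = )` of two such matrices.
#' @param n_runs Number of runs (default 5).
#' @param noise_sd Voxelwise noise SD of the pattern estimates.
#' @param n_resid Residual samples per run (default 200).
#' @param seed Integer seed.
#' @return A [pattern_dataset()].
#' @export
generate_patterns <- function(means, n_runs = 5, noise_sd = 1,
                              n_resid = 200, seed = 1L) {
  if (!is.list(means)) means <- list(early = means, late = means)
  stopifnot(all(c("early", "late") %in% names(means)))
  p <- ncol(means$early)
  nc <- nrow(means$early)
  withr_seed(seed, {
    est <- lapply(seq_len(n_runs), function(r) {
      m <- if (r <= 2) means$early else means$late
      m + matrix(rnorm(nc * p, 0, noise_sd), nc, p)
    })
    res <- lapply(seq_len(n_runs), function(r)
      matrix(rnorm(n_resid * p, 0, noise_sd), n_resid, p))
    pattern_dataset(est, residuals = res)
  })
}
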