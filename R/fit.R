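#' Latent-scale transforms for free parameters
#'
#' Model fitting works on an unconstrained latent scale: unit-interval
#' parameters (`kappa`, `eta`) through the logistic, positive
#' parameters (`beta`, generalization widths) through the exponential,
#' and the decision bias untransformed. `transform_params()` maps a
#' latent vector to [agent_params()]; `inverse_transform_params()` is
#' its inverse and rejects boundary values.
#'
#' @param latent Numeric vector, ordered as
#'   `spec$free_parameter_names`.
#' @param spec [model_spec()].
#' @param alpha0 Initial associability to attach (not a free
#'   parameter).
#' @return An `agent_params` object.
#' @export
transform_params <- function(latent, spec, alpha0 = 1) {
  nm <- spec$free_parameter_names
  if (length(latent) != length(nm)) {
    abort(paste0("Latent vector must have length ", length(nm),
                 " for variant `", spec$variant, "`."))
  }
  names(latent) <- nm
  val <- lapply(nm, function(p) {
    switch(param_transform(p),
           # clamped so extreme latents cannot saturate to exactly 0 or 1
           logistic = min(max(plogis(latent[[p]]), 1e-10), 1 - 1e-10),
           log = exp(latent[[p]]),
           identity = latent[[p]])
  })
  names(val) <- nm
  agent_params(kappa = val$kappa, eta = val$eta, beta = val$beta,
               bias = val$bias, sigma = val$sigma,
               sigma_a = val$sigma_a, sigma_n = val$sigma_n,
               alpha0 = alpha0)
}

#' @rdname transform_params
#' @param params An [agent_params()] object.
#' @export
inverse_transform_params <- function(params, spec) {
  vapply(spec$free_parameter_names, function(p) {
    x <- params[[p]]
    tr <- param_transform(p)
    if (tr == "logistic" && (x <= 0 || x >= 1)) {
      abort(paste0("`", p, "` = ", x, " is on the boundary of (0, 1)."))
    }
    if (tr == "log" && x <= 0) {
      abort(paste0("`", p, "` = ", x, " must be positive."))
    }
    switch(tr, logistic = qlogis(x), log = log(x), identity = x)
  }, numeric(1))
}

param_transform <- function(name) {
  switch(name,
         kappa = , eta = "logistic",
         beta = , sigma = , sigma_a = , sigma_n = "log",
         bias = "identity",
         abort(paste0("Unknown parameter `", name, "`.")))
}

#' Group-level prior over latent parameters
#'
#' Independent Gaussian priors on the latent (transformed) scale; the
#' default (mean 0, variance 3) is weakly informative: it centres
#' `kappa`/`eta` at 0.5, `beta` and the generalization widths at 1,
#' and the bias at 0.
#'
#' @param spec [model_spec()].
#' @param mean Prior mean(s), recycled over parameters.
#' @param var Prior variance(s), recycled; must be positive.
#' @return A `prior_spec` tibble with `parameter`, `transform`,
#'   `mean`, `var`.
#' @export
prior_spec <- function(spec, mean = 0, var = 3) {
  if (any(var <= 0)) abort("Prior variances must be positive.")
  nm <- spec$free_parameter_names
  out <- tibble::tibble(
    parameter = nm,
    transform = vapply(nm, param_transform, character(1),
                       USE.NAMES = FALSE),
    mean = rep_len(mean, length(nm)),
    var = rep_len(var, length(nm))
  )
  class(out) <- c("prior_spec", class(out))
  out
}

# central-difference Hessian, step h in each latent coordinate
numeric_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      if (i == j) {
        ei <- replace(numeric(d), i, h)
        H[i, i] <- (f(x + ei) - 2 * f(x) + f(x - ei)) / h^2
      } else {
        ei <- replace(numeric(d), i, h)
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) -
             f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Fit one subject by MAP with a Laplace evidence approximation
#'
#' Maximises the log posterior of the latent parameters under the
#' Gaussian prior with multistart BFGS, then approximates the log model
#' evidence by the Laplace free energy
#' `F = log p(y|theta*) + log p(theta*) - 1/2 log|H| + (d/2) log 2pi`,
#' where `H` is the central-difference Hessian of the negative log
#' posterior at the optimum. A non-positive-definite Hessian is
#' ridge-regularised and flagged.
#'
#' @param session A behavioural session tibble (with `avoided`,
#'   `outcome`).
#' @param spec [model_spec()].
#' @param design [build_design()].
#' @param prior [prior_spec()].
#' @param n_starts Number of optimisation starts (default 8, seeded).
#' @param seed Seed for the random starts.
#' @param warm_start Optional latent vector used as an extra start.
#' @return A `subject_posterior`: `latent_mean`, `latent_cov`,
#'   `free_energy`, `logLik`, `params` (posterior-mean parameters),
#'   `param_vars` (latent-scale posterior variances, whose reciprocals
#'   are the precision weights), `ridged` flag.
#' @export
fit_subject <- function(session, spec, design, prior = prior_spec(spec),
                        n_starts = 8, seed = 1L, warm_start = NULL) {
  if (nrow(session) < 1) abort("Session must contain at least one trial.")
  d <- length(spec$free_parameter_names)
  pm <- prior$mean
  pv <- prior$var

  nlp <- function(latent) {
    if (any(!is.finite(latent)) || any(abs(latent) > 50)) return(1e10)
    params <- transform_params(latent, spec)
    ll <- rl_loglik(params, spec, session, design)$logLik
    v <- -(ll + sum(dnorm(latent, pm, sqrt(pv), log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }

  starts <- withr_seed(seed, {
    s <- matrix(rnorm((n_starts - 1) * d, rep(pm, each = n_starts - 1),
                      rep(sqrt(pv), each = n_starts - 1)),
                nrow = n_starts - 1)
    rbind(pm, s)
  })
  if (!is.null(warm_start)) starts <- rbind(warm_start, starts)

  fits <- apply(starts, 1, function(s) {
    tryCatch(optim(s, nlp, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) abort("MAP optimisation failed from all starts.")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par

  H <- numeric_hessian(nlp, theta, h = 1e-4)
  ee <- eigen(H, symmetric = TRUE)
  # under a concave log-likelihood the posterior precision dominates the
  # prior precision in every direction; flat or saddle directions of the
  # numerical Hessian are floored at the weakest prior precision
  floor_ev <- 1 / max(pv)
  ridged <- min(ee$values) < floor_ev
  ev <- pmax(ee$values, floor_ev)
  cov <- ee$vectors %*% (t(ee$vectors) / ev)
  params <- transform_params(theta, spec)
  ll <- rl_loglik(params, spec, session, design)$logLik
  logprior <- sum(dnorm(theta, pm, sqrt(pv), log = TRUE))
  fe <- ll + logprior - 0.5 * sum(log(ev)) + d / 2 * log(2 * pi)

  structure(list(
    latent_mean = setNames(theta, spec$free_parameter_names),
    latent_cov = cov,
    free_energy = fe,
    logLik = ll,
    params = params,
    param_vars = setNames(diag(cov), spec$free_parameter_names),
    ridged = ridged,
    n_trials = nrow(session),
    spec = spec
  ), class = "subject_posterior")
}

#' @export
print.subject_posterior <- function(x, ...) {
  cat("<subject_posterior> F =", signif(x$free_energy, 6),
      " logLik =", signif(x$logLik, 6),
      if (x$ridged) " [ridged Hessian]" else "", "\n")
  est <- vapply(names(x$latent_mean), function(p) x$params[[p]], numeric(1))
  print(tibble::tibble(parameter = names(x$latent_mean),
                       estimate = est,
                       latent_mean = unname(x$latent_mean),
                       latent_var = unname(x$param_vars)))
  invisible(x)
}

#' Hierarchical (empirical-Bayes) population fit
#'
#' Alternates (i) subject-level MAP/Laplace fits under the current
#' group prior with (ii) moment-matching updates of the prior to the
#' empirical mean and variance of the subject posteriors (adding the
#' mean posterior variance, so shrinkage reflects estimation
#' uncertainty), until the summed free energy changes by less than
#' `tol` or `max_iter` is reached. After the first sweep subjects are
#' warm-started from their previous optimum with a reduced number of
#' fresh starts.
#'
#' @param sessions A list of session tibbles (>= 2 subjects).
#' @param spec [model_spec()].
#' @param design [build_design()].
#' @param init_prior Initial [prior_spec()].
#' @param tol Convergence tolerance on the summed free energy.
#' @param max_iter Maximum refinement iterations.
#' @param n_starts Starts per subject on the first sweep.
#' @param n_starts_refit Fresh starts per subject on later sweeps.
#' @param seed Base seed; per-subject seeds are derived from it.
#' The returned object keeps two evidence sets: the per-subject free
#' energies of the final (refined-prior) fits, and those of the first
#' sweep under the fixed `init_prior`. Model comparison should use the
#' latter (see [evidence_matrix()]): once the prior has been refined
#' on the same data, the complexity penalty that protects against
#' over-parameterised models is largely absorbed into the prior, so
#' refined evidences are biased toward richer models.
#'
#' @return A `group_fit`: `posteriors` (list of `subject_posterior`),
#'   final `prior`, `f_log` (summed free energy per iteration),
#'   `initial_free_energy` (per-subject F under `init_prior`),
#'   `spec`, `converged`.
#' @export
fit_population <- function(sessions, spec, design,
                           init_prior = prior_spec(spec),
                           tol = 0.01, max_iter = 32,
                           n_starts = 8, n_starts_refit = 3, seed = 1L) {
  if (length(sessions) < 2) abort("Population fitting needs >= 2 subjects.")
  n <- length(sessions)
  prior <- init_prior
  f_log <- numeric(0)
  posteriors <- vector("list", n)
  converged <- FALSE
  drops <- 0L

  initial_f <- NULL

  for (iter in seq_len(max_iter)) {
    first <- iter == 1L
    posteriors <- lapply(seq_len(n), function(s) {
      fit_subject(sessions[[s]], spec, design, prior,
                  n_starts = if (first) n_starts else n_starts_refit,
                  seed = seed + 1000L * iter + s,
                  warm_start = if (!first) posteriors[[s]]$latent_mean)
    })
    if (first) {
      initial_f <- vapply(posteriors, `[[`, numeric(1), "free_energy")
    }
    f_sum <- sum(vapply(posteriors, `[[`, numeric(1), "free_energy"))
    f_log <- c(f_log, f_sum)

    if (!is.finite(tol)) { converged <- TRUE; break }
    if (iter > 1L) {
      delta <- f_sum - f_log[iter - 1L]
      if (abs(delta) < tol) { converged <- TRUE; break }
      drops <- if (delta < -tol) drops + 1L else 0L
      if (drops >= 3L) {
        warn(paste0("Population fit diverging: summed free energy dropped ",
                    "for 3 consecutive iterations (last change ",
                    signif(delta, 4), "). Returning current state."))
        break
      }
    }
    mu <- do.call(rbind, lapply(posteriors, `[[`, "latent_mean"))
    vv <- do.call(rbind, lapply(posteriors, `[[`, "param_vars"))
    prior <- prior_spec(spec,
                        mean = colMeans(mu),
                        var = pmax(apply(mu, 2, var) + colMeans(vv), 1e-4))
  }

  structure(list(posteriors = posteriors, prior = prior, f_log = f_log,
                 initial_free_energy = initial_f,
                 spec = spec, converged = converged),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat("<group_fit>", length(x$posteriors), "subjects | variant:",
      x$spec$variant, "|", length(x$f_log), "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  cat("  summed free energy:", signif(utils::tail(x$f_log, 1), 8), "\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.group_fit <- function(x, ...) {
  purrr::imap_dfr(x$posteriors, function(p, s) {
    nm <- names(p$latent_mean)
    tibble::tibble(
      subject = s,
      parameter = nm,
      estimate = vapply(nm, function(q) p$params[[q]], numeric(1)),
      latent_mean = unname(p$latent_mean),
      latent_var = unname(p$param_vars),
      precision = 1 / unname(p$param_vars)
    )
  })
}

#' @export
glance.group_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$posteriors),
    variant = x$spec$variant,
    free_energy = utils::tail(x$f_log, 1),
    iterations = length(x$f_log),
    converged = x$converged
  )
}

#' Predictive accuracy of a fitted subject
#'
#' Fraction of trials on which the model, at the posterior-mean
#' parameters, assigns probability above one half to the choice the
#' subject actually made (for binary choices this equals the
#' percentage of correct classifications). A tie (`P = 0.5` exactly)
#' counts as incorrect.
#'
#' @param posterior A `subject_posterior`.
#' @param session The subject's session tibble.
#' @param spec [model_spec()].
#' @param design [build_design()].
#' @return A proportion in `[0, 1]`.
#' @export
predictive_accuracy <- function(posterior, session, spec, design) {
  tr <- rl_loglik(posterior$params, spec, session, design, trace = TRUE)$trace
  p <- tr$p_avoid
  mean((p > 0.5 & session$avoided == 1) | (p < 0.5 & session$avoided == 0))
}

#' Bayesian p value against random choice
#'
#' Posterior probability of the null hypothesis that choices are purely
#' random (`P(avoid) = 0.5` on every trial), comparing the model's free
#' energy with the null evidence `n * log(1/2)` under equal model
#' priors.
#'
#' @param posterior A `subject_posterior`.
#' @param n_trials Number of trials (defaults to the fitted session's).
#' @return A probability.
#' @export
bayes_p_random <- function(posterior, n_trials = posterior$n_trials) {
  f_null <- n_trials * log(0.5)
  1 / (1 + exp(posterior$free_energy - f_null))
}
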