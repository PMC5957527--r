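#' Random-effects Bayesian model selection
#'
#' Treats the population as a mixture of subjects best described by
#' different models and infers the posterior Dirichlet density over
#' model frequencies from per-subject log model evidences (here, the
#' Laplace free energies from [fit_population()]). Concentrations are
#' updated by the standard variational scheme — subject-wise model
#' responsibilities weighted by `exp(digamma(alpha_k) -
#' digamma(sum(alpha)))` — iterated to convergence. The headline
#' statistic per model is its exceedance probability: the posterior
#' probability that it is the most frequent model in the population,
#' computed in closed form from the Beta distribution for two models
#' and by Monte-Carlo Dirichlet sampling otherwise.
#'
#' @param log_evidence Numeric matrix, subjects in rows, models in
#'   columns (column names become model names).
#' @param alpha0 Prior Dirichlet concentration per model (default 1,
#'   uniform).
#' @param n_samples Monte-Carlo samples for exceedance probabilities
#'   (default 1e6; MC error on an EP is below 0.001).
#' @param seed Seed for the Monte-Carlo draw.
#' @param tol Convergence tolerance on the concentrations.
#' @return A `bms_result`: `dirichlet_alpha`, `expected_frequencies`,
#'   `exceedance_probabilities`, `responsibilities` (subjects x
#'   models), `n_mc_samples`, `seed`.
#' @export
#' @examples
#' lev <- cbind(m1 = c(-100, -102, -98), m2 = c(-104, -103, -105))
#' rfx_bms(lev)
rfx_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e6,
                    seed = 1L, tol = 1e-6) {
  log_evidence <- as.matrix(log_evidence)
  if (ncol(log_evidence) < 2) abort("Need at least 2 models.")
  if (nrow(log_evidence) < 1) abort("Need at least 1 subject.")
  bad <- which(!is.finite(log_evidence), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("Non-finite log evidence at subject ", bad[1, 1],
                 ", model ", bad[1, 2], "."))
  }
  k <- ncol(log_evidence)
  models <- colnames(log_evidence) %||% paste0("model", seq_len(k))

  alpha <- rep(alpha0, k)
  for (iter in seq_len(10000)) {
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- exp(w - apply(w, 1, max))
    g <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  ef <- alpha / sum(alpha)
  if (k == 2) {
    # P(x1 > x2) for (x1, x2) ~ Dirichlet(a1, a2) is P(Beta(a1, a2) > 1/2)
    ep1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    ep <- c(ep1, 1 - ep1)
  } else {
    ep <- withr_seed(seed, {
      draws <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha,
                                                               each = n_samples)),
                      nrow = n_samples)
      tabulate(max.col(draws), nbins = k) / n_samples
    })
  }

  structure(list(
    dirichlet_alpha = setNames(alpha, models),
    expected_frequencies = setNames(ef, models),
    exceedance_probabilities = setNames(ep, models),
    responsibilities = g,
    n_mc_samples = if (k == 2) 0L else as.integer(n_samples),
    seed = seed
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", length(x$dirichlet_alpha), "models\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = names(x$dirichlet_alpha),
    alpha = unname(x$dirichlet_alpha),
    expected_frequency = unname(x$expected_frequencies),
    exceedance_probability = unname(x$exceedance_probabilities)
  )
}

#' Collect a log-evidence matrix from per-model group fits
#'
#' By default the per-subject free energies computed under the fixed
#' initial prior are used, so all models are scored against the same
#' weakly-informative prior. Evidences taken after empirical-Bayes
#' prior refinement (`evidence = "refined"`) are biased toward richer
#' models, because the refined prior — learned from the same data —
#' absorbs most of the complexity penalty for extra parameters.
#'
#' @param fits Named list of `group_fit` objects over the same
#'   subjects.
#' @param evidence `"initial"` (fixed-prior, default) or `"refined"`
#'   (final-iteration) free energies.
#' @return A subjects x models matrix of free energies.
#' @export
evidence_matrix <- function(fits, evidence = c("initial", "refined")) {
  evidence <- match.arg(evidence)
  stopifnot(length(fits) >= 2)
  ns <- vapply(fits, function(f) length(f$posteriors), integer(1))
  if (length(unique(ns)) != 1) {
    abort("All group fits must cover the same subjects.")
  }
  sapply(fits, function(f) {
    if (evidence == "initial") f$initial_free_energy
    else vapply(f$posteriors, `[[`, numeric(1), "free_energy")
  })
}
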