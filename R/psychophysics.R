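#' Lapse-bounded logistic psychometric function
#'
#' Probability of reporting two shapes as "different" at a given
#' spikiness difference `delta_rho`:
#' `P(diff) = (1 - lapse) / (1 + exp((alpha - delta_rho) / beta))`.
#' The guess rate is fixed at 0, so predictions lie in `[0, 1 - lapse]`.
#'
#' @param alpha Bias: the rho difference at the inflection point.
#' @param beta Slope scale (rho units); must be positive.
#' @param lapse Stimulus-independent error rate bounding the upper
#'   asymptote at `1 - lapse`.
#' @param delta_rho Rho difference(s) between target and comparison.
#' @return Probabilities, same length as `delta_rho`.
#' @export
#' @examples
#' psychometric_prob(0.05, 0.02, 0, delta_rho = 0.071)
psychometric_prob <- function(alpha, beta, lapse = 0, delta_rho) {
  if (beta <= 0) abort("`beta` (slope) must be positive.")
  if (lapse < 0 || lapse >= 1) abort("`lapse` must lie in [0, 1).")
  (1 - lapse) / (1 + exp((alpha - delta_rho) / beta))
}

#' Fit a psychometric function by constrained maximum likelihood
#'
#' Binomial maximum-likelihood fit of [psychometric_prob()] to
#' same/different discrimination counts, with the lapse rate box-bounded
#' in `[0, lapse_max]` and the slope constrained positive. Optimisation
#' uses `L-BFGS-B` from multiple start points.
#'
#' @param data A data frame with columns `delta_rho` (stimulus level),
#'   `n_trials`, and `n_different` (count of "different" responses).
#' @param lapse_max Upper bound on the lapse rate (default 0.06).
#' @param n_starts Number of random optimisation starts (default 10).
#' @param seed Seed for the start points.
#' @return An object of class `psychometric_fit`: list with `alpha`,
#'   `beta`, `lapse`, `logLik`, `deviance`, `boundary` flag, `data`,
#'   and the per-start log-likelihoods.
#' @export
#' @examples
#' d <- tibble::tibble(delta_rho = c(0, 0.05, 0.075, 0.1, 0.15),
#'                     n_trials = 32,
#'                     n_different = c(2, 14, 24, 29, 32))
#' fit <- fit_psychometric(d)
#' tidy(fit)
fit_psychometric <- function(data, lapse_max = 0.06, n_starts = 10,
                             seed = 1L) {
  stopifnot(all(c("delta_rho", "n_trials", "n_different") %in% names(data)))
  if (any(data$n_different < 0) || any(data$n_different > data$n_trials)) {
    abort("`n_different` must lie in [0, n_trials] at every level.")
  }
  if (any(data$delta_rho < 0)) abort("`delta_rho` levels must be non-negative.")
  lev <- data[data$n_trials > 0, , drop = FALSE]
  if (length(unique(lev$delta_rho)) < 3) {
    abort("Need at least 3 distinct stimulus levels with trials.")
  }

  nll <- function(par) {
    p <- psychometric_prob(par[1], par[2], par[3], lev$delta_rho)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(lev$n_different * log(p) +
           (lev$n_trials - lev$n_different) * log(1 - p))
  }

  rng <- range(lev$delta_rho)
  lower <- c(-0.5, 1e-4, 0)
  upper <- c(1.0, 1.0, lapse_max)
  withr_seed(seed, {
    starts <- rbind(
      c(mean(rng), diff(rng) / 4, lapse_max / 2),
      cbind(runif(n_starts - 1, rng[1], rng[2]),
            exp(runif(n_starts - 1, log(0.005), log(0.2))),
            runif(n_starts - 1, 0, lapse_max))
    )
    fits <- apply(starts, 1, function(s) {
      tryCatch(
        optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e2, pgtol = 1e-10, maxit = 500)),
        error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) abort("Psychometric optimisation failed from all starts.")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  # polish on the natural parameter scales so all starts agree tightly
  best <- optim(best$par, nll, method = "L-BFGS-B",
                lower = lower, upper = upper,
                control = list(factr = 1, pgtol = 0, maxit = 2000,
                               parscale = c(0.05, 0.02, 0.02)))

  # saturated binomial log-likelihood for the deviance
  phat <- lev$n_different / lev$n_trials
  ll_sat <- sum(ifelse(lev$n_different > 0,
                       lev$n_different * log(phat), 0) +
                ifelse(lev$n_trials - lev$n_different > 0,
                       (lev$n_trials - lev$n_different) * log(1 - phat), 0))

  degenerate <- length(unique(phat)) == 1L &&
    (all(lev$n_different == 0) | all(lev$n_different == lev$n_trials))
  at_bound <- any(abs(best$par - lower) < 1e-8 * pmax(1, abs(lower)) |
                    abs(best$par - upper) < 1e-8 * pmax(1, abs(upper)))
  if (degenerate) {
    warn("Degenerate discrimination data (all responses identical): boundary estimate returned.")
  }

  structure(
    list(alpha = best$par[1], beta = best$par[2], lapse = best$par[3],
         logLik = -best$value,
         deviance = 2 * (ll_sat - (-best$value)),
         boundary = degenerate || at_bound,
         lapse_max = lapse_max,
         start_logLik = -vals,
         data = tibble::as_tibble(lev)),
    class = "psychometric_fit"
  )
}

#' Invert a psychometric function for a discrimination threshold
#'
#' Closed-form inversion of [psychometric_prob()]: the rho difference at
#' which the "different" probability reaches `target`. The 75% point is
#' the discrimination threshold theta used to place generalization
#' stimuli around each CS+.
#'
#' @param fit A `psychometric_fit`, or a list with `alpha`, `beta`,
#'   `lapse`.
#' @param target Target probability (default 0.75); must be below the
#'   upper asymptote `1 - lapse`.
#' @return The threshold, in rho units.
#' @export
threshold <- function(fit, target = 0.75) {
  if (target >= 1 - fit$lapse) {
    abort(paste0("Target ", target, " is unreachable: the upper asymptote is ",
                 1 - fit$lapse, "."))
  }
  if (target <= 0) abort("`target` must be positive.")
  fit$alpha - fit$beta * log((1 - fit$lapse) / target - 1)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> alpha =", signif(x$alpha, 4),
      " beta =", signif(x$beta, 4),
      " lapse =", signif(x$lapse, 4), "\n")
  cat("  logLik =", signif(x$logLik, 6),
      " deviance =", signif(x$deviance, 4),
      if (x$boundary) " [boundary]" else "", "\n")
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta", "lapse"),
                 estimate = c(x$alpha, x$beta, x$lapse))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, deviance = x$deviance,
                 boundary = x$boundary,
                 threshold_75 = threshold(x, 0.75))
}

#' Simulate same/different discrimination data
#'
#' Draws binomial response counts from a psychometric observer on the
#' study's fixed comparison grid (rho intervals 0, 0.05, 0.075, 0.1,
#' 0.15 by default).
#'
#' @param alpha,beta,lapse True psychometric parameters.
#' @param levels Rho-difference grid.
#' @param n_per_level Trials per level (default 32, i.e. 160 in total).
#' @param seed Integer seed.
#' @return A tibble usable with [fit_psychometric()].
#' @export
simulate_discrimination <- function(alpha, beta, lapse = 0.02,
                                    levels = c(0, 0.05, 0.075, 0.1, 0.15),
                                    n_per_level = 32, seed = 1L) {
  p <- psychometric_prob(alpha, beta, lapse, levels)
  withr_seed(seed, {
    tibble::tibble(
      delta_rho = levels,
      n_trials = n_per_level,
      n_different = rbinom(length(levels), n_per_level, p)
    )
  })
}
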