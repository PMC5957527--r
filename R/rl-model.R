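#' Specify a generative avoidance-learning model variant
#'
#' Three nested variants of the hybrid Rescorla-Wagner / Pearce-Hall
#' avoidance learner are supported:
#' * `"perceptual"` — perceptual confusion only: each stimulus is an
#'   independent state; a GS is evaluated as a mixture of its own value
#'   and the adjacent CS+ value with weight `p_confuse` (default 0.25,
#'   i.e. GS held 75% discriminable from the CS+).
#' * `"value_1w"` — perceptual confusion plus Gaussian value
#'   generalization across the rho axis with a single width `sigma`.
#' * `"value_2w"` — as above with separate widths for aversive
#'   (`sigma_a`) and neutral (`sigma_n`) feedback.
#'
#' The confusion probability can be held constant across trials
#' (`confusion = "constant"`) or interpolated linearly from `p_start`
#' to `p_end` over the session (`"linear"`), emulating a drift in GS
#' discriminability between pre- and post-conditioning perceptual
#' tests.
#'
#' @param variant Model variant.
#' @param confusion Confusion schedule.
#' @param p_confuse Constant confusion probability (default 0.25).
#' @param p_start,p_end Endpoints for the linear schedule.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("value_2w", "value_1w", "perceptual"),
                       confusion = c("constant", "linear"),
                       p_confuse = 0.25, p_start = NULL, p_end = NULL) {
  variant <- match.arg(variant)
  confusion <- match.arg(confusion)
  if (p_confuse < 0 || p_confuse > 1) abort("`p_confuse` must lie in [0, 1].")
  if (confusion == "linear") {
    if (is.null(p_start) || is.null(p_end)) {
      abort("A linear confusion schedule needs `p_start` and `p_end`.")
    }
    if (any(c(p_start, p_end) < 0) || any(c(p_start, p_end) > 1)) {
      abort("`p_start`/`p_end` must lie in [0, 1].")
    }
  }
  free <- switch(variant,
    perceptual = c("kappa", "eta", "beta", "bias"),
    value_1w = c("kappa", "eta", "beta", "bias", "sigma"),
    value_2w = c("kappa", "eta", "beta", "bias", "sigma_a", "sigma_n"))
  structure(list(variant = variant, confusion = confusion,
                 p_confuse = p_confuse, p_start = p_start, p_end = p_end,
                 free_parameter_names = free),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> variant:", x$variant,
      "| confusion:", x$confusion,
      if (x$confusion == "constant") paste0("(p = ", x$p_confuse, ")")
      else paste0("(", x$p_start, " -> ", x$p_end, ")"),
      "\n  free parameters:", paste(x$free_parameter_names, collapse = ", "),
      "\n")
  invisible(x)
}

#' Agent parameters for the avoidance learner
#'
#' @param kappa Learning-rate scale in (0, 1).
#' @param eta Associability (Pearce-Hall) update weight in (0, 1).
#' @param beta Softmax sensitivity, positive.
#' @param bias Decision bias (positive values bias against avoiding).
#' @param sigma Generalization width for the one-width variant.
#' @param sigma_a,sigma_n Aversive / neutral generalization widths for
#'   the two-width variant (rho units, positive).
#' @param alpha0 Initial associability (default 1; not a free
#'   parameter).
#' @return An `agent_params` list.
#' @export
agent_params <- function(kappa, eta, beta, bias = 0,
                         sigma = NULL, sigma_a = NULL, sigma_n = NULL,
                         alpha0 = 1) {
  if (kappa <= 0 || kappa >= 1) abort("`kappa` must lie in (0, 1).")
  if (eta <= 0 || eta >= 1) abort("`eta` must lie in (0, 1).")
  if (beta < 0) abort("`beta` must be non-negative.")
  for (s in c(sigma, sigma_a, sigma_n)) {
    if (s <= 0) abort("Generalization widths must be positive.")
  }
  if (alpha0 < 0) abort("`alpha0` must be non-negative.")
  structure(list(kappa = kappa, eta = eta, beta = beta, bias = bias,
                 sigma = sigma, sigma_a = sigma_a, sigma_n = sigma_n,
                 alpha0 = alpha0),
            class = "agent_params")
}

# resolve the (sigma_a, sigma_n) pair actually used by a variant;
# errors if the params do not cover the spec's free parameters
resolve_sigmas <- function(params, spec) {
  switch(spec$variant,
    perceptual = c(1, 1),  # unused by the perceptual-only pass
    value_1w = {
      s <- params$sigma %||% params$sigma_a
      if (is.null(s)) abort("Variant `value_1w` needs `sigma`.")
      c(s, s)
    },
    value_2w = {
      if (is.null(params$sigma_a) || is.null(params$sigma_n)) {
        abort("Variant `value_2w` needs `sigma_a` and `sigma_n`.")
      }
      c(params$sigma_a, params$sigma_n)
    })
}

# per-trial confusion probabilities under the spec's schedule
confusion_schedule <- function(spec, n_trials) {
  if (spec$confusion == "constant") {
    rep(spec$p_confuse, n_trials)
  } else {
    seq(spec$p_start, spec$p_end, length.out = n_trials)
  }
}

#' Gaussian generalization weights across the rho axis
#'
#' Similarity weight of every stimulus to the presented one:
#' `G_j = exp(-(rho_i - rho_j)^2 / (2 * sigma^2))`. The presented
#' stimulus always has weight 1.
#'
#' @param rho_presented Rho of the presented stimulus.
#' @param rho_all Rho coordinates of all stimuli.
#' @param sigma Width of the generalization function, positive.
#' @return Numeric weights in (0, 1], same length as `rho_all`.
#' @export
gaussian_weights <- function(rho_presented, rho_all, sigma) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  exp(-(rho_presented - rho_all)^2 / (2 * sigma^2))
}

#' Effective not-avoid value under perceptual confusion
#'
#' A generalization stimulus is evaluated as a mixture of its own
#' learned value and that of the CS+ it flanks:
#' `(1 - p) * V_GS + p * V_adjacent_CS+`; other stimuli return their
#' own value unchanged.
#'
#' @param values Named numeric vector of per-stimulus not-avoid values.
#' @param stimulus Stimulus label.
#' @param design An `avoid_design`.
#' @param confusion_prob Perceptual confusion probability.
#' @return The effective not-avoid value.
#' @export
effective_nonavoid_value <- function(values, stimulus, design,
                                     confusion_prob = 0.25) {
  row <- design$stimuli[design$stimuli$label == stimulus, ]
  if (nrow(row) == 0) abort(paste0("Unknown stimulus `", stimulus, "`."))
  if (row$role != "GS") return(unname(values[stimulus]))
  adj <- row$adjacent_cs_plus
  if (is.na(adj) || !adj %in% names(values)) {
    abort(paste0("GS `", stimulus, "` lacks an adjacent CS+ link."))
  }
  unname((1 - confusion_prob) * values[stimulus] + confusion_prob * values[adj])
}

#' Softmax probability of an avoidance decision
#'
#' `P(avoid) = 1 / (1 + exp(-beta * (V_avoid - V_notAvoid - cost -
#' bias)))` with the avoid value pinned at 0, so avoidance becomes
#' likely when the not-avoid value is more negative than the combined
#' response cost and bias.
#'
#' @param effective_value Effective not-avoid value (outcome scale;
#'   0 = safe, -1 = certain aversive outcome).
#' @param beta Softmax sensitivity, non-negative.
#' @param bias Decision bias (positive = against avoiding).
#' @param avoid_cost Per-decision avoidance cost (default 0.2).
#' @return Avoidance probability, strictly inside (0, 1).
#' @export
p_avoid <- function(effective_value, beta, bias = 0, avoid_cost = 0.2) {
  if (any(beta < 0)) abort("`beta` must be non-negative.")
  plogis(beta * (0 - effective_value - avoid_cost - bias))
}

#' Initialise learner state
#'
#' All not-avoid values start at 0 (neutral on the 0 / -1 outcome
#' scale) and the associability at `alpha0`.
#'
#' @param design An `avoid_design`.
#' @param alpha0 Initial associability.
#' @return A `learner_state` list: `values` (named), `associability`,
#'   `trial_index`.
#' @export
learner_state <- function(design, alpha0 = 1) {
  structure(list(
    values = setNames(rep(0, nrow(design$stimuli)), design$stimuli$label),
    associability = alpha0,
    trial_index = 0L
  ), class = "learner_state")
}

#' Advance the learner by one trial
#'
#' Applies the hybrid update: if the trial was avoided the outcome is
#' cancelled, the prediction error is 0 by definition, values are
#' unchanged and the associability decays to `(1 - eta) * alpha`.
#' Otherwise the prediction error `PE = R - V_presented` updates the
#' presented state by `kappa * alpha * PE`; under the value-spread
#' variants every state `j` is updated by `kappa * alpha * PE * G_j`,
#' with the Gaussian width chosen by the realised outcome valence
#' (aversive -> `sigma_a`, neutral -> `sigma_n`). The associability
#' then follows the Pearce-Hall rule
#' `alpha' = eta * |PE| + (1 - eta) * alpha`.
#'
#' @param state A [learner_state()].
#' @param stimulus Stimulus label presented on this trial.
#' @param avoided Logical: was an avoidance response made?
#' @param reward Realised outcome `R` (0 or -1; forced to 0 when
#'   avoided).
#' @param params [agent_params()].
#' @param spec [model_spec()].
#' @param design [build_design()].
#' @return A list with the new `state` and a one-row `trace` tibble
#'   (`v_eff`, `p_avoid`, `pe`, `alpha`).
#' @export
rl_step <- function(state, stimulus, avoided, reward, params, spec, design) {
  if (!stimulus %in% names(state$values)) {
    abort(paste0("Unknown stimulus `", stimulus, "`."))
  }
  t_next <- state$trial_index + 1L
  if (spec$confusion != "constant") {
    abort("The step-wise API supports constant confusion schedules; use `rl_loglik()` / `simulate_agent()` for scheduled confusion.")
  }
  pc <- spec$p_confuse
  v_eff <- effective_nonavoid_value(state$values, stimulus, design, pc)
  p <- p_avoid(v_eff, params$beta, params$bias, design$avoid_cost)
  alpha_used <- state$associability

  if (avoided) {
    pe <- 0
    reward <- 0
    state$associability <- (1 - params$eta) * state$associability
  } else {
    i <- stimulus
    pe <- reward - state$values[[i]]
    if (spec$variant == "perceptual") {
      state$values[[i]] <- state$values[[i]] +
        params$kappa * alpha_used * pe
    } else {
      sig <- resolve_sigmas(params, spec)
      sigma <- if (reward == -1) sig[1] else sig[2]
      g <- gaussian_weights(design$stimuli$rho[design$stimuli$label == i],
                            design$stimuli$rho, sigma)
      state$values <- state$values + params$kappa * alpha_used * pe * g
    }
    state$associability <- params$eta * abs(pe) +
      (1 - params$eta) * state$associability
  }
  state$trial_index <- t_next

  list(state = state,
       trace = tibble::tibble(trial = t_next, stimulus = stimulus,
                              v_eff = v_eff, p_shock = -v_eff,
                              p_avoid = p, pe = unname(pe),
                              alpha = alpha_used))
}

# compile a sequence/session + design into the integer representation
# consumed by the compiled pass
compile_trials <- function(trials, design) {
  labels <- design$stimuli$label
  stim <- match(trials$stimulus, labels)
  if (anyNA(stim)) {
    abort(paste0("Session contains stimuli absent from the design: ",
                 paste(unique(trials$stimulus[is.na(stim)]), collapse = ", ")))
  }
  adj <- match(design$stimuli$adjacent_cs_plus, labels)
  adj[is.na(adj)] <- 0L
  gs_stim <- design$stimuli$role == "GS"
  if (any(gs_stim & adj == 0L)) {
    abort("Design error: a GS lacks an adjacent CS+ link.")
  }
  list(stim = stim,
       is_gs = as.integer(trials$role == "GS"),
       adj = adj,
       sched = ifelse(trials$scheduled_outcome == "aversive", -1, 0),
       rho = design$stimuli$rho)
}

#' Log-likelihood of observed choices under an avoidance-learning model
#'
#' Runs the learner over the session's trial order and accumulates the
#' Bernoulli log-likelihood of the observed avoid / no-avoid choices
#' under the softmax rule. Optionally returns the per-trial latent
#' trace (effective value, predicted shock probability, prediction
#' error, associability) for use as model-based regressors.
#'
#' @param params [agent_params()].
#' @param spec [model_spec()].
#' @param session A session tibble as returned by [simulate_agent()]:
#'   the sequence columns plus `avoided` (0/1) and `outcome` (0/-1).
#' @param design [build_design()].
#' @param trace Return the per-trial latent trace?
#' @return A list with `logLik` and (when requested) a `trace` tibble.
#' @export
rl_loglik <- function(params, spec, session, design, trace = FALSE) {
  comp <- compile_trials(session, design)
  sig <- resolve_sigmas(params, spec)
  variant <- match(spec$variant, c("perceptual", "value_1w", "value_2w")) - 1L
  # observed outcomes drive learning; scheduled ones only matter unavoided
  sched <- ifelse(session$avoided == 1, 0, session$outcome)
  res <- rl_loglik_cpp(comp$stim, comp$is_gs, comp$adj, sched,
                       as.integer(session$avoided), comp$rho,
                       confusion_schedule(spec, nrow(session)),
                       params$kappa, params$eta, params$beta, params$bias,
                       sig[1], sig[2], variant,
                       params$alpha0 %||% 1, design$avoid_cost,
                       isTRUE(trace))
  out <- list(logLik = res$logLik)
  if (isTRUE(trace)) {
    out$trace <- tibble::tibble(
      trial = session$trial, stimulus = session$stimulus,
      v_eff = res$trace$v_eff, p_shock = -res$trace$v_eff,
      p_avoid = res$trace$p_avoid, pe = res$trace$pe,
      alpha = res$trace$alpha)
  }
  out
}

#' Simulate an agent on a trial sequence
#'
#' Generates choices from the softmax avoidance probability as the
#' learner runs over the sequence. Outcomes follow the sequence's
#' schedule when unavoided and are cancelled (0) when avoided; GS and
#' CS- trials are never scheduled aversive, so they can never deliver
#' an aversive outcome.
#'
#' @param params [agent_params()].
#' @param spec [model_spec()].
#' @param sequence A [generate_sequence()] tibble.
#' @param design [build_design()].
#' @param seed Integer seed; the session is reproducible from it.
#' @param trace Also return the latent trace?
#' @return A list with `session` (sequence + `avoided`, `outcome`) and
#'   optionally `trace`.
#' @export
simulate_agent <- function(params, spec, sequence, design, seed,
                           trace = FALSE) {
  comp <- compile_trials(sequence, design)
  sig <- resolve_sigmas(params, spec)
  variant <- match(spec$variant, c("perceptual", "value_1w", "value_2w")) - 1L
  res <- withr_seed(seed, {
    rl_simulate_cpp(comp$stim, comp$is_gs, comp$adj, comp$sched, comp$rho,
                    confusion_schedule(spec, nrow(sequence)),
                    params$kappa, params$eta, params$beta, params$bias,
                    sig[1], sig[2], variant,
                    params$alpha0 %||% 1, design$avoid_cost,
                    isTRUE(trace))
  })
  session <- sequence
  session$avoided <- res$avoided
  session$outcome <- res$outcome
  out <- list(session = session)
  if (isTRUE(trace)) {
    out$trace <- tibble::tibble(
      trial = sequence$trial, stimulus = sequence$stimulus,
      v_eff = res$trace$v_eff, p_shock = -res$trace$v_eff,
      p_avoid = res$trace$p_avoid, pe = res$trace$pe,
      alpha = res$trace$alpha)
  }
  out
}
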