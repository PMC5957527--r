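# Independent oracle for the learning-model likelihood: a deliberately
# naive trial-by-trial loop written directly from the model equations,
# with no code shared with the package's compiled implementation.
naive_loglik <- function(kappa, eta, beta, bias, session, design,
                         variant = "value_2w", sigma_a = 1, sigma_n = 1,
                         p_confuse = 0.25, alpha0 = 1, cost = 0.2) {
  stim <- design$stimuli
  V <- setNames(rep(0, nrow(stim)), stim$label)
  alpha <- alpha0
  ll <- 0
  for (t in seq_len(nrow(session))) {
    lab <- session$stimulus[t]
    row <- stim[stim$label == lab, ]
    v <- V[[lab]]
    if (row$role == "GS") {
      v <- (1 - p_confuse) * V[[lab]] + p_confuse * V[[row$adjacent_cs_plus]]
    }
    p <- 1 / (1 + exp(-beta * (0 - v - cost - bias)))
    ll <- ll + if (session$avoided[t] == 1) log(p) else log(1 - p)
    if (session$avoided[t] == 1) {
      alpha <- (1 - eta) * alpha
    } else {
      R <- session$outcome[t]
      pe <- R - V[[lab]]
      if (variant == "perceptual") {
        V[[lab]] <- V[[lab]] + kappa * alpha * pe
      } else {
        sigma <- if (variant == "value_1w") sigma_a
                 else if (R == -1) sigma_a else sigma_n
        for (j in stim$label) {
          g <- 1 / exp((row$rho - stim$rho[stim$label == j])^2 /
                         (2 * sigma^2))
          V[[j]] <- V[[j]] + kappa * alpha * pe * g
        }
      }
      alpha <- eta * abs(pe) + (1 - eta) * alpha
    }
  }
  ll
}

# random session fixture over the default design (choices and outcomes
# arbitrary but internally consistent: avoided trials have outcome 0,
# aversive outcomes only on CS+ trials)
random_fixture <- function(seed, n_trials = 50) {
  set.seed(seed)
  design <- build_design()
  stim <- design$stimuli
  idx <- sample(nrow(stim), n_trials, replace = TRUE)
  avoided <- rbinom(n_trials, 1, runif(1, 0.2, 0.8))
  outcome <- ifelse(avoided == 1, 0,
                    ifelse(stim$role[idx] == "CS_PLUS",
                           -rbinom(n_trials, 1, 0.8), 0))
  session <- tibble::tibble(
    block = rep(1L, n_trials), trial = seq_len(n_trials),
    stimulus = stim$label[idx], role = stim$role[idx],
    rho = stim$rho[idx],
    scheduled_outcome = ifelse(outcome == -1, "aversive", "neutral"),
    avoided = avoided, outcome = outcome)
  params <- list(kappa = runif(1, 0.05, 0.95), eta = runif(1, 0.05, 0.95),
                 beta = runif(1, 0, 10), bias = runif(1, -0.5, 1),
                 sigma_a = exp(runif(1, log(0.02), log(1.5))),
                 sigma_n = exp(runif(1, log(0.02), log(1.5))),
                 p_confuse = runif(1))
  variant <- sample(c("perceptual", "value_1w", "value_2w"), 1)
  list(design = design, session = session, params = params,
       variant = variant)
}

# package-side likelihood for a fixture
fixture_loglik <- function(fx) {
  spec <- model_spec(fx$variant, p_confuse = fx$params$p_confuse)
  ap <- agent_params(fx$params$kappa, fx$params$eta, fx$params$beta,
                     fx$params$bias,
                     sigma = if (fx$variant == "value_1w") fx$params$sigma_a,
                     sigma_a = if (fx$variant == "value_2w") fx$params$sigma_a,
                     sigma_n = if (fx$variant == "value_2w") fx$params$sigma_n)
  rl_loglik(ap, spec, fx$session, fx$design)$logLik
}

fixture_oracle_loglik <- function(fx) {
  naive_loglik(fx$params$kappa, fx$params$eta, fx$params$beta,
               fx$params$bias, fx$session, fx$design,
               variant = fx$variant,
               sigma_a = fx$params$sigma_a, sigma_n = fx$params$sigma_n,
               p_confuse = fx$params$p_confuse)
}
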