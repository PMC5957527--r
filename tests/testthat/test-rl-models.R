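test_that("gaussian generalization weights match hand-evaluated values", {
  expect_equal(gaussian_weights(0.25, 0.25, 0.5), 1)
  # wide aversive width barely attenuates at the CS+ / CS- gap
  expect_equal(gaussian_weights(0.25, 0.40, 0.752),
               exp(-0.0225 / (2 * 0.752^2)), tolerance = 1e-12)
  expect_equal(round(gaussian_weights(0.25, 0.40, 0.752), 4), 0.9803)
  # narrow neutral width kills transfer at the same gap
  expect_lt(gaussian_weights(0.25, 0.40, 0.028), 1e-6)
  expect_error(gaussian_weights(0.25, 0.4, 0), "positive")
})

test_that("perceptual confusion mixes GS value with the adjacent CS+", {
  d <- build_design()
  v <- setNames(rep(0, 7), d$stimuli$label)
  expect_equal(effective_nonavoid_value(v, "GS1lo", d, 0.25), 0)
  v["GS1lo"] <- -0.1
  v["CSplus1"] <- -0.8
  expect_equal(effective_nonavoid_value(v, "GS1lo", d, 0.25),
               0.75 * -0.1 + 0.25 * -0.8)
  # non-GS stimuli return their own value unchanged
  expect_equal(effective_nonavoid_value(v, "CSplus1", d, 0.25), -0.8)
  expect_error(effective_nonavoid_value(v, "nope", d), "Unknown")
})

test_that("softmax avoidance probability matches hand calculations", {
  expect_equal(p_avoid(0, 0, 0.4, 0.2), 0.5)
  expect_equal(p_avoid(0, 5, 0.415, 0.2), 1 / (1 + exp(3.075)),
               tolerance = 1e-12)
  expect_equal(p_avoid(-0.8, 5, 0.415, 0.2), 1 / (1 + exp(-0.925)),
               tolerance = 1e-12)
  p <- p_avoid(seq(-1, 0, by = 0.1), 8, 0.4, 0.2)
  expect_true(all(p > 0 & p < 1))
})

test_that("single-trial updates follow the printed learning rules", {
  d <- build_design()
  spec <- model_spec("value_2w")
  ap <- agent_params(0.8, 0.3, 5, 0.4, sigma_a = 0.75, sigma_n = 0.03)
  st <- learner_state(d, alpha0 = 0.6)

  # avoided trial: no PE, no value change, associability decays
  res <- rl_step(st, "CSplus1", avoided = TRUE, reward = 0, ap, spec, d)
  expect_equal(res$trace$pe, 0)
  expect_equal(res$state$values, st$values)
  expect_equal(res$state$associability, 0.42)

  # unavoided shock: delta-rule update of the presented state
  st2 <- learner_state(d, alpha0 = 0.5)
  st2$values["CSplus1"] <- -0.5
  res2 <- rl_step(st2, "CSplus1", avoided = FALSE, reward = -1, ap, spec, d)
  expect_equal(res2$trace$pe, -0.5)
  expect_equal(res2$state$values[["CSplus1"]],
               -0.5 + 0.8 * 0.5 * -0.5)
  # Pearce-Hall: alpha' = eta|PE| + (1-eta) alpha = 0.15 + 0.35
  expect_equal(res2$state$associability, 0.5)
  # aversive spread reaches every state in proportion to similarity
  g <- gaussian_weights(0.25, d$stimuli$rho, 0.75)
  expect_equal(unname(res2$state$values - st2$values),
               0.8 * 0.5 * -0.5 * g)

  # neutral outcome with a narrow width leaves neighbours untouched
  ap_n <- agent_params(0.8, 0.3, 5, 0.4, sigma_a = 0.75, sigma_n = 0.028)
  st3 <- learner_state(d)
  st3$values["CSplus1"] <- -0.5
  res3 <- rl_step(st3, "CSplus1", avoided = FALSE, reward = 0, ap_n, spec, d)
  moved <- abs(res3$state$values - st3$values)
  far <- d$stimuli$label[abs(d$stimuli$rho - 0.25) >= 0.15]
  expect_lt(max(moved[far]), 1e-6 * abs(0.8 * 1 * 0.5))
})

test_that("likelihood matches the naive trial-loop oracle on random fixtures", {
  for (seed in 1:40) {
    fx <- random_fixture(seed)
    expect_equal(fixture_loglik(fx), fixture_oracle_loglik(fx),
                 tolerance = 1e-10)
  }
})

test_that("likelihood closed forms hold in degenerate regimes", {
  d <- build_design()
  sq <- generate_sequence(d, seed = 3)
  spec <- model_spec("perceptual")

  # all-avoid session: values frozen, constant avoid probability
  sess <- sq
  sess$avoided <- 1L
  sess$outcome <- 0
  ap <- agent_params(0.5, 0.3, 5, 0.4)
  p_star <- p_avoid(0, 5, 0.4, 0.2)
  expect_equal(rl_loglik(ap, spec, sess, d)$logLik,
               nrow(sess) * log(p_star), tolerance = 1e-10)

  # zero sensitivity: every choice is a coin flip
  sess$avoided <- rep(c(0L, 1L), length.out = nrow(sess))
  ap0 <- agent_params(0.5, 0.3, 0, 0.4)
  expect_equal(rl_loglik(ap0, spec, sess, d)$logLik,
               nrow(sess) * log(0.5), tolerance = 1e-12)
})

test_that("two-width model with equal widths reproduces the one-width model", {
  for (seed in 41:55) {
    fx <- random_fixture(seed)
    s <- fx$params$sigma_a
    ap1 <- agent_params(fx$params$kappa, fx$params$eta, fx$params$beta,
                        fx$params$bias, sigma = s)
    ap2 <- agent_params(fx$params$kappa, fx$params$eta, fx$params$beta,
                        fx$params$bias, sigma_a = s, sigma_n = s)
    expect_identical(
      rl_loglik(ap1, model_spec("value_1w"), fx$session, fx$design)$logLik,
      rl_loglik(ap2, model_spec("value_2w"), fx$session, fx$design)$logLik)
  }
})

test_that("state trajectories respect their bounds", {
  d <- build_design()
  spec <- model_spec("perceptual")
  for (seed in 1:20) {
    set.seed(seed)
    ap <- agent_params(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                       runif(1, 0, 8), runif(1, -0.3, 0.8))
    sq <- generate_sequence(d, seed = seed)
    sim <- simulate_agent(ap, spec, sq, d, seed = seed + 500, trace = TRUE)
    # replay step-by-step to inspect values and associability
    st <- learner_state(d)
    for (t in seq_len(nrow(sim$session))) {
      st <- rl_step(st, sim$session$stimulus[t],
                    sim$session$avoided[t] == 1,
                    sim$session$outcome[t], ap, spec, d)$state
      expect_true(all(st$values >= -1 - 1e-12 & st$values <= 1e-12))
      expect_true(st$associability >= 0 && st$associability <= 1 + 1e-12)
    }
  }
})

test_that("simulation is reproducible and respects the schedule", {
  d <- build_design()
  sq <- generate_sequence(d, seed = 11)
  spec <- model_spec("value_2w")
  ap <- agent_params(0.5, 0.3, 5, 0.4, sigma_a = 0.75, sigma_n = 0.03)
  s1 <- simulate_agent(ap, spec, sq, d, seed = 21)
  s2 <- simulate_agent(ap, spec, sq, d, seed = 21)
  expect_identical(s1$session, s2$session)
  # GS and CS- trials never deliver an aversive outcome
  expect_true(all(s1$session$outcome[s1$session$role != "CS_PLUS"] == 0))
  # avoided trials always cancel the outcome
  expect_true(all(s1$session$outcome[s1$session$avoided == 1] == 0))
})

test_that("a non-learning agent keeps a flat avoidance rate", {
  d <- build_design()
  spec <- model_spec("perceptual")
  # kappa ~ 0 freezes values at 0, so P(avoid) is constant
  ap <- agent_params(1e-9, 0.3, 5, -0.1)
  p0 <- p_avoid(0, 5, -0.1, 0.2)
  sims <- lapply(1:20, function(s)
    simulate_agent(ap, spec, generate_sequence(d, seed = s), d,
                   seed = 900 + s)$session)
  all_tr <- dplyr::bind_rows(sims)
  for (r in unique(all_tr$role)) {
    k <- sum(all_tr$avoided[all_tr$role == r])
    n <- sum(all_tr$role == r)
    bounds <- qbinom(c(0.005, 0.995), n, p0)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("latent trace exposes regressor quantities consistently", {
  d <- build_design()
  spec <- model_spec("value_2w")
  ap <- agent_params(0.5, 0.3, 5, 0.4, sigma_a = 0.75, sigma_n = 0.03)
  sq <- generate_sequence(d, seed = 2)
  sim <- simulate_agent(ap, spec, sq, d, seed = 3, trace = TRUE)
  tr <- sim$trace
  expect_equal(tr$p_shock, -tr$v_eff)
  expect_true(all(tr$pe[sim$session$avoided == 1] == 0))
  expect_true(all(tr$p_avoid > 0 & tr$p_avoid < 1))
  expect_equal(tr$alpha[1], 1)
  # likelihood trace reproduces the simulation trace on the same data
  tr2 <- rl_loglik(ap, spec, sim$session, d, trace = TRUE)$trace
  expect_equal(tr2$p_avoid, tr$p_avoid, tolerance = 1e-12)
  expect_equal(tr2$pe, tr$pe, tolerance = 1e-12)
})
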