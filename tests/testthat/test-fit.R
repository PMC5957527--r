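spec2w <- model_spec("value_2w")

test_that("latent transforms have the expected fixed points and invert", {
  ap <- transform_params(rep(0, 6), spec2w)
  expect_equal(ap$kappa, 0.5)
  expect_equal(ap$eta, 0.5)
  expect_equal(ap$beta, 1)
  expect_equal(ap$bias, 0)
  expect_equal(ap$sigma_a, 1)
  expect_equal(ap$sigma_n, 1)

  for (seed in 1:10) {
    set.seed(seed)
    latent <- rnorm(6, 0, 2)
    back <- inverse_transform_params(transform_params(latent, spec2w), spec2w)
    expect_equal(unname(back), latent, tolerance = 1e-12)
  }

  # extreme latents stay inside the open interval (no underflow to 0)
  expect_gt(transform_params(c(-40, 0, 0, 0, 0, 0), spec2w)$kappa, 0)
  expect_lt(transform_params(c(40, 0, 0, 0, 0, 0), spec2w)$kappa, 1)
  expect_error(
    inverse_transform_params(
      structure(list(kappa = 1, eta = 0.5, beta = 1, bias = 0,
                     sigma_a = 1, sigma_n = 1), class = "agent_params"),
      spec2w),
    "boundary")
})

test_that("prior specification validates and recycles", {
  pr <- prior_spec(spec2w)
  expect_equal(nrow(pr), 6)
  expect_true(all(pr$var == 3))
  expect_equal(pr$transform[pr$parameter == "bias"], "identity")
  expect_error(prior_spec(spec2w, var = 0), "positive")
})

sim_subject <- function(seed, spec = spec2w,
                        ap = agent_params(0.5, 0.3, 5, 0.4,
                                          sigma_a = 0.75, sigma_n = 0.03)) {
  d <- build_design()
  sq <- generate_sequence(d, seed = seed)
  list(design = d,
       session = simulate_agent(ap, spec, sq, d, seed = seed + 1e4)$session)
}

test_that("subject MAP fit finds informative optima with sane evidence", {
  sx <- sim_subject(101)
  post <- fit_subject(sx$session, spec2w, sx$design, seed = 5)
  # Laplace evidence never exceeds the joint density at the optimum
  # when the Hessian is sharper than the 2*pi^d ball
  d <- length(post$latent_mean)
  joint <- post$logLik +
    sum(dnorm(post$latent_mean, 0, sqrt(3), log = TRUE))
  logdetH <- -determinant(post$latent_cov)$modulus[1]
  expect_equal(post$free_energy,
               joint - 0.5 * logdetH + d / 2 * log(2 * pi),
               tolerance = 1e-6)
  # posterior covariance is symmetric positive definite
  expect_equal(post$latent_cov, t(post$latent_cov), tolerance = 1e-8)
  expect_true(all(eigen(post$latent_cov, only.values = TRUE)$values > 0))
  # fitted bias should land near the generating value for 190 trials
  expect_lt(abs(post$params$bias - 0.4), 0.25)
})

test_that("uninformative data returns the prior for beta", {
  d <- build_design()
  sq <- generate_sequence(d, seed = 55)
  sess <- sq
  set.seed(99)
  sess$avoided <- rbinom(nrow(sq), 1, 0.5)
  sess$outcome <- ifelse(sess$avoided == 1, 0,
                         ifelse(sess$scheduled_outcome == "aversive", -1, 0))
  post <- fit_subject(sess, model_spec("perceptual"), d, seed = 1)
  i <- which(names(post$latent_mean) == "beta")
  # KL( posterior || prior ) for the beta marginal stays small
  m <- post$latent_mean[[i]]; v <- post$param_vars[[i]]
  kl <- 0.5 * (v / 3 + m^2 / 3 - 1 + log(3 / v))
  expect_lt(kl, 0.5)
})

test_that("population refinement equals independent fits at tol = Inf", {
  sessions <- lapply(201:204, function(s) sim_subject(s)$session)
  d <- build_design()
  gf <- fit_population(sessions, spec2w, d, tol = Inf, max_iter = 5,
                       seed = 3)
  expect_equal(length(gf$f_log), 1)
  indep <- lapply(seq_along(sessions), function(s)
    fit_subject(sessions[[s]], spec2w, d, seed = 3 + 1000L + s))
  expect_equal(vapply(gf$posteriors, `[[`, numeric(1), "free_energy"),
               vapply(indep, `[[`, numeric(1), "free_energy"),
               tolerance = 1e-8)
  expect_equal(gf$initial_free_energy,
               vapply(indep, `[[`, numeric(1), "free_energy"),
               tolerance = 1e-8)
})

test_that("refinement monotonically improves the summed free energy", {
  sessions <- lapply(301:312, function(s) sim_subject(s)$session)
  gf <- fit_population(sessions, spec2w, build_design(), max_iter = 6,
                       seed = 11)
  expect_true(all(diff(gf$f_log) > -1e-3 * abs(gf$f_log[-length(gf$f_log)])))
  td <- tidy(gf)
  expect_setequal(unique(td$parameter), spec2w$free_parameter_names)
  expect_true(all(td$precision > 0))
})

test_that("predictive accuracy counts classified choices, ties incorrect", {
  d <- build_design()
  sq <- generate_sequence(d, seed = 77)[1:10, ]
  sess <- sq
  sess$avoided <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L)
  sess$outcome <- ifelse(sess$avoided == 1, 0,
                         ifelse(sess$scheduled_outcome == "aversive", -1, 0))
  spec <- model_spec("perceptual")
  post <- list(params = agent_params(0.5, 0.3, 5, -0.5),
               n_trials = nrow(sess))
  # manual count against the model's stated probabilities
  tr <- rl_loglik(post$params, spec, sess, d, trace = TRUE)$trace
  manual <- mean(ifelse(tr$p_avoid == 0.5, FALSE,
                        (tr$p_avoid > 0.5) == (sess$avoided == 1)))
  expect_equal(predictive_accuracy(post, sess, spec, d), manual)

  # beta = 0 gives exactly 0.5 probability: every trial counts incorrect
  post0 <- list(params = agent_params(0.5, 0.3, 0, 0), n_trials = nrow(sess))
  expect_equal(predictive_accuracy(post0, sess, spec, d), 0)
})

test_that("the Bayesian p value compares evidence against random choice", {
  mk <- function(f, n) structure(list(free_energy = f, n_trials = n),
                                 class = "subject_posterior")
  expect_equal(bayes_p_random(mk(190 * log(0.5), 190)), 0.5)
  expect_equal(bayes_p_random(mk(100 * log(0.5) + log(99), 100)), 0.01,
               tolerance = 1e-12)
  expect_lt(bayes_p_random(mk(-50, 190)), 1e-20)
})
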