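hand_session <- function() {
  d <- build_design()
  # 6 hand-specified trials with known choices
  tibble::tibble(
    block = 1L, trial = 1:6,
    stimulus = c("CSplus1", "CSplus1", "CSminus", "GS1lo", "GS1hi", "CSplus2"),
    role = c("CS_PLUS", "CS_PLUS", "CS_MINUS", "GS", "GS", "CS_PLUS"),
    rho = d$stimuli$rho[match(stimulus, d$stimuli$label)],
    scheduled_outcome = "neutral",
    avoided = c(1L, 0L, 0L, 1L, 0L, 1L),
    outcome = 0)
}

test_that("avoidance summary reproduces hand counts and z-scores roles", {
  d <- build_design()
  sm <- avoidance_summary(hand_session(), d)
  expect_equal(sm$by_role$prop_avoid[sm$by_role$role == "CS_PLUS"], 2 / 3)
  expect_equal(sm$by_role$prop_avoid[sm$by_role$role == "CS_MINUS"], 0)
  expect_equal(sm$by_role$prop_avoid[sm$by_role$role == "GS"], 1 / 2)
  expect_equal(mean(sm$by_role$z), 0)
  expect_equal(sm$by_role$z,
               as.numeric(scale(sm$by_role$prop_avoid)))
  # degenerate equal proportions give zero z, not NaN
  s2 <- hand_session()
  s2$avoided <- 1L
  sm2 <- avoidance_summary(s2, d)
  expect_equal(sm2$by_role$z, rep(0, 3))
  s3 <- hand_session()[1:3, ]
  expect_error(avoidance_summary(s3, d), "GS")
})

test_that("peak-shift index is the far-minus-near GS contrast", {
  d <- build_design()  # CS- at 0.40
  sm <- avoidance_summary(hand_session(), d)
  # GS1lo (rho .179) is far from the CS-, GS1hi (.321) near;
  # CSplus2 has no GS trials in this fixture -> error
  expect_error(peak_shift_index(sm, d), "Missing GS")

  # build a balanced session with known GS proportions
  sess <- dplyr::bind_rows(lapply(1:10, function(i) {
    s <- tibble::tibble(
      block = 1L, trial = 1:7,
      stimulus = d$stimuli$label, role = d$stimuli$role,
      rho = d$stimuli$rho, scheduled_outcome = "neutral",
      avoided = 0L, outcome = 0)
    # far GSs avoided 5/10, near GSs 3/10
    s$avoided[s$stimulus %in% c("GS1lo", "GS2hi")] <- as.integer(i <= 5)
    s$avoided[s$stimulus %in% c("GS1hi", "GS2lo")] <- as.integer(i <= 3)
    s
  }))
  expect_equal(peak_shift_index(sess, d), 0.2)
  # symmetric avoidance gives exactly zero
  sess0 <- sess
  sess0$avoided[sess0$role == "GS"] <- 0L
  expect_equal(peak_shift_index(sess0, d), 0)
})

test_that("near/far GS labelling follows the CS- under axis flips", {
  d <- build_design(axis_flipped = TRUE)
  sess <- dplyr::bind_rows(lapply(1:10, function(i) {
    s <- tibble::tibble(
      block = 1L, trial = 1:7,
      stimulus = d$stimuli$label, role = d$stimuli$role,
      rho = d$stimuli$rho, scheduled_outcome = "neutral",
      avoided = 0L, outcome = 0)
    s$avoided[s$stimulus %in% c("GS1lo", "GS2hi")] <- as.integer(i <= 5)
    s$avoided[s$stimulus %in% c("GS1hi", "GS2lo")] <- as.integer(i <= 3)
    s
  }))
  # same labels as unflipped design still give +0.2: distances flipped too
  expect_equal(peak_shift_index(sess, d), 0.2)
})

test_that("QC filter applies its rules sequentially with stated reasons", {
  d <- build_design()
  mk <- function(id, p_avoid_csp) {
    sq <- generate_sequence(d, seed = match(id, sprintf("P%02d", 1:10)))
    sq$avoided <- 0L
    csp <- which(sq$role == "CS_PLUS")
    sq$avoided[csp[seq_len(round(p_avoid_csp * length(csp)))]] <- 1L
    sq$outcome <- 0
    sq$subject_id <- id
    sq
  }
  ids <- sprintf("P%02d", 1:10)
  props <- c(0.49, 0.30, 0.45, rep(0.8, 7))
  sessions <- dplyr::bind_rows(purrr::map2(ids, props, mk))
  # 3 below threshold; one catch failure among the survivors
  res <- qc_filter(sessions, catch_failed = c("P05", "P01"))
  expect_setequal(res$excluded$subject_id, c("P01", "P02", "P03", "P05"))
  expect_equal(res$excluded$reason[res$excluded$subject_id == "P01"],
               "low CS+ avoidance")  # rule 1 wins over rule 2
  expect_equal(res$excluded$reason[res$excluded$subject_id == "P05"],
               "catch item failure")
  expect_equal(length(unique(res$kept$subject_id)), 6)

  # exactly 50% is kept: the rule is strictly "less than"
  boundary <- dplyr::bind_rows(mk("P01", 0.5), mk("P02", 0.49))
  res2 <- qc_filter(boundary)
  expect_setequal(unique(res2$kept$subject_id), "P01")
})

test_that("Nyholt effective number matches its analytic anchors", {
  expect_equal(nyholt_meff(diag(6))$m_eff, 6)
  ones <- matrix(1, 6, 6)
  expect_equal(nyholt_meff(ones)$m_eff, 1, tolerance = 1e-10)
  expect_equal(nyholt_meff(diag(5), alpha = 0.05)$corrected_alpha, 0.01)
  # monotone decline as uniform correlation rises
  m_eff_r <- vapply(seq(0, 0.95, by = 0.05), function(r) {
    m <- matrix(r, 6, 6); diag(m) <- 1
    nyholt_meff(m)$m_eff
  }, numeric(1))
  expect_true(all(diff(m_eff_r) < 0))
  expect_error(nyholt_meff(matrix(c(1, .5, .4, 1), 2, 2)), "symmetric")
  expect_error(nyholt_meff(matrix(c(2, .5, .5, 1), 2, 2)), "unit diagonal")
})

test_that("precision weights reproduce OLS and duplication oracles", {
  set.seed(31)
  df <- tibble::tibble(x = rnorm(40), z = rnorm(40))
  df$y <- 1 + 0.5 * df$x - 0.2 * df$z + rnorm(40, 0, 0.3)

  eq <- precision_weighted_regression(df, y ~ x + z, rep(2.5, 40))
  ols <- lm(y ~ x + z, data = df)
  expect_equal(coef(eq), coef(ols), tolerance = 1e-10)

  # doubling one observation's weight equals duplicating the row
  w <- rep(1, 40); w[7] <- 2
  fit_w <- precision_weighted_regression(df, y ~ x + z, w)
  fit_d <- lm(y ~ x + z, data = df[c(1:40, 7), ])
  expect_equal(coef(fit_w), coef(fit_d), tolerance = 1e-10)

  expect_error(
    precision_weighted_regression(dplyr::mutate(df, x2 = x), y ~ x + x2,
                                  rep(1, 40)),
    "Singular|rank")
  expect_error(precision_weighted_regression(df, y ~ x, rep(-1, 40)),
               "positive")
})

test_that("weighted regression is calibrated under heteroscedastic noise", {
  hits <- vapply(1:100, function(i) {
    set.seed(4000 + i)
    n <- 482
    x <- rnorm(n)
    sd_i <- runif(n, 0.5, 2)
    df <- tibble::tibble(x = x, y = 0.05 * x + rnorm(n, 0, sd_i))
    fit <- tidy(precision_weighted_regression(df, y ~ x, 1 / sd_i^2))
    abs(fit$estimate[2] - 0.05) <= 2 * fit$std.error[2]
  }, logical(1))
  expect_gte(sum(hits), 93)
})
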