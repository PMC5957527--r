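mk_means <- function(p = 24, delta = 0, conds = c("A", "B")) {
  m <- matrix(0, length(conds), p, dimnames = list(conds, NULL))
  if (delta != 0) m["B", ] <- delta
  m
}

test_that("pattern datasets validate their structure", {
  e <- lapply(1:3, function(r) mk_means(10))
  ds <- pattern_dataset(e)
  expect_equal(ds$n_voxels, 10)
  bad <- e
  rownames(bad[[2]]) <- c("A", "C")
  expect_error(pattern_dataset(bad), "same conditions")
  expect_error(pattern_dataset(e[1]), "2 runs")
})

test_that("noise normalisation whitens residuals", {
  set.seed(5)
  p <- 12
  # correlated noise via a random mixing matrix
  mix <- matrix(rnorm(p * p, 0, 0.4), p, p) + diag(p)
  est <- lapply(1:3, function(r)
    mk_means(p) + matrix(rnorm(2 * p), 2, p) %*% mix)
  res <- lapply(1:3, function(r) matrix(rnorm(500 * p), 500, p) %*% mix)
  ds <- pattern_dataset(est, residuals = res)

  # identity residual covariance with zero shrinkage leaves data intact
  iso <- pattern_dataset(est, residuals = lapply(1:3, function(r)
    matrix(rnorm(400 * p), 400, p)))
  iso_w <- noise_normalize(iso, shrinkage = 0)
  expect_equal(iso_w$estimates[[1]], iso$estimates[[1]], tolerance = 0.2)

  # full shrinkage reduces to per-voxel scaling by the residual SD
  full <- noise_normalize(ds, shrinkage = 1)
  sds <- apply(ds$residuals[[1]], 2, sd)
  expect_equal(full$estimates[[1]],
               sweep(ds$estimates[[1]], 2, sds, "/"), tolerance = 1e-10)

  # whitened residual covariance approaches the identity
  w <- noise_normalize(ds)
  cw <- cov(w$residuals[[1]])
  expect_lt(norm(cw - diag(p), "F") / p, 0.1)
})

test_that("crossnobis distance has an unbiased zero point", {
  vals <- vapply(1:200, function(i) {
    ds <- generate_patterns(mk_means(), noise_sd = 1, seed = 6000 + i)
    cv_ldc(ds, c("A", "B"))$value
  }, numeric(1))
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * mc_se + 1e-12)
})

test_that("noiseless distances equal the squared separation per voxel", {
  for (delta in c(0.1, 0.3, 0.7)) {
    ds <- generate_patterns(mk_means(delta = delta), noise_sd = 0, seed = 1)
    expect_equal(cv_ldc(ds, c("A", "B"))$value, delta^2, tolerance = 1e-12)
    # symmetric in pair order
    expect_equal(cv_ldc(ds, c("B", "A"))$value,
                 cv_ldc(ds, c("A", "B"))$value)
  }
  # quadratic scaling: slope 2 on log-log
  deltas <- seq(0.1, 0.8, length.out = 6)
  v <- vapply(deltas, function(d)
    cv_ldc(generate_patterns(mk_means(delta = d), noise_sd = 0, seed = 1),
           c("A", "B"))$value, numeric(1))
  slope <- coef(lm(log(v) ~ log(deltas)))[2]
  expect_equal(unname(slope), 2, tolerance = 1e-8)
})

test_that("distances ignore a pattern common to both conditions", {
  set.seed(77)
  p <- 24
  common <- rnorm(p)
  base <- mk_means(p, delta = 0.4)
  shifted <- base + rep(1, 2) %o% common
  d1 <- cv_ldc(generate_patterns(base, noise_sd = 0.5, seed = 3),
               c("A", "B"))$value
  d2 <- cv_ldc(generate_patterns(shifted, noise_sd = 0.5, seed = 3),
               c("A", "B"))$value
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("distance change contrasts late against early runs", {
  # late separation halved: change = (0.25 - 1) * delta^2 (noiseless)
  delta <- 0.6
  ds <- generate_patterns(list(early = mk_means(delta = delta),
                               late = mk_means(delta = delta / 2)),
                          noise_sd = 0, seed = 2)
  ch <- distance_change(ds, c("A", "B"),
                        early_runs = 1:2, late_runs = 3:5)
  expect_equal(ch, (0.25 - 1) * delta^2, tolerance = 1e-10)
  # swapping the epochs flips the sign
  expect_equal(distance_change(ds, c("A", "B"),
                               early_runs = 3:4, late_runs = 1:2),
               -distance_change(ds, c("A", "B"),
                                early_runs = 1:2, late_runs = 3:4),
               tolerance = 1e-10)
  expect_error(distance_change(ds, c("A", "B"), early_runs = 1:2,
                               late_runs = 2:4), "disjoint")
  # stationary patterns: change fluctuates around zero
  chs <- vapply(1:200, function(i)
    distance_change(generate_patterns(mk_means(), noise_sd = 1,
                                      seed = 7000 + i), c("A", "B")),
    numeric(1))
  expect_lt(abs(mean(chs)), 2 * sd(chs) / sqrt(length(chs)) + 1e-12)
})
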