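#' Assemble a multivariate pattern dataset
#'
#' Holds per-run condition pattern estimates (e.g. beta images from a
#' categorical GLM restricted to a region) together with residual time
#' series used to estimate the noise covariance for multivariate noise
#' normalisation.
#'
#' @param estimates A list (one element per run) of condition x voxel
#'   matrices with condition row names, or a 3-d array run x condition
#'   x voxel.
#' @param residuals A list (one per run) of time x voxel residual
#'   matrices; optional (required for [noise_normalize()]).
#' @param runs Run labels (default `seq_along(estimates)`).
#' @return A `pattern_dataset`.
#' @export
pattern_dataset <- function(estimates, residuals = NULL, runs = NULL) {
  if (is.array(estimates) && length(dim(estimates)) == 3) {
    estimates <- lapply(seq_len(dim(estimates)[1]), function(r)
      estimates[r, , , drop = TRUE])
  }
  if (length(estimates) < 2) abort("Need at least 2 runs.")
  conds <- rownames(estimates[[1]])
  if (is.null(conds)) abort("Condition labels (row names) are required.")
  p <- ncol(estimates[[1]])
  for (e in estimates) {
    if (!identical(rownames(e), conds) || ncol(e) != p) {
      abort("Every run must contain the same conditions and voxel count.")
    }
  }
  if (!is.null(residuals)) {
    if (length(residuals) != length(estimates)) {
      abort("`residuals` must have one matrix per run.")
    }
    for (r in residuals) {
      if (ncol(r) != p) abort("Residual voxel count must match the estimates.")
    }
  }
  structure(list(estimates = estimates, residuals = residuals,
                 conditions = conds,
                 runs = runs %||% seq_along(estimates),
                 n_voxels = p),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("<pattern_dataset>", length(x$estimates), "runs x",
      length(x$conditions), "conditions x", x$n_voxels, "voxels",
      if (is.null(x$residuals)) "(no residuals)" else "", "\n")
  invisible(x)
}

# analytic shrinkage intensity toward the diagonal target
# (Ledoit-Wolf-type estimate from the residual sample)
shrinkage_intensity <- function(resid) {
  n <- nrow(resid)
  x <- scale(resid, center = TRUE, scale = FALSE)
  s <- crossprod(x) / (n - 1)
  # var of each covariance entry
  v <- matrix(0, ncol(x), ncol(x))
  for (t in seq_len(n)) {
    v <- v + (tcrossprod(x[t, ]) - s)^2
  }
  v <- v / (n * (n - 1))
  off <- upper.tri(s)
  num <- sum(v[off])
  den <- sum(s[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Multivariate noise normalisation of pattern estimates
#'
#' Estimates the per-run noise covariance from the residuals, shrinks
#' it toward its diagonal and whitens the patterns by the inverse
#' matrix square root, so voxel noise becomes approximately isotropic
#' and Euclidean inner products approximate Mahalanobis ones.
#'
#' @param dataset A [pattern_dataset()] with residuals.
#' @param shrinkage Shrinkage coefficient in `[0, 1]` toward the
#'   diagonal target; `NULL` (default) uses an analytic optimal
#'   estimate. When residual samples number fewer than a tenth of the
#'   voxels, the coefficient is floored at 0.5.
#' @return A whitened `pattern_dataset` (residuals whitened too).
#' @export
noise_normalize <- function(dataset, shrinkage = NULL) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  if (is.null(dataset$residuals)) {
    abort("Noise normalisation requires residuals.")
  }
  est <- dataset$estimates
  res <- dataset$residuals
  p <- dataset$n_voxels
  for (r in seq_along(est)) {
    lam <- shrinkage %||% shrinkage_intensity(res[[r]])
    if (nrow(res[[r]]) < p / 10) lam <- max(lam, 0.5)
    s <- stats::cov(res[[r]])
    s <- (1 - lam) * s + lam * diag(diag(s), p)
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) <= 1e-12 * max(e$values)) {
      abort("Shrunk noise covariance is singular; increase `shrinkage`.")
    }
    w <- e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors)
    est[[r]] <- est[[r]] %*% w
    res[[r]] <- res[[r]] %*% w
  }
  out <- dataset
  out$estimates <- est
  out$residuals <- res
  out
}

#' Cross-validated linear discriminant contrast (crossnobis) distance
#'
#' Leave-one-run-out estimate of the squared discriminant distance
#' between two condition patterns: for each fold the pattern
#' difference from the training runs is projected onto the difference
#' in the held-out run, and the projections are averaged and divided
#' by the voxel count. Because train and test noise are independent,
#' the estimator is unbiased under identical condition distributions —
#' it has a meaningful zero and can go negative.
#'
#' @param dataset A [pattern_dataset()] (normally noise-normalised
#'   first).
#' @param pair Character vector of two condition labels.
#' @param runs Optional subset of run labels to use (>= 2).
#' @return A `distance_estimate`: `pair`, `value`, `n_folds`,
#'   `fold_values`.
#' @export
cv_ldc <- function(dataset, pair, runs = NULL) {
  stopifnot(inherits(dataset, "pattern_dataset"), length(pair) == 2)
  if (!all(pair %in% dataset$conditions)) {
    abort(paste0("Condition(s) not in dataset: ",
                 paste(setdiff(pair, dataset$conditions), collapse = ", ")))
  }
  use <- if (is.null(runs)) seq_along(dataset$runs) else
    match(runs, dataset$runs)
  if (anyNA(use)) abort("Unknown run label.")
  if (length(use) < 2) abort("Cross-validation needs at least 2 runs.")
  p <- dataset$n_voxels

  deltas <- lapply(dataset$estimates[use], function(e)
    e[pair[1], ] - e[pair[2], ])
  folds <- vapply(seq_along(deltas), function(k) {
    train <- Reduce(`+`, deltas[-k]) / (length(deltas) - 1)
    sum(train * deltas[[k]]) / p
  }, numeric(1))

  structure(list(pair = sort(pair), value = mean(folds),
                 n_folds = length(folds), fold_values = folds),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat("<distance_estimate>", paste(x$pair, collapse = " vs "), "=",
      signif(x$value, 5), "over", x$n_folds, "folds\n")
  invisible(x)
}

#' Early-vs-late change in representational distance
#'
#' Difference between the crossnobis distance restricted to late runs
#' and to early runs. Negative values mean the two conditions became
#' more similar over the task (e.g. GS representations converging on
#' the CS+), matching the sign convention used when regressing
#' distance change on generalization parameters.
#'
#' @param dataset A [pattern_dataset()].
#' @param pair Two condition labels.
#' @param early_runs,late_runs Disjoint run-label sets, each with at
#'   least 2 runs (defaults: runs 1-2 vs 3-5).
#' @return The change score (late minus early).
#' @export
distance_change <- function(dataset, pair,
                            early_runs = dataset$runs[1:2],
                            late_runs = dataset$runs[-(1:2)]) {
  if (length(intersect(early_runs, late_runs))) {
    abort("Early and late run sets must be disjoint.")
  }
  late <- cv_ldc(dataset, pair, runs = late_runs)$value
  early <- cv_ldc(dataset, pair, runs = early_runs)$value
  late - early
}
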