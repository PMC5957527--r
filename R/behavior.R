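#' Summarise avoidance behaviour by stimulus and role
#'
#' Computes avoidance proportions per stimulus and per role (CS-, GS,
#' CS+), together with the within-participant standardised (z-scored)
#' role proportions. The z values give each participant's *relative*
#' GS avoidance — how intermediate their GS responding is between
#' safety and danger — independent of overall avoidance rate. When all
#' three role proportions are equal the z values are defined as 0.
#'
#' @param session A session tibble (with `avoided`).
#' @param design [build_design()].
#' @return An `avoidance_summary`: list with `by_role` and
#'   `by_stimulus` tibbles.
#' @export
avoidance_summary <- function(session, design) {
  if (nrow(session) == 0) abort("Session is empty.")
  roles <- c("CS_MINUS", "GS", "CS_PLUS")
  missing <- setdiff(roles, unique(session$role))
  if (length(missing)) {
    abort(paste0("No trials for role(s): ", paste(missing, collapse = ", ")))
  }
  by_stim <- session |>
    dplyr::group_by(.data$stimulus, .data$role) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     prop_avoid = mean(.data$avoided == 1),
                     .groups = "drop")
  by_role <- session |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     prop_avoid = mean(.data$avoided == 1),
                     .groups = "drop")
  by_role <- by_role[match(roles, by_role$role), ]
  s <- sd(by_role$prop_avoid)
  by_role$z <- if (s == 0) rep(0, 3) else
    (by_role$prop_avoid - mean(by_role$prop_avoid)) / s

  structure(list(by_role = by_role, by_stimulus = by_stim),
            class = "avoidance_summary")
}

#' @export
print.avoidance_summary <- function(x, ...) {
  cat("<avoidance_summary>\n")
  print(x$by_role)
  invisible(x)
}

#' Peak-shift asymmetry index
#'
#' For each CS+, compares avoidance of its two flanking GS: the one on
#' the far side of the CS- in rho space minus the one on the near
#' side. Positive values mean responding is displaced away from the
#' CS- — the classic peak-shift signature, which only arises when
#' value generalization interacts with the safety gradient around the
#' CS-. Near/far labels are derived from rho distances to the CS-, so
#' they follow axis counterbalancing automatically.
#'
#' @param summary An [avoidance_summary()] (or a session tibble, which
#'   is summarised first).
#' @param design [build_design()].
#' @return A single asymmetry score.
#' @export
peak_shift_index <- function(summary, design) {
  if (!inherits(summary, "avoidance_summary")) {
    summary <- avoidance_summary(summary, design)
  }
  stim <- design$stimuli
  cs_minus_rho <- stim$rho[stim$role == "CS_MINUS"]
  by_stim <- summary$by_stimulus

  diffs <- vapply(stim$label[stim$role == "CS_PLUS"], function(cs) {
    gs <- stim[stim$role == "GS" & stim$adjacent_cs_plus == cs, ]
    if (nrow(gs) != 2) abort(paste0("CS+ `", cs, "` lacks its two GS."))
    gs <- gs[order(abs(gs$rho - cs_minus_rho)), ]  # near first
    props <- by_stim$prop_avoid[match(gs$label, by_stim$stimulus)]
    if (anyNA(props)) abort(paste0("Missing GS trials for CS+ `", cs, "`."))
    props[2] - props[1]                            # far - near
  }, numeric(1))
  mean(diffs)
}

#' Quality-control filter for behavioural sessions
#'
#' Applies the exclusion rules sequentially: first subjects whose CS+
#' avoidance proportion is strictly below `cs_plus_avoid_min`
#' (inattentive or shock-insensitive responders; exactly at the
#' threshold is kept), then — among the survivors — subjects flagged
#' as having failed catch items.
#'
#' @param sessions A tibble of trials for all subjects, with a
#'   `subject_id` column, or a named list of session tibbles.
#' @param cs_plus_avoid_min Minimum CS+ avoidance proportion (default
#'   0.5).
#' @param catch_failed Optional character vector (or named logical) of
#'   subjects who failed catch items.
#' @return A list with `kept` (trial tibble of retained subjects) and
#'   `excluded` (tibble of `subject_id`, `reason`).
#' @export
qc_filter <- function(sessions, cs_plus_avoid_min = 0.5,
                      catch_failed = character(0)) {
  if (is.list(sessions) && !is.data.frame(sessions)) {
    sessions <- dplyr::bind_rows(sessions, .id = "subject_id")
  }
  stopifnot("subject_id" %in% names(sessions))
  if (is.logical(catch_failed)) {
    catch_failed <- names(catch_failed)[catch_failed]
  }

  csp <- sessions |>
    dplyr::filter(.data$role == "CS_PLUS") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(p = mean(.data$avoided == 1), .groups = "drop")
  low <- csp$subject_id[csp$p < cs_plus_avoid_min]

  remaining <- setdiff(unique(sessions$subject_id), low)
  caught <- intersect(remaining, catch_failed)

  excluded <- dplyr::bind_rows(
    tibble::tibble(subject_id = low, reason = "low CS+ avoidance"),
    tibble::tibble(subject_id = caught, reason = "catch item failure")
  )
  list(kept = sessions[!sessions$subject_id %in% excluded$subject_id, ],
       excluded = excluded)
}

#' Effective number of independent variables (Nyholt correction)
#'
#' Modified Bonferroni correction for correlated measures: from the
#' eigenvalues of their correlation matrix,
#' `m_eff = 1 + (M - 1) * (1 - Var(lambda) / M)` (sample variance with
#' the `M - 1` denominator). Independent measures give `m_eff = M`,
#' perfectly correlated ones `m_eff = 1`.
#'
#' @param correlation_matrix Symmetric correlation matrix with unit
#'   diagonal.
#' @param alpha Nominal significance level to correct (default 0.05).
#' @return A `nyholt_result`: `eigenvalues`, `m_eff`,
#'   `corrected_alpha`.
#' @export
#' @examples
#' nyholt_meff(diag(6))
nyholt_meff <- function(correlation_matrix, alpha = 0.05) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("Correlation matrix must be symmetric.")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    abort("Correlation matrix must have a unit diagonal.")
  }
  lambda <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-8) {
    abort("Correlation matrix is not positive semi-definite.")
  }
  M <- nrow(m)
  v <- if (M > 1) var(lambda) else 0
  m_eff <- 1 + (M - 1) * (1 - v / M)
  structure(list(eigenvalues = lambda, m_eff = m_eff,
                 corrected_alpha = alpha / m_eff, alpha = alpha),
            class = "nyholt_result")
}

#' @export
print.nyholt_result <- function(x, ...) {
  cat("<nyholt_result> m_eff =", signif(x$m_eff, 4),
      "-> corrected alpha =", signif(x$corrected_alpha, 4), "\n")
  invisible(x)
}

#' Precision-weighted least-squares regression
#'
#' Weighted linear regression with weights equal to the precision of
#' the outcome estimates (1 / posterior variance), the maximum-
#' likelihood estimator when measurement noise differs across
#' subjects. This is how posterior parameter estimates (for example
#' generalization widths) are related to subject-level covariates such
#' as symptom scores.
#'
#' @param data A data frame of subject-level variables.
#' @param formula Model formula.
#' @param precisions Positive weights, one per row (a numeric vector
#'   or the name of a column of `data`).
#' @return A `pw_lm` object (an `lm` with the weights recorded);
#'   `tidy()` gives the coefficient table.
#' @export
precision_weighted_regression <- function(data, formula, precisions) {
  if (is.character(precisions) && length(precisions) == 1) {
    precisions <- data[[precisions]]
  }
  if (length(precisions) != nrow(data)) {
    abort("`precisions` must supply one weight per row.")
  }
  if (any(!is.finite(precisions)) || any(precisions <= 0)) {
    abort("All precisions must be finite and positive.")
  }
  data$.w <- precisions
  fit <- stats::lm(formula, data = data, weights = .w)
  if (fit$rank < length(coef(fit))) {
    abort("Singular design: predictors are rank deficient.")
  }
  class(fit) <- c("pw_lm", class(fit))
  fit
}

#' @export
tidy.pw_lm <- function(x, ...) {
  s <- summary(x)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3],
                 p.value = s[, 4])
}

#' @export
glance.pw_lm <- function(x, ...) {
  s <- summary(x)
  tibble::tibble(r.squared = s$r.squared,
                 adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma,
                 df.residual = x$df.residual,
                 nobs = length(x$residuals))
}
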