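#' Plot an avoidance generalization gradient
#'
#' Per-stimulus avoidance proportions arranged along the rho axis,
#' coloured by role, for one summarised session or a cohort of them.
#'
#' @param summary An [avoidance_summary()] or a list of them.
#' @param design [build_design()].
#' @return A ggplot object.
#' @export
plot_gradient <- function(summary, design) {
  if (inherits(summary, "avoidance_summary")) summary <- list(summary)
  df <- purrr::imap_dfr(summary, function(s, i) {
    out <- s$by_stimulus
    out$subject <- i
    out
  })
  df <- dplyr::left_join(df, design$stimuli[, c("label", "rho")],
                         by = c("stimulus" = "label"))
  agg <- df |>
    dplyr::group_by(.data$stimulus, .data$role, .data$rho) |>
    dplyr::summarise(prop_avoid = mean(.data$prop_avoid), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$rho, .data$prop_avoid,
                                    colour = .data$role)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "shape spikiness (rho)",
                  y = "avoidance proportion", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(
    delta_rho = seq(0, max(object$data$delta_rho) * 1.2, length.out = 200))
  grid$p <- psychometric_prob(object$alpha, object$beta, object$lapse,
                              grid$delta_rho)
  obs <- object$data
  obs$p <- obs$n_different / obs$n_trials
  ggplot2::ggplot(grid, ggplot2::aes(.data$delta_rho, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(size = .data$n_trials),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 3) +
    ggplot2::geom_vline(xintercept = threshold(object, 0.75), linetype = 3) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "rho difference", y = "P(different)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("expected_frequency", "exceedance_probability"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "posterior-mean estimate", y = "subjects") +
    ggplot2::theme_minimal()
}

#' Plot a per-trial latent trace
#'
#' Predicted shock probability, prediction error and associability
#' over trials for one session.
#'
#' @param trace A trace tibble from [rl_loglik()] or
#'   [simulate_agent()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  df <- trace |>
    dplyr::select("trial", "p_shock", "pe", "alpha") |>
    tidyr::pivot_longer(-"trial", names_to = "quantity",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal()
}
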