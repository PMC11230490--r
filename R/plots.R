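#' Plot group choice proportions by uncertainty level
#'
#' Bar-and-dot display of the lottery-choice proportion at each risk level
#' and the corrected choice proportion at each ambiguity level, per domain
#' (rows) - the standard group-level view of risk and ambiguity attitudes.
#'
#' @param modelfree Output of [model_free_summary()].
#' @param phase Phase to display (default 1).
#' @return A ggplot object.
#' @export
plot_choice_proportions <- function(modelfree, phase = 1) {
  df <- dplyr::filter(modelfree, .data$phase == !!phase)
  long <- tidyr::pivot_longer(
    df, dplyr::matches("^(prop_risk|corrected_amb)_"),
    names_to = "cell", values_to = "value")
  long$panel <- ifelse(grepl("^prop_risk", long$cell),
                       "risk (choice proportion)",
                       "ambiguity (corrected proportion)")
  long$level <- paste0(sub(".*_", "", long$cell), "%")
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$domain, .data$panel, .data$level),
    m = mean(.data$value, na.rm = TRUE),
    se = stats::sd(.data$value, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$value))),
    .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$level, y = .data$m)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           width = 0.2) +
    ggplot2::geom_jitter(data = long,
                         ggplot2::aes(y = .data$value), width = 0.15,
                         alpha = 0.25, size = 0.6, na.rm = TRUE) +
    ggplot2::facet_grid(domain ~ panel, scales = "free") +
    ggplot2::labs(x = "uncertainty level", y = "proportion",
                  title = paste0("Choice behavior by uncertainty level (phase ",
                                 phase, ")")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an attitude measure across domains or phases
#'
#' @param consistency Output of [run_consistency_suite()] (used for the
#'   annotation) or `NULL`.
#' @param modelfree Output of [model_free_summary()].
#' @param measure `"risk_attitude"` or `"ambiguity_attitude"`.
#' @param axis `"cross_domain"` (monetary vs medical within phase 1) or
#'   `"cross_phase"` (phase 1 vs 2 within the monetary domain).
#' @return A ggplot object.
#' @export
plot_consistency <- function(modelfree, measure = "risk_attitude",
                             axis = c("cross_domain", "cross_phase"),
                             consistency = NULL) {
  axis <- match.arg(axis)
  if (axis == "cross_domain") {
    d <- dplyr::filter(modelfree, .data$phase == 1L)
    pr <- pair_measure(d, measure, "domain", "monetary", "medical",
                       "participant_id")
    labs <- c("monetary", "medical")
  } else {
    d <- dplyr::filter(modelfree, .data$domain == "monetary")
    pr <- pair_measure(d, measure, "phase", 1, 2, "participant_id")
    labs <- c("phase 1", "phase 2")
  }
  df <- tibble::tibble(x = pr$x, y = pr$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, linetype = 2,
                         na.rm = TRUE) +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = paste(measure, "-", axis)) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a single participant fit
#'
#' Observed lottery-choice rates per uncertainty level against the model's
#' predicted choice probabilities.
#'
#' @param object An `ordival_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ordival_fit
#' @export
autoplot.ordival_fit <- function(object, ...) {
  tr <- object$trials
  p <- predict_choice_probability(tr, object$alpha_hat, object$beta_hat,
                                  object$gamma_hat, object$variant,
                                  object$ratings)
  df <- tibble::tibble(
    level = ifelse(tr$uncertainty_type == "risk",
                   paste0("risk ", tr$win_probability * 100, "%"),
                   paste0("amb ", tr$ambiguity_level * 100, "%")),
    observed = as.numeric(object$chose_lottery), predicted = p)
  m <- dplyr::summarise(dplyr::group_by(df, .data$level),
                        observed = mean(.data$observed),
                        predicted = mean(.data$predicted), .groups = "drop")
  long <- tidyr::pivot_longer(m, c("observed", "predicted"),
                              names_to = "source", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$rate,
                                     fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "lottery-choice rate",
                  title = sprintf("fit: alpha=%.2f beta=%.2f gamma=%.2f",
                                  object$alpha_hat, object$beta_hat,
                                  object$gamma_hat)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
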