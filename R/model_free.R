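#' Lottery-choice proportions per participant, phase and domain
#'
#' Computes the fraction of trials on which the uncertain option was chosen
#' over the certain reference, grouped either by outcome level (collapsing
#' across uncertainty levels) or by uncertainty level (collapsing across
#' outcomes). Reference-equal catch trials are manipulation checks and are
#' excluded from every proportion. Empty groups yield `NA`, never zero: zero
#' is a valid attitude value.
#'
#' @param choices Choice records after exclusions.
#' @param trials Trial table.
#' @param group_by `"outcome"` or `"uncertainty_level"`.
#' @return Long tibble: `participant_id`, `phase`, `domain`,
#'   `uncertainty_type` (for uncertainty grouping), `level`, `n_trials`,
#'   `n_lottery`, `proportion`.
#' @export
choice_proportions <- function(choices, trials,
                               group_by = c("uncertainty_level", "outcome")) {
  group_by <- match.arg(group_by)
  value <- dplyr::filter(trials, !.data$is_reference_equal)
  x <- dplyr::inner_join(choices, value, by = "trial_id")
  if (group_by == "outcome") {
    x <- dplyr::group_by(x, .data$participant_id, .data$phase, .data$domain,
                         level = .data$outcome_ordinal)
  } else {
    x <- dplyr::mutate(x, level = ifelse(.data$uncertainty_type == "risk",
                                         .data$win_probability,
                                         .data$ambiguity_level))
    x <- dplyr::group_by(x, .data$participant_id, .data$phase, .data$domain,
                         .data$uncertainty_type, .data$level)
  }
  dplyr::summarise(x, n_trials = dplyr::n(),
                   n_lottery = sum(.data$chose_lottery),
                   proportion = mean(.data$chose_lottery), .groups = "drop")
}

#' Add corrected ambiguity proportions to a model-free summary
#'
#' An ambiguity-neutral decision-maker treats every ambiguous lottery as a
#' 50% lottery, so ambiguity preference is isolated by subtracting the 50%-
#' risk choice proportion from the choice proportion at each ambiguity
#' level: `corrected(a) = prop_ambiguity(a) - prop_risk(0.5)`. Negative
#' values indicate ambiguity aversion. The per-participant ambiguity
#' attitude is the mean corrected proportion over the three levels. A
#' missing 50%-risk cell makes the whole correction incomputable (`NA`).
#'
#' @param summary Wide summary as built inside [model_free_summary()], with
#'   `prop_amb_24/50/74` and `prop_risk_50` columns.
#' @return `summary` with `corrected_amb_24/50/74` and `ambiguity_attitude`.
#' @export
corrected_ambiguity_proportion <- function(summary) {
  for (lv in c("24", "50", "74")) {
    summary[[paste0("corrected_amb_", lv)]] <-
      summary[[paste0("prop_amb_", lv)]] - summary$prop_risk_50
  }
  summary$ambiguity_attitude <-
    (summary$corrected_amb_24 + summary$corrected_amb_50 +
       summary$corrected_amb_74) / 3
  summary
}

#' Model-free attitude summary per participant, phase and domain
#'
#' One row per (participant, phase, domain) with choice proportions by
#' outcome level and by uncertainty level, the risk attitude (unweighted
#' mean of the three risk-level proportions; higher = more uncertainty
#' tolerant), and the 50%-risk-corrected ambiguity attitude (negative =
#' averse).
#'
#' @inheritParams choice_proportions
#' @return A wide tibble with columns `prop_outcome_2/3/4`,
#'   `prop_risk_25/50/75`, `risk_attitude`, `prop_amb_24/50/74`,
#'   `corrected_amb_24/50/74`, `ambiguity_attitude`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(4, seed = 1), build_trialset(0))
#' model_free_summary(coh$choices, build_trialset(0))
model_free_summary <- function(choices, trials) {
  lv <- choice_proportions(choices, trials, "uncertainty_level")
  lv$key <- paste0("prop_", ifelse(lv$uncertainty_type == "risk", "risk_", "amb_"),
                   round(lv$level * 100))
  wide <- tidyr::pivot_wider(
    dplyr::select(lv, "participant_id", "phase", "domain", "key", "proportion"),
    names_from = "key", values_from = "proportion")
  oc <- choice_proportions(choices, trials, "outcome")
  oc$key <- paste0("prop_outcome_", oc$level)
  wide_oc <- tidyr::pivot_wider(
    dplyr::select(oc, "participant_id", "phase", "domain", "key", "proportion"),
    names_from = "key", values_from = "proportion")
  out <- dplyr::left_join(wide, wide_oc,
                          by = c("participant_id", "phase", "domain"))
  for (col in c("prop_risk_25", "prop_risk_50", "prop_risk_75",
                "prop_amb_24", "prop_amb_50", "prop_amb_74")) {
    if (is.null(out[[col]])) out[[col]] <- NA_real_
  }
  out$risk_attitude <- (out$prop_risk_25 + out$prop_risk_50 +
                          out$prop_risk_75) / 3
  corrected_ambiguity_proportion(out)
}
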