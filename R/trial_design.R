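#' Outcome levels for a decision domain
#'
#' Each domain offers five ordered outcomes, coded by ordinal value 0-4.
#' Ordinal 0 is the null outcome (the lottery's losing side), ordinal 1 is the
#' certain reference available on every trial ($500 / "slight improvement"),
#' and ordinals 2-4 are the strictly better lottery payoffs. The ordinal code
#' is the value `V` entering the ordinal subjective-value model.
#'
#' @param domain `"monetary"` or `"medical"`.
#' @return A tibble with columns `domain`, `ordinal_value`, `label`.
#' @export
#' @examples
#' outcome_levels("medical")
outcome_levels <- function(domain = c("monetary", "medical")) {
  domain <- match.arg(domain)
  labels <- switch(domain,
    monetary = c("$0", "$500", "$800", "$1200", "$2500"),
    medical  = c("no effect", "slight improvement", "moderate improvement",
                 "major improvement", "recovery"))
  tibble::tibble(domain = domain, ordinal_value = 0:4, label = labels)
}

#' The certain reference option of a domain
#'
#' The reference is the ordinal-1 outcome, offered with certainty on every
#' trial: a fixed $500 gain in the monetary domain, a guaranteed "slight
#' improvement" in the medical domain.
#'
#' @inheritParams outcome_levels
#' @return A one-row tibble (`domain`, `ordinal_value`, `label`).
#' @export
#' @examples
#' reference_option("monetary")$label
reference_option <- function(domain = c("monetary", "medical")) {
  domain <- match.arg(domain)
  dplyr::filter(outcome_levels(domain), .data$ordinal_value == 1L)
}

# Uncertainty levels of the task: three known probabilities and three
# occluded fractions (ambiguous lotteries always have a 50% objective
# winning chance behind the occluder).
uncertainty_levels <- function() {
  tibble::tibble(
    uncertainty_type = rep(c("risk", "ambiguity"), each = 3L),
    win_probability  = c(0.25, 0.50, 0.75, 0.50, 0.50, 0.50),
    ambiguity_level  = c(0, 0, 0, 0.24, 0.50, 0.74))
}

# Fixed outcome assignment for the six extra value trials (one per
# uncertainty level). Keeping this independent of the seed makes the
# (uncertainty, outcome) composition identical across seeds; only the
# colors are randomized.
extra_value_outcomes <- function() {
  lv <- uncertainty_levels()
  lv$outcome_ordinal <- c(2L, 3L, 4L, 2L, 3L, 4L)
  lv
}

build_domain_trials <- function(domain, seed) {
  lv <- uncertainty_levels()

  # 36 fully crossed value trials: 6 uncertainty levels x 3 lottery
  # outcomes above the reference x 2 winning colors.
  crossed <- tidyr::crossing(lv, outcome_ordinal = 2:4,
                             win_color = c("red", "blue"))
  crossed$replicate <- 1L

  # 6 extra value trials (one per level, fixed outcomes, seeded colors)
  # bring the value-trial count to 42: 21 risky, 21 ambiguous.
  extra <- extra_value_outcomes()
  extra$replicate <- 2L

  # 7 reference-equal catch trials: one per uncertainty level plus a second
  # at 50% risk. Their lottery pays exactly the reference outcome.
  catch <- lv[c(seq_len(nrow(lv)), 2L), ]
  catch$outcome_ordinal <- 1L
  catch$replicate <- c(rep(1L, 6L), 2L)

  free <- dplyr::bind_rows(extra, catch)
  # Seeded color assignment for the 13 non-crossed trials, balanced so the
  # domain-wide red/blue difference is at most one (25 vs 24 of 49).
  set.seed(substream_seed(seed, paste0("colors_", domain)))
  n_free <- nrow(free)
  cols <- sample(rep(c("red", "blue"), length.out = n_free))
  free$win_color <- cols

  out <- dplyr::bind_rows(crossed, free)
  out$domain <- domain
  out$outcome_ordinal <- as.integer(out$outcome_ordinal)
  out$is_reference_equal <- out$outcome_ordinal == 1L
  out <- dplyr::left_join(out,
    dplyr::rename(outcome_levels(domain), outcome_ordinal = "ordinal_value",
                  outcome_label = "label"),
    by = c("domain", "outcome_ordinal"))
  dplyr::arrange(out, .data$uncertainty_type, .data$ambiguity_level,
                 .data$win_probability, .data$outcome_ordinal,
                 .data$win_color, .data$replicate)
}

#' Build the default two-domain trial set
#'
#' Constructs the full 98-trial task: 49 trials per domain, each pairing an
#' uncertain lottery against the domain's certain reference. Per domain the
#' set holds 42 value trials (the complete crossing of the 6 uncertainty
#' levels - 25/50/75% risk and 24/50/74% ambiguity - with the 3
#' above-reference outcomes and both winning colors, plus one fixed extra
#' value trial per level) and 7 reference-equal catch trials (one per level
#' plus a second at 50% risk). Winning colors on non-crossed trials are
#' assigned pseudo-randomly from the seed, balanced within a domain; the
#' (uncertainty, outcome) composition is identical for every seed.
#'
#' @param seed Non-negative integer; the only source of randomness (colors).
#' @return A tibble of 98 trials with columns `trial_id`, `domain`,
#'   `uncertainty_type`, `win_probability`, `ambiguity_level`,
#'   `outcome_ordinal`, `outcome_label`, `win_color`, `is_reference_equal`,
#'   `replicate`, plus attribute `seed`.
#' @export
#' @examples
#' trials <- build_trialset(seed = 0)
#' dplyr::count(trials, domain, is_reference_equal)
build_trialset <- function(seed = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  out <- dplyr::bind_rows(build_domain_trials("monetary", seed),
                          build_domain_trials("medical", seed))
  out$trial_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "trial_id", "domain", "uncertainty_type",
                         "win_probability", "ambiguity_level",
                         "outcome_ordinal", "outcome_label", "win_color",
                         "is_reference_equal", "replicate")
  attr(out, "seed") <- as.integer(seed)
  out
}
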