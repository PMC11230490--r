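#' Subjective value of an uncertain or certain option
#'
#' Computes `SV = (P - beta * A / 2) * value^alpha`, the subjective value of
#' an option offering `value` with probability `P` under ambiguity level `A`.
#' `alpha` is the curvature of the utility function over outcome values
#' (alpha < 1: risk averse); `beta` discounts the winning probability
#' linearly in the ambiguity level (beta > 0: ambiguity averse). The certain
#' reference has `P = 1`, `A = 0`, so its subjective value is
#' `value_ref^alpha`. The effective probability weight `P - beta * A / 2` is
#' used as-is and may leave `[0, 1]` for extreme beta; no clamping is applied
#' so the likelihood stays smooth during optimization.
#'
#' @param P Winning probability: 0.25/0.50/0.75 for risky lotteries, 0.50 for
#'   ambiguous lotteries, 1 for the certain option. Vectorized.
#' @param A Ambiguity level (occluded fraction): 0.24/0.50/0.74 for ambiguous
#'   lotteries, 0 otherwise. Vectorized.
#' @param value Non-negative outcome value: the ordinal code (ordinal model)
#'   or the 0-10 pleasantness rating (rating model).
#' @param alpha Positive utility curvature.
#' @param beta Ambiguity attitude (real).
#' @return Numeric vector of subjective values.
#' @export
#' @examples
#' subjective_value(P = 0.5, A = 0.74, value = 4, alpha = 1, beta = 0.5) # 1.26
subjective_value <- function(P, A, value, alpha, beta) {
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  if (any(value < 0)) stop("outcome value must be non-negative", call. = FALSE)
  (P - beta * A / 2) * value^alpha
}

#' Softmax (logistic) probability of choosing the lottery
#'
#' Maps the subjective-value difference to a lottery-choice probability:
#' `P_V = 1 / (1 + exp(-gamma * (SV_L - SV_C)))`, with `gamma > 0` the
#' individual inverse-temperature (choice-noise) parameter. Computed
#' overflow-safely; equal subjective values give exactly 0.5.
#'
#' @param sv_lottery,sv_certain Subjective values of the lottery and of the
#'   certain reference (vectorized).
#' @param gamma Positive noise parameter; larger gamma means more
#'   deterministic choices.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' choice_probability(2, 1, gamma = 1) # plogis(1)
choice_probability <- function(sv_lottery, sv_certain, gamma) {
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  if (any(!is.finite(sv_lottery)) || any(!is.finite(sv_certain))) {
    stop("non-finite subjective values", call. = FALSE)
  }
  stats::plogis(gamma * (sv_lottery - sv_certain))
}

# Resolve the per-trial lottery value and the reference value for a model
# variant. Ordinal: V = ordinal code, reference = 1. Rating: V = that
# participant's rating of the outcome in that domain/phase; requires a
# complete rating set for ordinals 0-4.
trial_values <- function(trials, variant = c("ordinal", "rating"),
                         ratings = NULL) {
  variant <- match.arg(variant)
  if (variant == "ordinal") {
    list(v_lottery = as.numeric(trials$outcome_ordinal), v_ref = 1)
  } else {
    if (is.null(ratings)) {
      stop("rating variant requires a rating set", call. = FALSE)
    }
    map <- ratings$rating[match(trials$outcome_ordinal,
                                ratings$outcome_ordinal)]
    ref <- ratings$rating[match(1L, ratings$outcome_ordinal)]
    if (anyNA(map) || is.na(ref)) {
      stop("incomplete rating set for the domain's outcome levels",
           call. = FALSE)
    }
    list(v_lottery = map, v_ref = ref)
  }
}

#' Per-trial lottery-choice probabilities under the model
#'
#' @param trials Tibble of trials (one domain) as from [build_trialset()].
#' @param alpha,beta,gamma Model parameters.
#' @param variant `"ordinal"` (values are ordinal codes, reference value 1)
#'   or `"rating"` (values are the participant's 0-10 outcome ratings).
#' @param ratings For the rating variant, a tibble with `outcome_ordinal` and
#'   `rating` covering ordinals 0-4 for this participant/domain/phase.
#' @return Numeric vector of lottery-choice probabilities, one per trial.
#' @export
predict_choice_probability <- function(trials, alpha, beta, gamma,
                                       variant = c("ordinal", "rating"),
                                       ratings = NULL) {
  variant <- match.arg(variant)
  vals <- trial_values(trials, variant, ratings)
  # boundary fits can sit on the alpha -> Inf ridge; cap the exponent where
  # value^alpha would overflow (beyond it every choice probability is
  # already saturated, so predictions are unchanged)
  vmax <- max(vals$v_lottery, vals$v_ref)
  if (vmax > 1) alpha <- pmin(alpha, 700 / log(vmax))
  sv_l <- subjective_value(trials$win_probability, trials$ambiguity_level,
                           vals$v_lottery, alpha, beta)
  sv_c <- subjective_value(1, 0, vals$v_ref, alpha, beta)
  # extreme boundary fits (huge |beta|) can overflow the product; the
  # logistic is saturated far before this clamp matters
  sv_l <- pmin(pmax(sv_l, -1e306), 1e306)
  sv_c <- pmin(pmax(sv_c, -1e306), 1e306)
  choice_probability(sv_l, sv_c, gamma)
}

#' Negative log-likelihood of a participant's choices
#'
#' Bernoulli negative log-likelihood of the observed lottery/reference
#' choices under the subjective-value model with softmax choice:
#' `NLL = -sum(c * log(P_V) + (1 - c) * log(1 - P_V))`. Choice probabilities
#' are clipped to `[1e-9, 1 - 1e-9]` so saturated predictions cannot produce
#' an infinite objective.
#'
#' @param alpha,beta,gamma Model parameters (`alpha`, `gamma` positive).
#' @param chose_lottery Logical (or 0/1) vector of observed choices, aligned
#'   with `trials`.
#' @inheritParams predict_choice_probability
#' @return A non-negative scalar.
#' @export
#' @examples
#' tr <- dplyr::filter(build_trialset(0), domain == "monetary")
#' negative_log_likelihood(1, 0, 2, rep(TRUE, nrow(tr)), tr)
negative_log_likelihood <- function(alpha, beta, gamma, chose_lottery, trials,
                                    variant = c("ordinal", "rating"),
                                    ratings = NULL) {
  if (nrow(trials) < 1L) stop("empty choice set", call. = FALSE)
  stopifnot(length(chose_lottery) == nrow(trials))
  p <- clip01(predict_choice_probability(trials, alpha, beta, gamma,
                                         variant, ratings))
  c_ <- as.numeric(chose_lottery)
  -sum(c_ * log(p) + (1 - c_) * log(1 - p))
}
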