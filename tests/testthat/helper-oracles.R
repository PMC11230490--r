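# Independent oracles and tiny fixtures, deliberately written as plain
# per-trial loops that share no code with the package internals.

# Naive per-trial negative log-likelihood of the softmax subjective-value
# model; clips probabilities to [1e-9, 1 - 1e-9] like the implementation.
naive_nll <- function(alpha, beta, gamma, chose_lottery, trials,
                      values = NULL, v_ref = 1) {
  if (is.null(values)) values <- trials$outcome_ordinal
  total <- 0
  for (i in seq_len(nrow(trials))) {
    sv_l <- (trials$win_probability[i] -
               beta * trials$ambiguity_level[i] / 2) * values[i]^alpha
    sv_c <- v_ref^alpha
    p <- 1 / (1 + exp(-gamma * (sv_l - sv_c)))
    p <- min(max(p, 1e-9), 1 - 1e-9)
    total <- total - if (chose_lottery[i]) log(p) else log(1 - p)
  }
  total
}

# Hand-rolled single trials (bypassing build_trialset) for arithmetic cases.
make_trial_rows <- function(win_probability, ambiguity_level, outcome_ordinal,
                            domain = "monetary") {
  tibble::tibble(
    trial_id = seq_along(win_probability), domain = domain,
    uncertainty_type = ifelse(ambiguity_level > 0, "ambiguity", "risk"),
    win_probability = win_probability, ambiguity_level = ambiguity_level,
    outcome_ordinal = as.integer(outcome_ordinal),
    outcome_label = as.character(outcome_ordinal),
    win_color = "red", is_reference_equal = outcome_ordinal == 1L,
    replicate = 1L)
}

# Random valid trial rows for property-style checks.
random_trials <- function(n, seed) {
  set.seed(seed)
  risky <- runif(n) < 0.5
  make_trial_rows(
    win_probability = ifelse(risky, sample(c(0.25, 0.5, 0.75), n, TRUE), 0.5),
    ambiguity_level = ifelse(risky, 0, sample(c(0.24, 0.5, 0.74), n, TRUE)),
    outcome_ordinal = sample(1:4, n, TRUE))
}

# Assemble a dataset list in the shape fit_cohort()/apply_exclusions() take.
cohort_dataset <- function(coh, trials) {
  c(list(trials = trials),
    coh[c("choices", "ratings", "participants", "truth")])
}
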