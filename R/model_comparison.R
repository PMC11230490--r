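#' Bayesian information criterion of a fit
#'
#' `BIC = 2 * NLL + k * log(n_trials)` with `k = 3` fitted parameters
#' (alpha, beta, gamma) and the natural logarithm.
#'
#' @param fit An `ordival_fit`, or a list/row with `nll` and `n_trials`.
#' @param k Number of free parameters (default 3).
#' @return Scalar BIC (lower is better).
#' @export
#' @examples
#' bic(list(nll = 20, n_trials = 49)) # 40 + 3 log 49
bic <- function(fit, k = 3) {
  n <- fit$n_trials
  if (is.null(n) || any(n < 1)) stop("n_trials must be >= 1", call. = FALSE)
  2 * fit$nll + k * log(n)
}

#' Seeded k-fold partition of trials
#'
#' Randomly assigns `n` trials to `k` folds whose sizes differ by at most
#' one; 49 trials under 5 folds gives sizes 9 and 10.
#'
#' @param n Number of trials.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold label (1..k) per trial.
#' @export
#' @examples
#' table(cv_folds(49, 5, seed = 1))
cv_folds <- function(n, k = 5, seed = 0L) {
  stopifnot(n >= k)
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  set.seed(substream_seed(seed, "cv_folds"))
  sample(rep(seq_len(k), times = sizes))
}

#' K-fold cross-validated prediction error for one participant
#'
#' Randomly partitions the participant's trials into `k` folds, refits the
#' model on the k-1 training folds and scores the left-out fold by the mean
#' squared error between the predicted lottery-choice probability and the
#' binary choice (a Brier-style residual; predictions are probabilities, not
#' thresholded choices). Folds whose training set contains no uncertain
#' choice cannot be fitted and are skipped with a message; the result
#' averages the remaining folds.
#'
#' @inheritParams fit_participant
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `mean_mse`, `fold_mse`, `fold_sizes`, `n_skipped`.
#' @export
cross_validate <- function(chose_lottery, trials,
                           variant = c("ordinal", "rating"), ratings = NULL,
                           k = 5, seed = 0L, grid = make_start_grid(),
                           tol = 1e-6, maxfeval = 2000L) {
  variant <- match.arg(variant)
  n <- nrow(trials)
  fold <- cv_folds(n, k, seed)
  fold_mse <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    train <- fold != f
    if (!any(chose_lottery[train])) {
      message("cross_validate: fold ", f,
              " skipped (training set has no uncertain choice)")
      next
    }
    fit <- fit_participant(chose_lottery[train], trials[train, ], variant,
                           ratings, grid = grid, tol = tol,
                           maxfeval = maxfeval)
    p <- predict_choice_probability(trials[!train, ], fit$alpha_hat,
                                    fit$beta_hat, fit$gamma_hat, variant,
                                    ratings)
    fold_mse[f] <- mean((p - as.numeric(chose_lottery[!train]))^2)
  }
  list(mean_mse = mean(fold_mse, na.rm = TRUE), fold_mse = fold_mse,
       fold_sizes = as.integer(table(fold)), n_skipped = sum(is.na(fold_mse)))
}

#' Compare the ordinal and rating model variants
#'
#' Fits each variant to every retained participant x phase x domain unit and
#' summarizes, per domain and phase, the across-participant mean BIC and
#' mean 5-fold cross-validated MSE. The selected variant per (domain, phase)
#' is the one winning on both criteria; a split verdict is flagged
#' `"discordant"` and both criteria are reported either way.
#'
#' @inheritParams fit_cohort
#' @param variants Character vector of variants to compare.
#' @param k Folds for cross-validation.
#' @param seed Run seed; fold assignment is sub-seeded per participant unit.
#' @return List with `comparison` (variant x domain x phase rows:
#'   `mean_bic`, `mean_cv_mse`, `n_participants`) and `selection` (per
#'   domain x phase: `selected`, `bic_winner`, `cv_winner`).
#' @export
compare_models <- function(dataset, variants = c("ordinal", "rating"),
                           k = 5, seed = 0L, grid = make_start_grid(),
                           prefiltered = FALSE) {
  trials <- dataset$trials
  choices <- if (prefiltered) dataset$choices else
    apply_exclusions(dataset)$modeling_choices
  ch <- dplyr::inner_join(
    dplyr::select(choices, "participant_id", "phase", "trial_id",
                  "chose_lottery"),
    dplyr::select(trials, "trial_id", "domain"), by = "trial_id")
  units <- dplyr::distinct(ch, .data$participant_id, .data$phase, .data$domain)
  rows <- purrr::map_dfr(variants, function(v) {
    purrr::pmap_dfr(units, function(participant_id, phase, domain) {
      sel <- ch$participant_id == participant_id & ch$phase == phase &
        ch$domain == domain
      tr <- trials[match(ch$trial_id[sel], trials$trial_id), ]
      rat <- if (!is.null(dataset$ratings)) {
        dplyr::filter(dataset$ratings,
                      .data$participant_id == !!participant_id,
                      .data$phase == !!phase, .data$domain == !!domain)
      }
      fit <- fit_participant(ch$chose_lottery[sel], tr, v, rat, grid = grid)
      cv <- cross_validate(ch$chose_lottery[sel], tr, v, rat, k = k,
                           seed = substream_seed(seed,
                             paste(participant_id, phase, domain)),
                           grid = grid)
      tibble::tibble(variant = v, participant_id = participant_id,
                     phase = phase, domain = domain, bic = bic(fit),
                     cv_mse = cv$mean_mse)
    })
  })
  comparison <- dplyr::summarise(
    dplyr::group_by(rows, .data$variant, .data$domain, .data$phase),
    mean_bic = mean(.data$bic), mean_cv_mse = mean(.data$cv_mse),
    n_participants = dplyr::n(), .groups = "drop")
  selection <- dplyr::summarise(
    dplyr::group_by(comparison, .data$domain, .data$phase),
    bic_winner = .data$variant[which.min(.data$mean_bic)],
    cv_winner = .data$variant[which.min(.data$mean_cv_mse)],
    .groups = "drop")
  selection$selected <- ifelse(selection$bic_winner == selection$cv_winner,
                               selection$bic_winner, "discordant")
  list(comparison = comparison, selection = selection, by_participant = rows)
}
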