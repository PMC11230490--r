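aggregate_choice_cells <- function(P, A, V, chose_lottery) {
  key <- paste(P, A, V)
  idx <- !duplicated(key)
  n1 <- tapply(as.numeric(chose_lottery), key, sum)
  n0 <- tapply(1 - as.numeric(chose_lottery), key, sum)
  k <- key[idx]
  list(P = P[idx], A = A[idx], V = V[idx],
       n1 = as.numeric(n1[k]), n0 = as.numeric(n0[k]))
}

#' Build the multistart grid of optimizer starting points
#'
#' Cartesian product of arithmetic sequences over the per-parameter start
#' ranges, advancing by `step` from the range start and clipped to the range
#' end. Defaults reproduce the published search grid: alpha starts in
#' `[0.01, 4]` (8 values), beta in `[-2, 2]` (9 values) and gamma start
#' magnitudes `{0.01, 0.51}`, giving 8 x 9 x 2 = 144 starts.
#'
#' @param alpha_range,beta_range,gamma_range Length-2 numeric ranges
#'   (gamma on the positive magnitude scale).
#' @param step Grid step (> 0), default 0.5.
#' @return Tibble with columns `alpha`, `beta`, `gamma` and a `start_index`.
#' @export
#' @examples
#' nrow(make_start_grid()) # 144
make_start_grid <- function(alpha_range = c(0.01, 4),
                            beta_range = c(-2, 2),
                            gamma_range = c(0.01, 1),
                            step = 0.5) {
  stopifnot(step > 0)
  seq_clip <- function(r) {
    if (length(r) != 2L || r[2] < r[1]) stop("empty range", call. = FALSE)
    seq(r[1], r[2], by = step)
  }
  g <- tidyr::crossing(alpha = seq_clip(alpha_range),
                       beta = seq_clip(beta_range),
                       gamma = seq_clip(gamma_range))
  g <- dplyr::arrange(g, .data$alpha, .data$beta, .data$gamma)
  g$start_index <- seq_len(nrow(g))
  g
}

#' Fit the subjective-value model to one participant's choices
#'
#' Maximum-likelihood estimation of `(alpha, beta, gamma)` by Nelder-Mead
#' simplex minimization of the negative log-likelihood, restarted from every
#' point of the start grid; the lowest-NLL solution wins, with exact ties
#' broken by the lowest start index. `alpha` and `gamma` are kept positive
#' through a log transform; `beta` is unconstrained. Deterministic given the
#' same inputs. Estimates with `alpha > 10`, `|beta| > 4` or `gamma > 100`
#' are flagged as boundary fits.
#'
#' @param chose_lottery Logical vector of choices aligned with `trials`.
#' @param trials Single-domain trial tibble (>= 10 trials).
#' @param variant `"ordinal"` or `"rating"`.
#' @param ratings Participant's rating set (rating variant only).
#' @param grid Start grid from [make_start_grid()].
#' @param tol Convergence tolerance on objective and parameter spread
#'   (default 1e-6).
#' @param maxfeval Evaluation cap per start (default 2000).
#' @return An object of class `ordival_fit`; see [tidy.ordival_fit()] and
#'   [glance.ordival_fit()].
#' @export
#' @examples
#' tr <- dplyr::filter(build_trialset(0), domain == "monetary")
#' ch <- simulate_agent_choices(0.8, 0.3, 3, tr, seed = 2)
#' fit <- fit_participant(ch$chose_lottery, tr)
#' glance(fit)
fit_participant <- function(chose_lottery, trials,
                            variant = c("ordinal", "rating"), ratings = NULL,
                            grid = make_start_grid(), tol = 1e-6,
                            maxfeval = 2000L) {
  variant <- match.arg(variant)
  if (nrow(trials) < 10L) stop("need at least 10 trials", call. = FALSE)
  stopifnot(length(chose_lottery) == nrow(trials))
  if (!any(chose_lottery)) {
    stop("participant never chose the uncertain option; cannot be modeled",
         call. = FALSE)
  }
  vals <- trial_values(trials, variant, ratings)
  # likelihood cells: trials sharing (P, A, V) contribute through their
  # choice counts only, which makes the objective cost independent of the
  # raw trial count
  cells <- aggregate_choice_cells(trials$win_probability,
                                  trials$ambiguity_level, vals$v_lottery,
                                  chose_lottery)
  res <- fit_multistart_cpp(cells$P, cells$A, cells$V, vals$v_ref,
                            cells$n1, cells$n0,
                            as.matrix(grid[, c("alpha", "beta", "gamma")]),
                            tol = tol, maxfeval = as.integer(maxfeval))
  if (!all(is.finite(res$start_nll))) {
    bad <- which(!is.finite(res$start_nll))
    stop("optimization failed from ", length(bad), " start(s); first bad start index ",
         bad[1L], call. = FALSE)
  }
  # a fit can legitimately drive log(alpha) or log(gamma) toward -Inf
  # (value-insensitive or noise-free behavior); floor at a tiny positive so
  # the estimate stays inside the parameter domain, and flag it
  alpha_hat <- max(res$alpha, 1e-12)
  gamma_hat <- max(res$gamma, 1e-12)
  structure(list(
    alpha_hat = alpha_hat, beta_hat = res$beta, gamma_hat = gamma_hat,
    reported_ambiguity_attitude = -res$beta,
    nll = res$nll, n_trials = nrow(trials), variant = variant,
    start_point = unlist(grid[res$start_index, c("alpha", "beta", "gamma")]),
    start_index = res$start_index, converged = res$converged,
    n_starts = nrow(grid), start_nll = res$start_nll,
    boundary_fit = alpha_hat > 10 || alpha_hat < 1e-6 || abs(res$beta) > 4 ||
      gamma_hat > 100 || gamma_hat < 1e-6,
    trials = trials, chose_lottery = chose_lottery, ratings = ratings),
    class = "ordival_fit")
}

#' @export
print.ordival_fit <- function(x, ...) {
  cat(sprintf(
    "subjective-value model fit (%s): alpha=%.3f beta=%.3f gamma=%.3f\n",
    x$variant, x$alpha_hat, x$beta_hat, x$gamma_hat))
  cat(sprintf("  NLL %.4f over %d trials (%d starts%s)\n", x$nll, x$n_trials,
              x$n_starts, if (x$boundary_fit) ", boundary fit" else ""))
  invisible(x)
}

#' Tidy a participant fit into one row per parameter
#'
#' @param x An `ordival_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (and the reported ambiguity
#'   attitude `-beta` as its own term).
#' @method tidy ordival_fit
#' @export
tidy.ordival_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "ambiguity_attitude"),
    estimate = c(x$alpha_hat, x$beta_hat, x$gamma_hat,
                 x$reported_ambiguity_attitude))
}

#' One-row model summary of a participant fit
#'
#' @param x An `ordival_fit`.
#' @param ... Unused.
#' @return Tibble with `nll`, `bic`, `n_trials`, `converged`, `n_starts`,
#'   `boundary_fit`, `variant`.
#' @method glance ordival_fit
#' @export
glance.ordival_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, bic = bic(x), n_trials = x$n_trials,
                 converged = x$converged, n_starts = x$n_starts,
                 boundary_fit = x$boundary_fit, variant = x$variant)
}

#' Fit every retained participant x phase x domain unit
#'
#' Applies the exclusion filters (catch-trial, duplicate-ID, age-gap, and
#' the modeling-only never-uncertain rule) unless pre-filtered choices are
#' supplied, then fits the model separately per unit. Per-unit failures are
#' recorded, not fatal.
#'
#' @param dataset List with `trials`, `choices` and optionally
#'   `participants`, `ratings` (e.g. [simulate_cohort()] output plus trials).
#' @param variant `"ordinal"` or `"rating"`.
#' @param grid,tol,maxfeval Passed to [fit_participant()].
#' @param prefiltered If `TRUE`, `dataset$choices` is used as-is.
#' @return Tibble, one row per fitted unit: estimates, `nll`, `bic`,
#'   bookkeeping columns, and `error` (NA unless the unit failed).
#' @export
fit_cohort <- function(dataset, variant = c("ordinal", "rating"),
                       grid = make_start_grid(), tol = 1e-6,
                       maxfeval = 2000L, prefiltered = FALSE) {
  variant <- match.arg(variant)
  trials <- dataset$trials
  choices <- if (prefiltered) dataset$choices else
    apply_exclusions(dataset)$modeling_choices
  ch <- dplyr::inner_join(
    dplyr::select(choices, "participant_id", "phase", "trial_id",
                  "chose_lottery"),
    dplyr::select(trials, "trial_id", "domain"), by = "trial_id")
  units <- dplyr::distinct(ch, .data$participant_id, .data$phase, .data$domain)
  purrr::pmap_dfr(units, function(participant_id, phase, domain) {
    rows <- ch$participant_id == participant_id & ch$phase == phase &
      ch$domain == domain
    tr <- trials[match(ch$trial_id[rows], trials$trial_id), ]
    rat <- if (!is.null(dataset$ratings)) {
      dplyr::filter(dataset$ratings,
                    .data$participant_id == !!participant_id,
                    .data$phase == !!phase, .data$domain == !!domain)
    }
    base <- tibble::tibble(participant_id = participant_id, phase = phase,
                           domain = domain, variant = variant)
    fit <- tryCatch(
      fit_participant(ch$chose_lottery[rows], tr, variant, rat,
                      grid = grid, tol = tol, maxfeval = maxfeval),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(dplyr::mutate(base, alpha_hat = NA_real_, beta_hat = NA_real_,
                           gamma_hat = NA_real_,
                           reported_ambiguity_attitude = NA_real_,
                           nll = NA_real_, bic = NA_real_,
                           n_trials = sum(rows), converged = NA,
                           n_starts = nrow(grid), boundary_fit = NA,
                           start_alpha = NA_real_, start_beta = NA_real_,
                           start_gamma = NA_real_,
                           error = conditionMessage(fit)))
    }
    dplyr::mutate(base, alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat,
                  gamma_hat = fit$gamma_hat,
                  reported_ambiguity_attitude = fit$reported_ambiguity_attitude,
                  nll = fit$nll, bic = bic(fit), n_trials = fit$n_trials,
                  converged = fit$converged, n_starts = fit$n_starts,
                  boundary_fit = fit$boundary_fit,
                  start_alpha = fit$start_point[["alpha"]],
                  start_beta = fit$start_point[["beta"]],
                  start_gamma = fit$start_point[["gamma"]],
                  error = NA_character_)
  })
}
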