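#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties, listwise deletion of incomplete pairs, and a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' A constant vector leaves the correlation undefined and is flagged.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble with `rho`, `p_value`, `n`, `n_dropped`, `defined`.
#' @export
#' @examples
#' spearman_cor(1:5, c(5, 6, 7, 8, 7))
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          n_dropped = n_dropped, defined = FALSE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n, n_dropped = n_dropped,
                 defined = TRUE)
}

pair_measure <- function(df, value_col, split_col, a, b, keys) {
  wide <- tidyr::pivot_wider(
    df[, c(keys, split_col, value_col)],
    names_from = dplyr::all_of(split_col),
    values_from = dplyr::all_of(value_col))
  list(x = wide[[as.character(a)]], y = wide[[as.character(b)]])
}

#' Full consistency grid of model-free and model-based attitudes
#'
#' Emits the study's correlation grid: for each of the four attitude
#' measures (risk choice proportion, corrected ambiguity proportion, fitted
#' alpha, fitted beta) the cross-domain correlation within each phase, the
#' cross-phase (test-retest) correlation within each domain, and the
#' model-versus-model-free validation correlations (alpha vs risk
#' proportion; beta vs corrected ambiguity proportion) within each domain
#' and phase. Units are paired per participant with listwise deletion;
#' dropped counts are reported so every cell's n is auditable. Model-based
#' rows use the raw fitted `beta_hat` (aversion positive); the fits table
#' also carries `-beta` as the reported attitude.
#'
#' @param modelfree Output of [model_free_summary()].
#' @param fits Output of [fit_cohort()] (may be `NULL` to skip model-based
#'   rows).
#' @return Tibble of `CorrelationResult` rows: `measure`, `axis`, `context`,
#'   `rho`, `p_value`, `n`, `n_dropped`.
#' @export
run_consistency_suite <- function(modelfree, fits = NULL) {
  measures <- list(
    risk_prop = list(df = modelfree, col = "risk_attitude"),
    corrected_amb_prop = list(df = modelfree, col = "ambiguity_attitude"))
  if (!is.null(fits)) {
    fits_ok <- dplyr::filter(fits, is.na(.data$error))
    measures$alpha <- list(df = fits_ok, col = "alpha_hat")
    measures$beta <- list(df = fits_ok, col = "beta_hat")
  }
  out <- list()
  add <- function(measure, axis, context, x, y) {
    if (sum(stats::complete.cases(x, y)) < 3L) return()
    r <- spearman_cor(x, y)
    out[[length(out) + 1L]] <<- dplyr::mutate(
      r, measure = measure, axis = axis, context = context,
      .before = 1L)
  }
  for (m in names(measures)) {
    df <- measures[[m]]$df; col <- measures[[m]]$col
    for (ph in sort(unique(df$phase))) {
      d <- dplyr::filter(df, .data$phase == ph)
      pr <- pair_measure(d, col, "domain", "monetary", "medical",
                         "participant_id")
      add(m, "cross_domain", paste0("phase", ph), pr$x, pr$y)
    }
    for (dom in sort(unique(df$domain))) {
      d <- dplyr::filter(df, .data$domain == dom)
      pr <- pair_measure(d, col, "phase", 1, 2, "participant_id")
      add(m, "cross_phase", dom, pr$x, pr$y)
    }
  }
  if (!is.null(fits)) {
    fits_ok <- dplyr::filter(fits, is.na(.data$error))
    joined <- dplyr::inner_join(
      fits_ok, modelfree, by = c("participant_id", "phase", "domain"))
    for (ph in sort(unique(joined$phase))) {
      for (dom in sort(unique(joined$domain))) {
        d <- dplyr::filter(joined, .data$phase == ph, .data$domain == dom)
        add("alpha", "model_vs_modelfree", paste0(dom, "_phase", ph),
            d$alpha_hat, d$risk_attitude)
        add("beta", "model_vs_modelfree", paste0(dom, "_phase", ph),
            d$beta_hat, d$ambiguity_attitude)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Group-level monotonicity manipulation checks
#'
#' Verifies, per domain and phase, that (a) group-mean outcome-pleasantness
#' ratings are non-decreasing in the ordinal outcome level and (b) group-
#' mean lottery-choice proportions are non-decreasing in the lottery's
#' outcome level - the two signatures of participants understanding the
#' outcome scale. A cell with fewer than two levels is reported as
#' not-applicable (`NA`).
#'
#' @param modelfree Output of [model_free_summary()] (uses the
#'   `prop_outcome_*` columns).
#' @param ratings Rating records (`participant_id`, `phase`, `domain`,
#'   `outcome_ordinal`, `rating`).
#' @return Tibble: `domain`, `phase`, `check`, `n_levels`, `passed`.
#' @export
manipulation_checks <- function(modelfree, ratings) {
  non_decreasing <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA)
    all(diff(v) >= 0)
  }
  rat <- dplyr::summarise(
    dplyr::group_by(ratings, .data$domain, .data$phase, .data$outcome_ordinal),
    m = mean(.data$rating), .groups = "drop_last")
  rat <- dplyr::summarise(
    rat, check = "ratings_monotone", n_levels = dplyr::n(),
    passed = non_decreasing(.data$m[order(.data$outcome_ordinal)]),
    .groups = "drop")

  oc_cols <- grep("^prop_outcome_", names(modelfree), value = TRUE)
  oc <- tidyr::pivot_longer(
    modelfree[, c("participant_id", "phase", "domain", oc_cols)],
    dplyr::all_of(oc_cols), names_to = "level", values_to = "prop")
  oc$level <- as.integer(sub("prop_outcome_", "", oc$level))
  oc <- dplyr::summarise(
    dplyr::group_by(oc, .data$domain, .data$phase, .data$level),
    m = mean(.data$prop, na.rm = TRUE), .groups = "drop_last")
  oc <- dplyr::summarise(
    oc, check = "choices_monotone", n_levels = sum(!is.na(.data$m)),
    passed = non_decreasing(.data$m[order(.data$level)]), .groups = "drop")
  dplyr::bind_rows(rat, oc)
}
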