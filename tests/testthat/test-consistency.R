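trialset <- build_trialset(0)

test_that("spearman correlation handles ties, signs, and missing pairs", {
  x <- c(1, 2, 3, 4, 5)
  # monotone transform: perfect rank agreement
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # tied ranks via average ranks (frozen from the base-R oracle)
  r <- spearman_cor(x, c(5, 6, 7, 8, 7))
  expect_equal(r$rho, 0.8207827, tolerance = 1e-6)
  ct <- suppressWarnings(
    cor.test(x, c(5, 6, 7, 8, 7), method = "spearman", exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate))
  # two-sided t-approximation p-value
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), r$n - 2))

  # listwise deletion is counted
  r2 <- spearman_cor(c(x, NA, 7), c(5, 6, 7, 8, 7, 1, NA))
  expect_equal(r2$n, 5L)
  expect_equal(r2$n_dropped, 2L)

  # degenerate inputs
  expect_false(spearman_cor(c(1, 1, 1), c(1, 2, 3))$defined)
  expect_error(spearman_cor(c(1, 2), c(1, 2)), "at least 3")
  # symmetric in argument order
  y <- c(2, 7, 1, 9, 4)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
})

test_that("consistency suite recovers planted couplings and null cases", {
  coh <- simulate_cohort(
    cohort_spec(400, cross_domain_rho = 0, cross_phase_rho = 0.6, seed = 97),
    trialset)
  mf <- model_free_summary(coh$choices, trialset)
  out <- run_consistency_suite(mf)
  expect_true(all(c("measure", "axis", "context", "rho", "p_value", "n") %in%
                    names(out)))
  expect_true(all(abs(out$rho) <= 1))
  expect_true(all(out$n >= 3))
  # model-free rows for both measures on both axes
  expect_setequal(unique(out$measure), c("risk_prop", "corrected_amb_prop"))
  expect_setequal(unique(out$axis), c("cross_domain", "cross_phase"))

  # independent domains: near-zero cross-domain association of risk props
  cd <- dplyr::filter(out, measure == "risk_prop", axis == "cross_domain")
  expect_true(all(abs(cd$rho) < 0.12))
  # planted temporal persistence shows up, attenuated by binomial noise
  cp <- dplyr::filter(out, measure == "risk_prop", axis == "cross_phase")
  expect_true(all(cp$rho > 0.25))

  # invariant to participant ordering
  mf_shuffled <- mf[sample(nrow(mf)), ]
  expect_equal(run_consistency_suite(mf_shuffled)$rho, out$rho)
})

test_that("model-based rows join fits to model-free summaries", {
  coh <- simulate_cohort(cohort_spec(12, seed = 101), trialset)
  ds <- cohort_dataset(coh, trialset)
  filt <- apply_exclusions(ds)
  mf <- model_free_summary(filt$modelfree_choices, trialset)
  fits <- fit_cohort(c(ds, list(choices = filt$modeling_choices)),
                     prefiltered = TRUE)
  out <- run_consistency_suite(mf, fits)
  expect_true(all(c("alpha", "beta") %in% out$measure))
  mv <- dplyr::filter(out, axis == "model_vs_modelfree")
  # fitted alpha tracks the risky-choice proportion within each unit
  expect_true(all(mv$rho[mv$measure == "alpha"] > 0.5))
  # auditable cell sizes
  expect_true(all(mv$n <= 12))
})

test_that("manipulation checks flag monotone and inverted rating patterns", {
  coh <- simulate_cohort(cohort_spec(40, seed = 103), trialset)
  mf <- model_free_summary(coh$choices, trialset)
  checks <- manipulation_checks(mf, coh$ratings)
  expect_true(all(checks$passed))
  expect_setequal(unique(checks$check),
                  c("ratings_monotone", "choices_monotone"))

  # adversarial fixture: inverted ratings fail only the rating check
  inv <- coh$ratings
  inv$rating <- 10 - inv$rating
  checks_inv <- manipulation_checks(mf, inv)
  expect_false(any(checks_inv$passed[checks_inv$check == "ratings_monotone"]))
  expect_true(all(checks_inv$passed[checks_inv$check == "choices_monotone"]))

  # degenerate single-level input is not applicable, not a failure
  one_level <- dplyr::filter(coh$ratings, outcome_ordinal == 2)
  checks_deg <- manipulation_checks(mf, one_level)
  expect_true(all(is.na(
    checks_deg$passed[checks_deg$check == "ratings_monotone"])))
})
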