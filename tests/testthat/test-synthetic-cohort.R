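trialset <- build_trialset(0)

test_that("simulated choices follow the generative softmax model", {
  trm <- dplyr::filter(trialset, domain == "monetary")
  # noiseless limit: SV_L = 0.75 * 4 = 3 > 1 = SV_C, so the lottery is
  # always taken at very large gamma
  tr_easy <- make_trial_rows(rep(0.75, 50), rep(0, 50), rep(4, 50))
  ch <- simulate_agent_choices(1, 0, 1e6, tr_easy, seed = 3)
  expect_true(all(ch$chose_lottery))

  # equal subjective values are coin flips for any gamma: the uncertain
  # reference (SV_L = 0.5) against the certain reference (SV_C = 1) is NOT
  # a coin flip - its rate follows the logistic in their difference
  tr_eq <- make_trial_rows(rep(1, 4000), rep(0, 4000), rep(1, 4000))
  ch <- simulate_agent_choices(0.7, 0, 8, tr_eq, seed = 4)
  expect_equal(mean(ch$chose_lottery), 0.5, tolerance = 3 * 0.5 / sqrt(4000))
  tr_catch <- make_trial_rows(rep(0.5, 4000), rep(0, 4000), rep(1, 4000))
  ch <- simulate_agent_choices(0.7, 0, 2, tr_catch, seed = 4)
  p_catch <- 1 / (1 + exp(-2 * (0.5 - 1)))
  expect_equal(mean(ch$chose_lottery), p_catch,
               tolerance = 3 * sqrt(p_catch * (1 - p_catch) / 4000))

  # closed-form logistic rate: alpha=1, beta=0, gamma=5, 50% risk, V=4
  n <- 10000
  tr50 <- make_trial_rows(rep(0.5, n), rep(0, n), rep(4, n))
  ch <- simulate_agent_choices(1, 0, 5, tr50, seed = 5)
  p_true <- 1 / (1 + exp(-5 * (2 - 1)))
  expect_equal(mean(ch$chose_lottery), p_true,
               tolerance = 3 * sqrt(p_true * (1 - p_true) / n))

  expect_error(simulate_agent_choices(1, 0, 1, trm[0, ], 1), "empty")
  expect_error(simulate_agent_choices(1, 0, 1, trialset, 1), "single domain")
})

test_that("cohort bookkeeping, determinism, and rating bounds hold", {
  spec <- cohort_spec(5, seed = 7)
  coh <- simulate_cohort(spec, trialset)
  expect_equal(nrow(coh$choices), 5L * 2L * 98L)
  expect_equal(nrow(coh$ratings), 5L * 2L * 2L * 5L)
  expect_equal(nrow(coh$participants), 10L)
  expect_equal(nrow(coh$truth), 5L * 2L * 2L)
  expect_true(all(coh$ratings$rating >= 0 & coh$ratings$rating <= 10))
  expect_true(all(coh$truth$alpha > 0 & coh$truth$gamma > 0))

  coh2 <- simulate_cohort(cohort_spec(5, seed = 7), trialset)
  expect_identical(coh, coh2)
  coh3 <- simulate_cohort(cohort_spec(5, seed = 8), trialset)
  expect_false(identical(coh$choices, coh3$choices))
})

test_that("expected ratings increase with the ordinal outcome level", {
  coh <- simulate_cohort(cohort_spec(200, seed = 13), trialset)
  m <- tapply(coh$ratings$rating, coh$ratings$outcome_ordinal, mean)
  expect_true(all(diff(m) > 0))
})

test_that("planted rank correlations are realized by the Gaussian copula", {
  spec <- cohort_spec(2000, cross_domain_rho = 0.3, cross_phase_rho = 0.6,
                      seed = 19)
  truth <- ordival:::sample_truth(spec)
  w <- tidyr::pivot_wider(truth[, c("agent", "phase", "domain", "alpha")],
                          names_from = c("domain", "phase"),
                          values_from = "alpha")
  expect_lt(abs(cor(w$monetary_1, w$monetary_2, method = "spearman") - 0.6),
            0.05)
  expect_lt(abs(cor(w$monetary_1, w$medical_1, method = "spearman") - 0.3),
            0.05)
  expect_error(cohort_spec(10, cross_domain_rho = 0.995), "infeasible")
})

test_that("planted aberrant agents emit the behavior their rule targets", {
  spec <- cohort_spec(40, aberrant_fractions = c(catch_failer = 0.1,
                                                 never_uncertain = 0.1,
                                                 duplicate_id = 0.1),
                      seed = 23)
  coh <- simulate_cohort(spec, trialset)
  roles <- dplyr::distinct(coh$truth, participant_id, role)
  expect_equal(sum(roles$role == "catch_failer"), 4L)

  catch_ids <- trialset$trial_id[trialset$is_reference_equal]
  for (pid in roles$participant_id[roles$role == "catch_failer"]) {
    ch <- dplyr::filter(coh$choices, participant_id == pid,
                        trial_id %in% catch_ids)
    expect_true(all(ch$chose_lottery))
  }
  for (pid in roles$participant_id[roles$role == "never_uncertain"]) {
    ch <- dplyr::filter(coh$choices, participant_id == pid)
    expect_false(any(ch$chose_lottery))
  }
  roster <- dplyr::filter(coh$participants, phase == 1)
  dup_workers <- roster$mturk_like_id[
    roster$participant_id %in%
      roles$participant_id[roles$role == "duplicate_id"]]
  expect_true(all(table(roster$mturk_like_id)[dup_workers] >= 2))
})
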