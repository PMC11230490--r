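trialset <- build_trialset(0)

test_that("choice proportions are per-group lottery rates, catch excluded", {
  trm <- dplyr::filter(trialset, domain == "monetary")
  # 6 of 12 lottery choices at 50% risk -> 0.5
  tr12 <- make_trial_rows(rep(0.5, 12), rep(0, 12), rep(2:4, 4))
  ch12 <- tibble::tibble(participant_id = "p", phase = 1L,
                         trial_id = tr12$trial_id,
                         chose_lottery = rep(c(TRUE, FALSE), 6))
  pr <- choice_proportions(ch12, tr12, "uncertainty_level")
  expect_equal(pr$proportion[pr$level == 0.5], 0.5)
  # and within the real trial set: 7 value trials per level
  risk50 <- dplyr::filter(trm, uncertainty_type == "risk",
                          win_probability == 0.5, !is_reference_equal)
  expect_equal(nrow(risk50), 7L)
  ch <- tibble::tibble(participant_id = "p", phase = 1L,
                       trial_id = risk50$trial_id,
                       chose_lottery = seq_len(7) <= 3)
  pr <- choice_proportions(ch, trialset, "uncertainty_level")
  expect_equal(pr$proportion[pr$level == 0.5], 3 / 7)

  # catch trials never enter proportions
  catch <- dplyr::filter(trm, is_reference_equal)
  ch_catch <- tibble::tibble(participant_id = "p", phase = 1L,
                             trial_id = catch$trial_id, chose_lottery = TRUE)
  expect_equal(nrow(choice_proportions(ch_catch, trialset)), 0L)

  # all-reference chooser scores 0 at every level; unseen levels are NA,
  # not zero
  value <- dplyr::filter(trm, !is_reference_equal)
  ch0 <- tibble::tibble(participant_id = "p", phase = 1L,
                        trial_id = value$trial_id, chose_lottery = FALSE)
  s <- model_free_summary(ch0, trialset)
  expect_equal(s$risk_attitude, 0)
  expect_equal(s$ambiguity_attitude, 0)
  s_part <- model_free_summary(ch, trialset) # only 50%-risk trials seen
  expect_true(is.na(s_part$prop_risk_25))
  expect_true(is.na(s_part$risk_attitude))
})

test_that("corrected ambiguity proportion subtracts the 50%-risk rate", {
  base <- tibble::tibble(participant_id = "p", phase = 1L,
                         domain = "monetary",
                         prop_amb_24 = 0.5, prop_amb_50 = 0.6,
                         prop_amb_74 = 0.4, prop_risk_50 = 0.6)
  out <- corrected_ambiguity_proportion(base)
  expect_equal(out$corrected_amb_74, -0.2) # averse
  expect_equal(out$corrected_amb_50, 0)    # neutral anchor
  expect_equal(out$ambiguity_attitude, (-0.1 + 0 - 0.2) / 3)
  # a missing 50%-risk cell poisons the whole correction
  base$prop_risk_50 <- NA_real_
  expect_true(is.na(corrected_ambiguity_proportion(base)$ambiguity_attitude))
})

test_that("risk attitude is the unweighted mean of the three risk levels", {
  coh <- simulate_cohort(cohort_spec(8, seed = 43), trialset)
  s <- model_free_summary(coh$choices, trialset)
  expect_equal(s$risk_attitude,
               (s$prop_risk_25 + s$prop_risk_50 + s$prop_risk_75) / 3)
  expect_true(all(s$ambiguity_attitude >= -1 & s$ambiguity_attitude <= 1,
                  na.rm = TRUE))
})

test_that("a near-deterministic agent's proportions rise with win probability", {
  trm <- dplyr::filter(trialset, domain == "monetary")
  ch <- simulate_agent_choices(1, 0, 50, trm, seed = 47)
  ch$participant_id <- "p"; ch$phase <- 1L
  pr <- choice_proportions(ch, trialset, "uncertainty_level")
  risk <- dplyr::arrange(dplyr::filter(pr, uncertainty_type == "risk"), level)
  expect_true(all(diff(risk$proportion) >= 0))
})

test_that("corrected ambiguity attitude decreases in the generative beta", {
  coh <- simulate_cohort(cohort_spec(250, seed = 53), trialset)
  s <- model_free_summary(coh$choices, trialset)
  j <- dplyr::inner_join(coh$truth, s, by = c("participant_id", "phase",
                                              "domain"))
  ct <- cor.test(j$beta, j$ambiguity_attitude, method = "spearman",
                 exact = FALSE)
  expect_lt(ct$estimate, -0.3)
  expect_lt(ct$p.value, 1e-6)
})
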