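trialset <- build_trialset(0)

roster <- function(ids, workers, ages1, ages2 = NULL) {
  p1 <- tibble::tibble(participant_id = ids, phase = 1L, age = ages1,
                       mturk_like_id = workers)
  if (is.null(ages2)) return(p1)
  dplyr::bind_rows(p1, tibble::tibble(participant_id = ids, phase = 2L,
                                      age = ages2, mturk_like_id = workers))
}

test_that("duplicate worker IDs exclude every sharer", {
  r <- roster(c("a", "b", "c"), c("W1", "W1", "W2"), c(30, 40, 50))
  ex <- filter_duplicate_ids(r)
  expect_equal(sort(ex$participant_id), c("a", "b"))
  expect_equal(unique(ex$rule), "duplicate_id")
  expect_equal(nrow(filter_duplicate_ids(
    roster(c("a", "b"), c("W1", "W2"), c(30, 40)))), 0L)
})

test_that("age gap rule is strict at the 2-year threshold, phase 2 only", {
  r <- roster(c("a", "b", "c"), c("W1", "W2", "W3"),
              ages1 = c(50, 50, 50), ages2 = c(53, 52, 50))
  ex <- filter_age_gap(r)
  expect_equal(ex$participant_id, "a") # gap 3 fires
  expect_equal(ex$phase, 2L)           # only the follow-up is dropped
  # gap 2 ("b") and gap 0 ("c") are retained
  expect_false(any(c("b", "c") %in% ex$participant_id))
})

test_that("catch-trial rule fires above 50%, per domain and phase", {
  catch <- dplyr::filter(trialset, is_reference_equal, domain == "monetary")
  mk <- function(n_uncertain) tibble::tibble(
    participant_id = "p", phase = 1L, trial_id = catch$trial_id,
    chose_lottery = seq_len(7) <= n_uncertain)
  expect_equal(nrow(filter_catch_trials(mk(4), trialset)), 1L) # 4/7 > 50%
  expect_equal(nrow(filter_catch_trials(mk(3), trialset)), 0L) # 3/7 retained
  expect_equal(nrow(filter_catch_trials(mk(0), trialset)), 0L)
  ex <- filter_catch_trials(mk(7), trialset)
  expect_equal(ex$domain, "monetary") # scoped to the offending domain
  expect_error(
    filter_catch_trials(mk(4), dplyr::filter(trialset, !is_reference_equal)),
    "catch")
})

test_that("never-uncertain rule flags all-reference units for modeling only", {
  trm <- dplyr::filter(trialset, domain == "monetary")
  all_ref <- tibble::tibble(participant_id = "p", phase = 1L,
                            trial_id = trm$trial_id, chose_lottery = FALSE)
  one_lot <- all_ref
  one_lot$chose_lottery[which(!trm$is_reference_equal)[1]] <- TRUE
  expect_equal(nrow(filter_never_uncertain(all_ref, trialset)), 1L)
  expect_equal(nrow(filter_never_uncertain(one_lot, trialset)), 0L)

  ds <- list(trials = trialset, choices = all_ref, participants = NULL)
  res <- apply_exclusions(ds)
  expect_equal(nrow(res$modelfree_choices), nrow(all_ref)) # kept model-free
  expect_equal(nrow(res$modeling_choices), 0L)             # dropped for fits
})

test_that("filters on a planted cohort fire at least their planted counts", {
  coh <- simulate_cohort(
    cohort_spec(60, aberrant_fractions = c(catch_failer = 0.1,
                                           never_uncertain = 0.05,
                                           duplicate_id = 0.05),
                seed = 31), trialset)
  res <- apply_exclusions(cohort_dataset(coh, trialset))
  tally <- res$tally
  get <- function(r) {
    n <- tally$n_excluded[tally$rule == r]
    if (length(n) == 0) 0L else n
  }
  # catch failers: 6 agents x 2 phases x 2 domains
  expect_gte(get("catch_trial"), 24L)
  expect_gte(get("never_uncertain"), 12L)
  expect_gte(get("duplicate_id"), 3L * 2L) # sharers include their partners
})

test_that("retained sets are idempotent and order-insensitive", {
  coh <- simulate_cohort(
    cohort_spec(30, aberrant_fractions = c(catch_failer = 0.1,
                                           never_uncertain = 0.1),
                seed = 37), trialset)
  ds <- cohort_dataset(coh, trialset)
  res1 <- apply_exclusions(ds)
  # re-applying to the already-filtered choices changes nothing
  ds2 <- ds
  ds2$choices <- res1$modelfree_choices
  res2 <- apply_exclusions(ds2)
  expect_identical(res2$modelfree_choices, res1$modelfree_choices)
  expect_identical(
    dplyr::arrange(res1$modeling_choices, participant_id, phase, trial_id),
    dplyr::arrange(res2$modeling_choices, participant_id, phase, trial_id))
})
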