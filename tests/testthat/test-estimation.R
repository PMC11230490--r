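trialset <- build_trialset(0)
trm <- dplyr::filter(trialset, domain == "monetary")

test_that("start grid enumerates the published ranges by half steps", {
  g <- make_start_grid()
  expect_equal(sort(unique(g$alpha)),
               c(0.01, 0.51, 1.01, 1.51, 2.01, 2.51, 3.01, 3.51))
  expect_equal(sort(unique(g$beta)), seq(-2, 2, by = 0.5))
  expect_equal(sort(unique(g$gamma)), c(0.01, 0.51))
  expect_equal(nrow(g), 144L)
  expect_equal(g$start_index, seq_len(144L))
  expect_error(make_start_grid(alpha_range = c(2, 1)), "empty range")
})

test_that("fit keeps the optimizer contract and is deterministic", {
  ch <- simulate_agent_choices(0.8, 0.3, 3, trm, seed = 59)
  f1 <- fit_participant(ch$chose_lottery, trm)
  # the returned NLL is the best over starts and beats the NLL at every
  # grid start point
  expect_equal(f1$nll, min(f1$start_nll))
  g <- make_start_grid()
  nll_at_starts <- mapply(function(a, b, gm)
    negative_log_likelihood(a, b, gm, ch$chose_lottery, trm),
    g$alpha[seq(1, 144, 9)], g$beta[seq(1, 144, 9)], g$gamma[seq(1, 144, 9)])
  expect_true(all(f1$nll <= nll_at_starts + 1e-9))
  expect_equal(f1$reported_ambiguity_attitude, -f1$beta_hat)
  expect_gte(f1$nll, 0)

  f2 <- fit_participant(ch$chose_lottery, trm)
  expect_identical(glance(f1), glance(f2))

  # trial order does not change the estimate
  perm <- sample(nrow(trm))
  f3 <- fit_participant(ch$chose_lottery[perm], trm[perm, ])
  expect_equal(f3$alpha_hat, f1$alpha_hat, tolerance = 1e-5)
  expect_equal(f3$beta_hat, f1$beta_hat, tolerance = 1e-5)
})

test_that("simplex solution is not beaten by an independent optimizer", {
  set.seed(61)
  for (k in 1:3) {
    ch <- simulate_agent_choices(runif(1, 0.4, 1.2), runif(1, -0.5, 1),
                                 runif(1, 1, 6), trm, seed = 70 + k)
    f <- fit_participant(ch$chose_lottery, trm)
    obj <- function(x)
      negative_log_likelihood(max(exp(x[1]), 1e-12), x[2],
                              max(exp(x[3]), 1e-12), ch$chose_lottery, trm)
    best <- Inf
    for (i in seq(1, 144, by = 16)) {
      g <- make_start_grid()[i, ]
      o <- stats::optim(c(log(g$alpha), g$beta, log(g$gamma)), obj,
                        control = list(reltol = 1e-10, maxit = 5000))
      best <- min(best, o$value)
    }
    expect_lte(f$nll, best + 1e-4)
  }
})

test_that("true parameters are recovered at large trial counts", {
  trbig <- trm[rep(seq_len(49), length.out = 4000), ]
  trbig$trial_id <- seq_len(nrow(trbig))
  set.seed(67)
  p <- predict_choice_probability(trbig, 0.8, 0.6, 3, "ordinal")
  ch <- runif(nrow(trbig)) < p
  f <- fit_participant(ch, trbig)
  expect_equal(f$alpha_hat, 0.8, tolerance = 0.06)
  expect_equal(f$beta_hat, 0.6, tolerance = 0.12)
  expect_equal(f$gamma_hat, 3, tolerance = 0.45)
})

test_that("risky trials alone recover alpha for ambiguity-neutral agents", {
  # for a beta = 0 agent the ambiguous trials carry no extra information
  # about alpha, so a risky-only fit agrees with the full-data fit up to
  # sampling noise
  trm_big <- trm[rep(seq_len(49), 30), ]
  trm_big$trial_id <- seq_len(nrow(trm_big))
  set.seed(73)
  p <- predict_choice_probability(trm_big, 0.8, 0, 3, "ordinal")
  ch <- runif(nrow(trm_big)) < p
  risky <- trm_big$uncertainty_type == "risk"
  f_all <- fit_participant(ch, trm_big)
  f_risk <- fit_participant(ch[risky], trm_big[risky, ])
  expect_equal(f_risk$alpha_hat, f_all$alpha_hat, tolerance = 0.1)
  expect_equal(f_all$alpha_hat, 0.8, tolerance = 0.1)
})

test_that("unfittable inputs raise the documented errors", {
  expect_error(fit_participant(rep(FALSE, 49), trm), "never chose")
  expect_error(fit_participant(rep(TRUE, 5), trm[1:5, ]), "at least 10")
})

test_that("fit_cohort fits each retained unit and records failures", {
  coh <- simulate_cohort(
    cohort_spec(6, aberrant_fractions = c(never_uncertain = 0.2), seed = 71),
    trialset)
  fits <- fit_cohort(cohort_dataset(coh, trialset))
  roles <- dplyr::distinct(coh$truth, participant_id, role)
  n_never <- sum(roles$role == "never_uncertain")
  expect_gte(n_never, 2L)
  # never-uncertain units are absent; remaining units fit cleanly
  expect_false(any(fits$participant_id %in%
                     roles$participant_id[roles$role == "never_uncertain"]))
  expect_true(all(is.na(fits$error)))
  expect_equal(fits$bic, 2 * fits$nll + 3 * log(fits$n_trials))
  expect_lte(nrow(fits), (6 - n_never) * 4L)
})
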