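#' Distribution specification for a generative parameter
#'
#' @param dist `"lnorm"`, `"norm"` or `"const"`.
#' @param ... Parameters: `meanlog`/`sdlog` (lnorm), `mean`/`sd` (norm),
#'   `value` (const).
#' @return A list usable in [cohort_spec()].
#' @export
#' @examples
#' param_dist("lnorm", meanlog = log(0.7), sdlog = 0.5)
param_dist <- function(dist = c("lnorm", "norm", "const"), ...) {
  dist <- match.arg(dist)
  structure(c(list(dist = dist), list(...)), class = "ordival_dist")
}

dist_quantile <- function(d, u) {
  switch(d$dist,
    lnorm = stats::qlnorm(u, d$meanlog, d$sdlog),
    norm  = stats::qnorm(u, d$mean, d$sd),
    const = rep(d$value, length(u)))
}

#' Specify a synthetic two-phase cohort
#'
#' Describes the generative population for the simulator: marginal
#' distributions of the agent parameters (utility curvature `alpha`,
#' ambiguity attitude `beta`, choice noise `gamma`), rank-correlation targets
#' coupling each parameter across the two outcome domains and across the two
#' study phases, fractions of aberrant agents planted to trigger each
#' exclusion rule, and the rating-generation settings. Defaults describe a
#' mildly risk- and ambiguity-averse online population: `alpha` lognormal
#' with median 0.7, `beta` normal(0.3, 0.5), `gamma` lognormal with median
#' 4.5 (calibrated so simulated cohorts reproduce the strong observed
#' coupling between fitted risk attitudes and risky-choice proportions),
#' moderate cross-domain (0.4) and cross-phase (0.5) parameter
#' persistence, and ratings that are a noisy linear map of the ordinal codes
#' onto the 0-10 scale.
#'
#' @param n_agents Number of agents (>= 1).
#' @param alpha_dist,beta_dist,gamma_dist [param_dist()] marginals.
#' @param cross_domain_rho,cross_phase_rho Spearman targets in (-0.99, 0.99),
#'   either a scalar applied to all three parameters or a named vector with
#'   entries `alpha`, `beta`, `gamma`.
#' @param aberrant_fractions Named list/vector with `catch_failer`,
#'   `never_uncertain`, `duplicate_id` fractions; values in `[0, 1]`, sum < 1.
#' @param rating_exponent Shape of the ordinal-to-rating map
#'   `10 * (ordinal / 4)^exponent`; 1 (default) is the linear map
#'   `2.5 * ordinal`.
#' @param rating_noise_sd SD of the additive rating noise (ratings are then
#'   clipped to `[0, 10]`).
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `ordival_cohort_spec`.
#' @export
cohort_spec <- function(n_agents,
                        alpha_dist = param_dist("lnorm", meanlog = log(0.7), sdlog = 0.5),
                        beta_dist  = param_dist("norm", mean = 0.3, sd = 0.5),
                        gamma_dist = param_dist("lnorm", meanlog = log(4.5), sdlog = 0.5),
                        cross_domain_rho = 0.4,
                        cross_phase_rho = 0.5,
                        aberrant_fractions = c(catch_failer = 0,
                                               never_uncertain = 0,
                                               duplicate_id = 0),
                        rating_exponent = 1,
                        rating_noise_sd = 0.8,
                        seed = 0L) {
  stopifnot(n_agents >= 1)
  expand_rho <- function(r, what) {
    if (length(r) == 1L && is.null(names(r))) {
      r <- c(alpha = unname(r), beta = unname(r), gamma = unname(r))
    }
    stopifnot(all(c("alpha", "beta", "gamma") %in% names(r)))
    if (any(abs(r) > 0.99)) {
      stop("infeasible ", what, " correlation target (|rho| > 0.99)",
           call. = FALSE)
    }
    r[c("alpha", "beta", "gamma")]
  }
  af <- unlist(aberrant_fractions)
  miss <- setdiff(c("catch_failer", "never_uncertain", "duplicate_id"), names(af))
  af[miss] <- 0
  stopifnot(all(af >= 0), all(af <= 1), sum(af) < 1)
  structure(list(
    n_agents = as.integer(n_agents),
    alpha_dist = alpha_dist, beta_dist = beta_dist, gamma_dist = gamma_dist,
    cross_domain_rho = expand_rho(cross_domain_rho, "cross-domain"),
    cross_phase_rho = expand_rho(cross_phase_rho, "cross-phase"),
    aberrant_fractions = af[c("catch_failer", "never_uncertain", "duplicate_id")],
    rating_exponent = rating_exponent, rating_noise_sd = rating_noise_sd,
    seed = as.integer(seed)), class = "ordival_cohort_spec")
}

# Latent Gaussian correlation giving a target Spearman rho under a Gaussian
# copula: r = 2 sin(pi * rho_s / 6), so the planted rank correlation is met
# exactly in expectation.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Sample one parameter for all agents across the 4 units
# (monetary/medical x phase 1/2) from a Gaussian copula whose correlation is
# the Kronecker product of a 2x2 phase block and a 2x2 domain block; direct
# cross-domain and cross-phase edges then carry exactly the requested
# Spearman targets, and the diagonal (domain and phase both differ) edge
# carries their product.
sample_param_units <- function(n, dist, rho_domain, rho_phase) {
  rd <- spearman_to_pearson(rho_domain)
  rp <- spearman_to_pearson(rho_phase)
  R <- kronecker(matrix(c(1, rp, rp, 1), 2), matrix(c(1, rd, rd, 1), 2))
  L <- chol(R)
  z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% L
  u <- stats::pnorm(z)
  # columns: monetary.p1, medical.p1, monetary.p2, medical.p2
  matrix(dist_quantile(dist, as.vector(u)), n, 4L)
}

sample_truth <- function(spec) {
  n <- spec$n_agents
  pars <- list(alpha = spec$alpha_dist, beta = spec$beta_dist,
               gamma = spec$gamma_dist)
  # row order matches the copula unit columns (mon.p1, med.p1, mon.p2,
  # med.p2) repeated per agent
  out <- tibble::tibble(
    agent = rep(seq_len(n), each = 4L),
    phase = rep(c(1L, 1L, 2L, 2L), n),
    domain = rep(c("monetary", "medical"), 2L * n))
  for (p in names(pars)) {
    m <- sample_param_units(n, pars[[p]],
                            spec$cross_domain_rho[[p]],
                            spec$cross_phase_rho[[p]])
    out[[p]] <- as.vector(t(m))
  }
  out
}

assign_roles <- function(spec) {
  n <- spec$n_agents
  af <- spec$aberrant_fractions
  counts <- ceiling(af * n)
  roles <- rep("normal", n)
  idx <- sample.int(n) # seeded by caller
  take <- 0L
  for (r in names(counts)) {
    if (counts[[r]] > 0L) {
      roles[idx[take + seq_len(counts[[r]])]] <- r
      take <- take + counts[[r]]
    }
  }
  roles
}

#' Simulate one agent's choices on a single-domain trial slice
#'
#' Generative direction of the model: for every trial the lottery is chosen
#' with its softmax probability under the agent's `(alpha, beta, gamma)` and
#' the ordinal outcome values.
#'
#' @param alpha,beta,gamma Agent parameters.
#' @param trials Trials from one domain (error if empty or mixed-domain).
#' @param seed Integer seed; identical inputs give identical choices.
#' @return Tibble with `trial_id`, `chose_lottery`.
#' @export
#' @examples
#' tr <- dplyr::filter(build_trialset(0), domain == "monetary")
#' simulate_agent_choices(0.8, 0.3, 2, tr, seed = 1)
simulate_agent_choices <- function(alpha, beta, gamma, trials, seed = 0L) {
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  if (dplyr::n_distinct(trials$domain) != 1L) {
    stop("trials must come from a single domain", call. = FALSE)
  }
  p <- predict_choice_probability(trials, alpha, beta, gamma, "ordinal")
  set.seed(substream_seed(seed, "agent_choices"))
  tibble::tibble(trial_id = trials$trial_id,
                 chose_lottery = stats::runif(nrow(trials)) < p)
}

#' Simulate a full two-phase synthetic cohort
#'
#' Draws agent parameters from the spec's marginals coupled by a Gaussian
#' copula so that each parameter's rank correlation across domains and
#' phases matches the planted targets, simulates every agent's 98 choices in
#' both phases from the softmax model, generates monotone noisy 0-10 outcome
#' ratings, and plants aberrant agents that deterministically trigger the
#' exclusion rules: catch failers choose the uncertain option on every
#' reference-equal catch trial, never-uncertain agents always take the
#' reference, and duplicate-ID agents share a worker ID with another agent.
#'
#' @param spec A [cohort_spec()].
#' @param trialset Trials from [build_trialset()].
#' @return A list of class `ordival_cohort` with tibbles `choices`
#'   (`participant_id`, `phase`, `trial_id`, `chose_lottery`), `ratings`
#'   (`participant_id`, `phase`, `domain`, `outcome_ordinal`, `rating`),
#'   `participants` (`participant_id`, `phase`, `age`, `mturk_like_id`) and
#'   `truth` (generative parameters and planted role per participant x
#'   phase x domain).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(5, seed = 1), build_trialset(0))
#' nrow(coh$choices) # 5 agents x 2 phases x 98 trials
simulate_cohort <- function(spec, trialset) {
  stopifnot(inherits(spec, "ordival_cohort_spec"))
  n <- spec$n_agents
  ids <- sprintf("P%04d", seq_len(n))

  set.seed(substream_seed(spec$seed, "cohort_params"))
  truth <- sample_truth(spec)
  roles <- assign_roles(spec)
  truth$participant_id <- ids[truth$agent]
  truth$role <- roles[truth$agent]
  truth <- dplyr::select(truth, "participant_id", "phase", "domain",
                         "alpha", "beta", "gamma", "role")

  # worker IDs: unique except for planted duplicates, which reuse the worker
  # ID of a non-duplicate partner (cycled in index order)
  worker <- sprintf("W%06d", seq_len(n) * 7L + 13L)
  dup <- which(roles == "duplicate_id")
  if (length(dup) > 0L) {
    partners <- setdiff(seq_len(n), dup)
    worker[dup] <- worker[partners[(seq_along(dup) - 1L) %% length(partners) + 1L]]
  }

  set.seed(substream_seed(spec$seed, "ages"))
  age1 <- pmin(pmax(round(stats::rnorm(n, 49.4, 14.8)), 20L), 80L)
  age2 <- age1 + sample(0:1, n, replace = TRUE)
  participants <- tibble::tibble(
    participant_id = rep(ids, 2L), phase = rep(1:2, each = n),
    age = c(age1, age2), mturk_like_id = rep(worker, 2L))

  # choices: one vectorized pass over truth x that domain's trials
  set.seed(substream_seed(spec$seed, "choices"))
  choices <- dplyr::inner_join(truth, trialset, by = "domain",
                               relationship = "many-to-many")
  p <- predict_choice_probability(choices, choices$alpha, choices$beta,
                                  choices$gamma, "ordinal")
  choices$chose_lottery <- stats::runif(nrow(choices)) < p
  choices$chose_lottery[choices$role == "never_uncertain"] <- FALSE
  fail <- choices$role == "catch_failer" & choices$is_reference_equal
  choices$chose_lottery[fail] <- TRUE
  choices <- dplyr::select(choices, "participant_id", "phase", "trial_id",
                           "chose_lottery")
  choices <- dplyr::arrange(choices, .data$participant_id, .data$phase,
                            .data$trial_id)

  set.seed(substream_seed(spec$seed, "ratings"))
  ratings <- tidyr::crossing(participant_id = ids, phase = 1:2,
                             domain = c("monetary", "medical"),
                             outcome_ordinal = 0:4)
  mu <- 10 * (ratings$outcome_ordinal / 4)^spec$rating_exponent
  # stored to 1e-6: survey-scale precision, and the CSV representation
  # round-trips bit-identically
  ratings$rating <- round(pmin(pmax(mu + stats::rnorm(nrow(ratings),
                                                      sd = spec$rating_noise_sd),
                                    0), 10), 6)

  structure(list(choices = choices, ratings = ratings,
                 participants = participants, truth = truth,
                 spec = spec),
            class = "ordival_cohort")
}

#' @export
print.ordival_cohort <- function(x, ...) {
  cat("Synthetic two-phase cohort:", x$spec$n_agents, "agents,",
      nrow(x$choices), "choice records\n")
  tab <- table(x$truth$role[!duplicated(x$truth$participant_id)])
  cat("roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
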