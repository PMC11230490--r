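exclusion_row <- function(rule, participant_id, phase, domain, detail) {
  tibble::tibble(rule = rule, participant_id = participant_id,
                 phase = as.integer(phase), domain = domain, detail = detail)
}

empty_exclusions <- function() {
  tibble::tibble(rule = character(), participant_id = character(),
                 phase = integer(), domain = character(), detail = character())
}

#' Exclude participants with duplicate worker IDs
#'
#' Every participant sharing a worker identification number with another is
#' excluded entirely (all phases, both domains), mirroring the handling of
#' duplicate MTurk IDs in online cohorts.
#'
#' @param participants Tibble with `participant_id`, `phase` and
#'   `mturk_like_id` (falls back to `participant_id` when absent).
#' @return Exclusion rows (`rule`, `participant_id`, `phase`, `domain`,
#'   `detail`), one per firing.
#' @export
filter_duplicate_ids <- function(participants) {
  p1 <- dplyr::filter(participants, .data$phase == 1L)
  id <- p1$mturk_like_id %||% p1$participant_id
  shared <- id[duplicated(id)]
  hit <- p1[id %in% shared, ]
  if (nrow(hit) == 0L) return(empty_exclusions())
  exclusion_row("duplicate_id", hit$participant_id, 1L, "all",
                paste0("worker id ", (hit$mturk_like_id %||% hit$participant_id),
                       " shared"))
}

#' Exclude follow-up records with an implausible age gap
#'
#' Phase-2 data are excluded when the reported age differs from the phase-1
#' age by strictly more than `threshold_years` (a 9-month inter-phase
#' interval permits legitimate gaps of 0-1 years; "exceeding" the 2-year
#' threshold is read as a strict inequality, so a gap of exactly 2 is
#' retained). Only the follow-up session is removed.
#'
#' @param participants Tibble with `participant_id`, `phase`, `age`.
#' @param threshold_years Strict threshold in years (default 2).
#' @return Exclusion rows, one per phase-2 firing.
#' @export
filter_age_gap <- function(participants, threshold_years = 2) {
  wide <- tidyr::pivot_wider(
    dplyr::distinct(participants, .data$participant_id, .data$phase, .data$age),
    names_from = "phase", values_from = "age", names_prefix = "age")
  if (!all(c("age1", "age2") %in% names(wide))) return(empty_exclusions())
  wide <- dplyr::filter(wide, !is.na(.data$age1), !is.na(.data$age2),
                        abs(.data$age2 - .data$age1) > threshold_years)
  if (nrow(wide) == 0L) return(empty_exclusions())
  exclusion_row("age_gap", wide$participant_id, 2L, "all",
                sprintf("age gap %g > %g years", abs(wide$age2 - wide$age1),
                        threshold_years))
}

#' Exclude participants who fail the catch trials
#'
#' Catch trials offer an uncertain lottery whose payoff equals the certain
#' reference; choosing the uncertain side often signals misunderstanding. A
#' participant's data in a domain and phase are excluded when they chose the
#' uncertain reference-equal option on strictly more than 50% of that
#' domain's catch trials (4 of 7 fires, 3 of 7 does not).
#'
#' @param choices Choice records (`participant_id`, `phase`, `trial_id`,
#'   `chose_lottery`).
#' @param trials Trial table flagging `is_reference_equal`.
#' @return Exclusion rows scoped to (participant, phase, domain).
#' @export
filter_catch_trials <- function(choices, trials) {
  catch <- dplyr::filter(trials, .data$is_reference_equal)
  if (nrow(catch) == 0L) stop("no catch trials in the trial set", call. = FALSE)
  by_dom <- dplyr::count(catch, .data$domain)
  if (any(!c("monetary", "medical") %in% by_dom$domain)) {
    stop("a domain has zero catch trials", call. = FALSE)
  }
  x <- dplyr::inner_join(choices, dplyr::select(catch, "trial_id", "domain"),
                         by = "trial_id")
  x <- dplyr::summarise(
    dplyr::group_by(x, .data$participant_id, .data$phase, .data$domain),
    n_catch = dplyr::n(), n_uncertain = sum(.data$chose_lottery),
    .groups = "drop")
  hit <- dplyr::filter(x, .data$n_uncertain / .data$n_catch > 0.5)
  if (nrow(hit) == 0L) return(empty_exclusions())
  exclusion_row("catch_trial", hit$participant_id, hit$phase, hit$domain,
                sprintf("chose uncertain on %d/%d catch trials",
                        hit$n_uncertain, hit$n_catch))
}

#' Flag participants who never chose an uncertain option
#'
#' A participant who always took the certain reference in a domain and phase
#' provides no information for model fitting (the likelihood is maximized on
#' the noise boundary), so they are excluded from the modeling stage only;
#' their model-free summaries are retained. Based on non-catch trials.
#'
#' @inheritParams filter_catch_trials
#' @return Exclusion rows scoped to (participant, phase, domain).
#' @export
filter_never_uncertain <- function(choices, trials) {
  value <- dplyr::filter(trials, !.data$is_reference_equal)
  x <- dplyr::inner_join(choices, dplyr::select(value, "trial_id", "domain"),
                         by = "trial_id")
  x <- dplyr::summarise(
    dplyr::group_by(x, .data$participant_id, .data$phase, .data$domain),
    n_lottery = sum(.data$chose_lottery), .groups = "drop")
  hit <- dplyr::filter(x, .data$n_lottery == 0L)
  if (nrow(hit) == 0L) return(empty_exclusions())
  exclusion_row("never_uncertain", hit$participant_id, hit$phase, hit$domain,
                "never chose the uncertain option (modeling stage only)")
}

#' Apply all exclusion rules to a dataset
#'
#' Runs the four rules and materializes two analysis sets: the model-free
#' set (duplicate-ID, age-gap and catch-trial exclusions applied) and the
#' modeling set (additionally removing never-uncertain units). Participant-
#' scoped rules (duplicate ID, age gap) remove both domains; catch-trial and
#' never-uncertain rules remove only the offending (phase, domain) unit. The
#' retained sets are invariant to the order the rules are applied in.
#'
#' @param dataset An `ordival_dataset` (or a list with `trials`, `choices`,
#'   `participants`).
#' @param age_threshold_years Passed to [filter_age_gap()].
#' @return A list with `exclusions` (all rows), `modelfree_choices` and
#'   `modeling_choices` (filtered choice tibbles), plus `tally` (rule counts).
#' @export
apply_exclusions <- function(dataset, age_threshold_years = 2) {
  excl <- dplyr::bind_rows(
    if (!is.null(dataset$participants)) filter_duplicate_ids(dataset$participants),
    if (!is.null(dataset$participants))
      filter_age_gap(dataset$participants, age_threshold_years),
    filter_catch_trials(dataset$choices, dataset$trials),
    filter_never_uncertain(dataset$choices, dataset$trials))
  if (nrow(excl) == 0L) excl <- empty_exclusions()

  drop_units <- function(choices, rows) {
    if (nrow(rows) == 0L) return(choices)
    ch <- dplyr::left_join(choices,
                           dplyr::select(dataset$trials, "trial_id", "domain"),
                           by = "trial_id")
    bad_all <- dplyr::filter(rows, .data$domain == "all")
    bad_dom <- dplyr::filter(rows, .data$domain != "all")
    keep <- rep(TRUE, nrow(ch))
    if (nrow(bad_all) > 0L) {
      # duplicate-id rows (phase 1, domain "all") remove the participant
      # everywhere; age-gap rows remove only phase 2
      dup <- dplyr::filter(bad_all, .data$rule == "duplicate_id")
      age <- dplyr::filter(bad_all, .data$rule != "duplicate_id")
      keep <- keep & !(ch$participant_id %in% dup$participant_id)
      keep <- keep & !(paste(ch$participant_id, ch$phase) %in%
                         paste(age$participant_id, age$phase))
    }
    if (nrow(bad_dom) > 0L) {
      keep <- keep & !(paste(ch$participant_id, ch$phase, ch$domain) %in%
                         paste(bad_dom$participant_id, bad_dom$phase,
                               bad_dom$domain))
    }
    choices[keep, ]
  }

  mf <- drop_units(dataset$choices,
                   dplyr::filter(excl, .data$rule != "never_uncertain"))
  mb <- drop_units(dataset$choices, excl)
  list(exclusions = excl,
       modelfree_choices = mf,
       modeling_choices = mb,
       tally = dplyr::count(excl, .data$rule, name = "n_excluded"))
}
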