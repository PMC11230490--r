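trial_cols <- readr::cols(
  trial_id = readr::col_integer(), domain = readr::col_character(),
  uncertainty_type = readr::col_character(),
  win_probability = readr::col_double(), ambiguity_level = readr::col_double(),
  outcome_ordinal = readr::col_integer(), outcome_label = readr::col_character(),
  win_color = readr::col_character(), is_reference_equal = readr::col_logical(),
  replicate = readr::col_integer())

choice_cols <- readr::cols(
  participant_id = readr::col_character(), phase = readr::col_integer(),
  trial_id = readr::col_integer(), chose_lottery = readr::col_logical())

rating_cols <- readr::cols(
  participant_id = readr::col_character(), phase = readr::col_integer(),
  domain = readr::col_character(), outcome_ordinal = readr::col_integer(),
  rating = readr::col_double())

participant_cols <- readr::cols(
  participant_id = readr::col_character(), phase = readr::col_integer(),
  age = readr::col_double(), mturk_like_id = readr::col_character())

read_table_checked <- function(path, spec, what) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  # a missing column is reported as our own error below, not readr's warning
  x <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                        progress = FALSE))
  need <- names(spec$cols)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L && !identical(miss, "replicate")) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0L) {
    stop(what, ": unparseable value at row ", prob$row[1L], ", column ",
         prob$col[1L], call. = FALSE)
  }
  x
}

#' Write the tabular components of a study dataset to CSV
#'
#' Booleans are serialized as `true`/`false` literals, probabilities as
#' decimals in `[0, 1]`, all files UTF-8 with a header row, so canonical
#' files round-trip bit-identically through [load_dataset()].
#'
#' @param dataset A list with any of `trials`, `choices`, `ratings`,
#'   `participants` (e.g. from [simulate_cohort()] plus the trial set).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  write_one <- function(df, name) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.logical),
                                          ~ ifelse(.x, "true", "false")))
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    p
  }
  for (nm in c("trials", "choices", "ratings", "participants", "truth")) {
    if (!is.null(dataset[[nm]])) paths[nm] <- write_one(dataset[[nm]], nm)
  }
  invisible(paths)
}

#' Load and validate a study dataset from CSV files
#'
#' Reads trials, choices, ratings and participants, checks referential
#' integrity (every choice must reference a known trial and a known
#' participant-phase), and returns an analysis-ready list. In strict mode an
#' orphan reference is an error naming the offending row; in lax mode orphan
#' rows are dropped and counted in the `dropped` attribute plus a message.
#'
#' @param paths Named list/vector with `trials`, `choices`, and optionally
#'   `ratings`, `participants`.
#' @param strict Fail on orphan references (default `TRUE`).
#' @return A list of class `ordival_dataset` with tibbles `trials`,
#'   `choices`, `ratings`, `participants` and attribute `dropped`.
#' @export
load_dataset <- function(paths, strict = TRUE) {
  trials <- read_table_checked(paths[["trials"]], trial_cols, "trials")
  choices <- read_table_checked(paths[["choices"]], choice_cols, "choices")
  ratings <- if (!is.null(paths[["ratings"]]) && file.exists(paths[["ratings"]]))
    read_table_checked(paths[["ratings"]], rating_cols, "ratings") else NULL
  participants <- if (!is.null(paths[["participants"]]) &&
                      file.exists(paths[["participants"]]))
    read_table_checked(paths[["participants"]], participant_cols,
                       "participants") else NULL

  if (!all(choices$phase %in% c(1L, 2L))) {
    stop("choices: phase must be 1 or 2", call. = FALSE)
  }
  orphan <- !(choices$trial_id %in% trials$trial_id)
  if (!is.null(participants)) {
    known <- paste(participants$participant_id, participants$phase)
    orphan <- orphan | !(paste(choices$participant_id, choices$phase) %in% known)
  }
  dropped <- sum(orphan)
  if (dropped > 0L) {
    if (strict) {
      stop("choices: orphan reference at row ", which(orphan)[1L],
           " (trial_id ", choices$trial_id[which(orphan)[1L]], ")",
           call. = FALSE)
    }
    message("load_dataset: dropped ", dropped, " orphan choice row(s)")
    choices <- choices[!orphan, ]
  }
  structure(list(trials = trials, choices = choices, ratings = ratings,
                 participants = participants),
            dropped = dropped, class = "ordival_dataset")
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A named list validated for the keys [run_pipeline()] understands.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}
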