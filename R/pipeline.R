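default_run_config <- function() {
  list(
    seed = 0L,
    outdir = "ordival_run",
    stages = c("simulate", "filter", "modelfree", "fit", "compare",
               "correlate"),
    trial_seed = 0L,
    cohort = list(n_agents = 50L,
                  cross_domain_rho = 0.4, cross_phase_rho = 0.5,
                  aberrant_fractions = list(catch_failer = 0,
                                            never_uncertain = 0,
                                            duplicate_id = 0)),
    model = list(variant = "ordinal"),
    grid = list(step = 0.5),
    cv = list(k = 5L),
    paths = NULL)
}

validate_run_config <- function(cfg) {
  base <- default_run_config()
  known <- names(base)
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown run-config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(base, cfg)
  stopifnot(is.numeric(out$seed), length(out$seed) == 1L)
  if (!all(out$stages %in% base$stages)) {
    stop("unknown stage(s): ",
         paste(setdiff(out$stages, base$stages), collapse = ", "),
         call. = FALSE)
  }
  if (!out$model$variant %in% c("ordinal", "rating")) {
    stop("model.variant must be 'ordinal' or 'rating'", call. = FALSE)
  }
  out
}

config_hash <- function(cfg) {
  # where artifacts land does not change what they contain
  cfg$outdir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (k in utf8ToInt(as.character(s))) h <- ((h * 16777619) + k) %% 2^32
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4),
         format(as.hexmode(as.integer(h %% 65536)), width = 4))
}

write_stage_csv <- function(df, outdir, name) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.logical),
                                        ~ ifelse(.x, "true", "false")))
  readr::write_csv(df, file.path(outdir, paste0(name, ".csv")),
                   progress = FALSE)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> filter -> modelfree -> fit -> compare ->
#' correlate from a single validated run config, with one global seed fanned
#' out to stage-specific sub-seeds (adding a stage never perturbs earlier
#' stages' randomness). Each stage writes its CSV artifact into `outdir`; a
#' `manifest.json` records the config, its hash, the seed and the stages
#' run, and a `summary.txt` gives a human-readable recap. When
#' `config$paths` points at externally supplied trials/choices CSVs, the
#' simulate stage is skipped and the pipeline starts from the filter stage.
#' A stage failure aborts with the failing stage named; artifacts of
#' completed stages are retained.
#'
#' @param config Named list (see [read_run_config()]); missing keys take
#'   defaults.
#' @return Invisibly, a list with the outdir, the manifest, and the in-memory
#'   stage results.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 1, outdir = tempfile(),
#'                          cohort = list(n_agents = 4),
#'                          stages = c("simulate", "filter", "modelfree")))
#' names(res$results)
#' }
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  done <- character(0)
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, name)
    res
  }

  trials <- build_trialset(cfg$trial_seed)

  if (!is.null(cfg$paths)) {
    dataset <- load_dataset(cfg$paths, strict = FALSE)
    trials <- dataset$trials
    cfg$stages <- setdiff(cfg$stages, "simulate")
  } else {
    cohort <- stage("simulate", function() {
      spc <- cohort_spec(
        n_agents = cfg$cohort$n_agents,
        cross_domain_rho = cfg$cohort$cross_domain_rho %||% 0.4,
        cross_phase_rho = cfg$cohort$cross_phase_rho %||% 0.5,
        aberrant_fractions = unlist(cfg$cohort$aberrant_fractions %||%
                                      c(catch_failer = 0)),
        seed = substream_seed(cfg$seed, "cohort"))
      simulate_cohort(spc, trials)
    })
    if (is.null(cohort)) stop("no input data: enable the simulate stage or supply paths",
                              call. = FALSE)
    dataset <- c(list(trials = trials), cohort[c("choices", "ratings",
                                                 "participants", "truth")])
    write_dataset(dataset, cfg$outdir)
    results$cohort <- cohort
  }

  filt <- stage("filter", function() apply_exclusions(dataset))
  if (!is.null(filt)) {
    write_stage_csv(filt$exclusions, cfg$outdir, "exclusions")
    results$exclusions <- filt
  }
  mf_choices <- if (!is.null(filt)) filt$modelfree_choices else dataset$choices
  mb_choices <- if (!is.null(filt)) filt$modeling_choices else dataset$choices

  mf <- stage("modelfree", function()
    model_free_summary(mf_choices, trials))
  if (!is.null(mf)) {
    write_stage_csv(mf, cfg$outdir, "modelfree")
    results$modelfree <- mf
  }

  grid <- make_start_grid(step = cfg$grid$step %||% 0.5)
  fits <- stage("fit", function()
    fit_cohort(c(dataset, list(choices = mb_choices)),
               variant = cfg$model$variant, grid = grid, prefiltered = TRUE))
  if (!is.null(fits)) {
    write_stage_csv(fits, cfg$outdir, "fits")
    results$fits <- fits
  }

  comp <- stage("compare", function()
    compare_models(c(dataset, list(choices = mb_choices)),
                   k = cfg$cv$k %||% 5L,
                   seed = substream_seed(cfg$seed, "cv"), grid = grid,
                   prefiltered = TRUE))
  if (!is.null(comp)) {
    write_stage_csv(comp$comparison, cfg$outdir, "comparison")
    results$comparison <- comp
  }

  corr <- stage("correlate", function() {
    stopifnot(!is.null(mf))
    run_consistency_suite(mf, fits)
  })
  if (!is.null(corr)) {
    write_stage_csv(corr, cfg$outdir, "correlations")
    results$correlations <- corr
    if (!is.null(dataset$ratings)) {
      checks <- manipulation_checks(mf, dataset$ratings)
      write_stage_csv(checks, cfg$outdir, "checks")
      results$checks <- checks
    }
  }

  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   seed = cfg$seed, stages_run = done,
                   stages_skipped = setdiff(default_run_config()$stages, done),
                   package_version = as.character(utils::packageVersion("ordival")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(
    paste("ordival run", manifest$config_hash, "seed", cfg$seed),
    paste("stages:", paste(done, collapse = ", ")),
    paste("agents:", cfg$cohort$n_agents %||% NA),
    paste("artifacts in:", normalizePath(cfg$outdir))),
    file.path(cfg$outdir, "summary.txt"))
  invisible(list(outdir = cfg$outdir, manifest = manifest, results = results))
}
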