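# End-to-end pipeline: simulate/read -> derive -> analyze -> report.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (pre-existing cohort CSVs) or `simulate`
#' (generator settings) must be supplied. The configuration plus the seed
#' fully determines every output, and is echoed into the run manifest.
#'
#' @param input_dir directory with the four cohort CSVs, or `NULL`.
#' @param simulate list with `designs` (list of [study_design()]), `params`
#'   (a [sim_params()]) and `n_per_study`, or `NULL`.
#' @param thresholds a [cid_thresholds()] object.
#' @param contrast two arm labels for the headline comparison.
#' @param adjust covariate-adjust the headline Cox models (default `TRUE`).
#' @param strata_by_study stratify Cox baseline hazards by study (default
#'   `TRUE`).
#' @param subgroups run the subgroup forest (default `TRUE`).
#' @param seed integer seed for every random stream.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL,
                            thresholds = cid_thresholds(),
                            contrast = c("GLY", "TIO"),
                            adjust = TRUE, strata_by_study = TRUE,
                            subgroups = TRUE, seed = 1L) {
  if (is.null(input_dir) == is.null(simulate)) {
    stop("exactly one of 'input_dir' and 'simulate' must be provided")
  }
  if (!inherits(thresholds, "cid_thresholds")) {
    stop("'thresholds' must be a cid_thresholds object")
  }
  if (!is.null(simulate)) {
    for (nm in c("designs", "params", "n_per_study")) {
      if (is.null(simulate[[nm]])) stop("'simulate' needs a '", nm, "' entry")
    }
  }
  structure(list(input_dir = input_dir, simulate = simulate,
                 thresholds = thresholds, contrast = contrast,
                 adjust = isTRUE(adjust),
                 strata_by_study = isTRUE(strata_by_study),
                 subgroups = isTRUE(subgroups), seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

.km_table <- function(km) {
  data.frame(time = km$curve$time, n_risk = km$curve$n_risk,
             n_event = km$curve$n_event, survival = km$curve$survival,
             lower = km$curve$lower, upper = km$curve$upper)
}

#' Run the full CID analysis pipeline
#'
#' Simulates (or reads) a cohort, derives first/sustained CID results,
#' fits the headline treatment contrasts, and writes the reporting bundle to
#' `out_dir`: the cohort CSVs, `cid_results.csv`, `events_summary.csv` +
#' `events_tests.csv`, `at_event.csv`, `forest_first.csv` /
#' `forest_sustained.csv`, per-arm KM curve CSVs, `model_report.json` and a
#' `manifest.json` (seed, thresholds, settings, per-stage counts, package
#' version) sufficient to reproduce the run. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created, with a notice, if absent).
#' @return invisibly, a list with the in-memory objects (`cohort`, `cid`,
#'   `summary`, `at_event`, `forest`, `contrasts`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config object")
  }
  if (!dir.exists(out_dir)) {
    message("creating output directory: ", out_dir)
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      sm <- config$simulate
      pars <- sm$params
      pars$seed <- config$seed
      class(pars) <- "sim_params"
      simulate_cohort(sm$designs, pars, sm$n_per_study)
    } else {
      read_cohort(config$input_dir)
    }
  })
  message(sprintf("stage input: %d patients in, %d visit rows, %d exacerbations",
                  nrow(cohort$baseline), nrow(cohort$visits),
                  nrow(cohort$exacerbations)))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  cid <- stage("derive", derive_cid(cohort, config$thresholds))
  message(sprintf("stage derive: %d patients, %d first-CID events, %d sustained-CID events",
                  nrow(cid), sum(cid$first_cid_event),
                  sum(cid$sustained_cid_event)))
  utils::write.csv(cid, file.path(out_dir, "cid_results.csv"),
                   row.names = FALSE)

  summary <- stage("summarize", summarize_events(cid, cohort$baseline))
  utils::write.csv(summary$counts, file.path(out_dir, "events_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$tests, file.path(out_dir, "events_tests.csv"),
                   row.names = FALSE)

  at_event <- stage("at_event",
                    values_at_event(cid, cohort$visits, cohort$baseline))
  utils::write.csv(at_event, file.path(out_dir, "at_event.csv"),
                   row.names = FALSE)

  arms <- unique(cohort$baseline$arm)
  do_contrast <- all(config$contrast %in% arms)
  contrasts <- NULL
  if (do_contrast) {
    contrasts <- stage("analyze", list(
      first = fit_treatment_contrasts(cid, cohort$baseline, config$contrast,
                                      "first", adjust = config$adjust,
                                      strata_by_study = config$strata_by_study),
      sustained = fit_treatment_contrasts(cid, cohort$baseline, config$contrast,
                                          "sustained", adjust = config$adjust,
                                          strata_by_study = config$strata_by_study)
    ))
    for (ep in names(contrasts)) {
      for (a in config$contrast) {
        utils::write.csv(.km_table(contrasts[[ep]]$km[[a]]),
                         file.path(out_dir, sprintf("km_%s_%s.csv", ep, a)),
                         row.names = FALSE)
      }
    }
    report <- lapply(contrasts, function(ct) {
      list(endpoint = ct$endpoint, contrast = ct$contrast,
           hr = ct$hr, hr_lower = ct$hr_lower, hr_upper = ct$hr_upper,
           hr_p = ct$hr_p, logrank_chisq = ct$logrank$statistic,
           logrank_p = ct$logrank$p_value,
           cox_table = ct$cox$table, diagnostics = ct$cox$diagnostics,
           km_median = lapply(ct$km, function(k) {
             list(median = k$median, lower = k$median_lower,
                  upper = k$median_upper, q25 = k$q25, q75 = k$q75)
           }))
    })
    .write_json(report, file.path(out_dir, "model_report.json"))
  } else {
    message("stage analyze: contrast arms not all present; skipping contrasts")
  }

  forest <- NULL
  if (config$subgroups && do_contrast) {
    forest <- stage("report", {
      list(first = subgroup_forest(cid, cohort$baseline,
                                   contrast = config$contrast,
                                   endpoint = "first"),
           sustained = subgroup_forest(cid, cohort$baseline,
                                       contrast = config$contrast,
                                       endpoint = "sustained"))
    })
    utils::write.csv(forest$first, file.path(out_dir, "forest_first.csv"),
                     row.names = FALSE)
    utils::write.csv(forest$sustained,
                     file.path(out_dir, "forest_sustained.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "copdcid",
    version = as.character(utils::packageVersion("copdcid")),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    contrast = config$contrast,
    adjust = config$adjust,
    strata_by_study = config$strata_by_study,
    subgroups = config$subgroups,
    input = if (is.null(config$simulate)) {
      list(mode = "files", input_dir = config$input_dir)
    } else {
      list(mode = "simulate",
           n_per_study = as.list(config$simulate$n_per_study),
           # per-arm vectors as objects so their names survive JSON
           params = local({
             p <- unclass(config$simulate$params)
             for (nm in c("fev1_effect", "sgrq_effect", "exac_rate")) {
               p[[nm]] <- as.list(p[[nm]])
             }
             p
           }),
           designs = lapply(config$simulate$designs, function(d) {
             list(study_id = d$study_id, duration_weeks = d$duration_weeks,
                  visit_interval_weeks = d$visit_interval_weeks,
                  arms = as.list(d$arms))
           }))
    },
    counts = list(patients = nrow(cohort$baseline),
                  visit_rows = nrow(cohort$visits),
                  exacerbations = nrow(cohort$exacerbations),
                  first_cid_events = sum(cid$first_cid_event),
                  sustained_cid_events = sum(cid$sustained_cid_event))
  )
  .write_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, cid = cid, summary = summary,
                 at_event = at_event, forest = forest,
                 contrasts = contrasts, manifest = manifest))
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' A manifest written by [run_pipeline()] fully specifies a simulate-mode
#' run; replaying it reproduces every output byte-identically.
#'
#' @param manifest_path path to `manifest.json`.
#' @return a [pipeline_config()].
#' @export
config_from_manifest <- function(manifest_path) {
  # names of the per-arm vectors must survive the round trip, so parse
  # without simplification and unlist (which keeps list names)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  th <- do.call(cid_thresholds, lapply(m$thresholds, unlist))
  common <- list(thresholds = th, contrast = unlist(m$contrast),
                 adjust = isTRUE(m$adjust),
                 strata_by_study = isTRUE(m$strata_by_study),
                 subgroups = isTRUE(m$subgroups), seed = unlist(m$seed))
  if (identical(m$input$mode, "simulate")) {
    pars <- lapply(m$input$params, unlist)
    params <- do.call(sim_params, pars)
    designs <- lapply(m$input$designs, function(d) {
      study_design(d$study_id, d$duration_weeks, unlist(d$arms),
                   d$visit_interval_weeks)
    })
    do.call(pipeline_config, c(list(
      simulate = list(designs = designs, params = params,
                      n_per_study = unlist(m$input$n_per_study))), common))
  } else {
    do.call(pipeline_config, c(list(input_dir = m$input$input_dir), common))
  }
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()]: either an `input_dir` entry or a
#' `simulate` block (`designs` as a list of `{study_id, duration_weeks,
#' arms, visit_interval_weeks}`, `params` as [sim_params()] arguments,
#' `n_per_study` as a map), plus optional `thresholds`, `contrast`,
#' `adjust`, `strata_by_study`, `subgroups`, `seed`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(cid_thresholds, as.list(y$thresholds %||% list()))
  simulate <- NULL
  if (!is.null(y$simulate)) {
    pars <- as.list(y$simulate$params %||% list())
    for (nm in c("fev1_effect", "sgrq_effect", "exac_rate")) {
      if (!is.null(pars[[nm]])) pars[[nm]] <- unlist(pars[[nm]])
    }
    designs <- lapply(y$simulate$designs, function(d) {
      study_design(d$study_id, d$duration_weeks, unlist(d$arms),
                   d$visit_interval_weeks %||% 4L)
    })
    simulate <- list(designs = designs, params = do.call(sim_params, pars),
                     n_per_study = unlist(y$simulate$n_per_study))
  }
  pipeline_config(
    input_dir = y$input_dir, simulate = simulate, thresholds = th,
    contrast = unlist(y$contrast %||% c("GLY", "TIO")),
    adjust = y$adjust %||% TRUE,
    strata_by_study = y$strata_by_study %||% TRUE,
    subgroups = y$subgroups %||% TRUE,
    seed = y$seed %||% 1L
  )
}
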