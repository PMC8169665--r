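# One-command orchestration: simulate (or load) -> preprocess -> fit ->
# analyse -> describe, with every stage's outputs and seeds captured in a
# run manifest so a run can be reproduced exactly.

#' Default pipeline configuration
#'
#' Demo-scale defaults: an 8-participant synthetic study at the
#' paper-like truth scale with default nuisance rates, and a reduced
#' sampler budget (3 chains, 400 + 400 sweeps) so the full pipeline runs
#' in minutes. Production analyses should raise `burn_in`/`draws` to the
#' reference settings (2000 + 2000).
#'
#' @param ... named overrides (nested lists are merged).
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    input_csv = NULL,           # fit this CSV instead of simulating
    simulate = list(n_participants = 8, scenario = "paper",
                    trials_per_condition = 40, n_blocks = 4,
                    nuisance = unclass(napt_nuisance())),
    preprocess = preprocess_config(),
    fit = list(chains = 3, burn_in = 400, draws = 400, thin = 1,
               gh_points = 5, eps = 1e-7, rhat_threshold = 1.1),
    ppc = list(probs = c(0.1, 0.3, 0.5, 0.7, 0.9), n_draws = 20))
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> fit -> analyse -> describe
#' and writes all outputs plus a run manifest to `out_dir`. Every stage is
#' seeded from `config$seed`, so a rerun with the same config reproduces
#' the same files.
#'
#' @param config configuration list from [pipeline_config()], or a path to
#'   a YAML/JSON file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return (invisibly) list with the in-memory results (`data`, `cleaned`,
#'   `report`, `fit`, `summary`, `contrasts`, `ppc`, `descriptives`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- Sys.time()
  timings <- list()
  files <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  emit <- function(key, path) { files[key] <<- path; path }

  # -- simulate or load -------------------------------------------------
  truth <- NULL
  if (is.null(config$input_csv)) {
    study <- stage("simulate", {
      sim <- config$simulate
      simulate_napt_study(
        n_participants = sim$n_participants, scenario = sim$scenario,
        trials_per_condition = sim$trials_per_condition,
        n_blocks = sim$n_blocks,
        nuisance = do.call(napt_nuisance, sim$nuisance),
        seed = config$seed)
    })
    data <- study$data
    truth <- study$truth
    paths <- write_napt(study, file.path(out_dir, "synthetic"),
                        seed = config$seed)
    for (k in names(paths)) emit(paste0("synthetic_", k), paths[[k]])
  } else {
    data <- stage("load", read.csv(config$input_csv))
  }

  # -- preprocess -------------------------------------------------------
  prep <- stage("preprocess", run_preprocessing(data, config$preprocess))
  write.csv(prep$data, emit("cleaned", file.path(out_dir, "cleaned.csv")),
            row.names = FALSE)
  write_exclusion_report(prep$report,
                         emit("exclusion_report",
                              file.path(out_dir, "exclusion_report.json")))

  # -- fit --------------------------------------------------------------
  fit <- stage("fit", {
    fc <- config$fit
    hdm(prep$data, chains = fc$chains, burn_in = fc$burn_in,
        draws = fc$draws, thin = fc$thin, seed = config$seed,
        gh_points = fc$gh_points, eps = fc$eps,
        rhat_threshold = fc$rhat_threshold)
  })
  write_draws(fit, emit("draws", file.path(out_dir, "draws.csv")))
  write.csv(data.frame(parameter = names(fit$rhat), rhat = fit$rhat),
            emit("rhat", file.path(out_dir, "rhat.csv")), row.names = FALSE)

  # -- analyse ----------------------------------------------------------
  converged <- max(fit$rhat) < fit$config$rhat_threshold
  summary_tab <- stage("summarise",
                       condition_summary(fit, check_rhat = FALSE))
  write.csv(summary_tab,
            emit("condition_summary",
                 file.path(out_dir, "condition_summary.csv")),
            row.names = FALSE)
  contrasts <- stage("contrasts", {
    cs <- list(identity = identity_contrast(fit))
    for (f in napt_faces) {
      cs[[paste0("drift_valence_", f)]] <- valence_difference(fit, f, "drift")
      cs[[paste0("ndt_valence_", f)]] <-
        valence_difference(fit, f, "nondecision")
    }
    cs
  })
  contrast_json <- lapply(contrasts, function(ct)
    list(name = ct$name, mean = ct$mean, hdi = ct$hdi,
         significant = ct$significant))
  jsonlite::write_json(contrast_json,
                       emit("contrasts", file.path(out_dir, "contrasts.json")),
                       auto_unbox = TRUE, digits = NA)
  ppc <- stage("ppc", ppc_quantile_check(fit, prep$data,
                                         probs = config$ppc$probs,
                                         n_draws = config$ppc$n_draws,
                                         seed = config$seed))
  write.csv(ppc, emit("ppc", file.path(out_dir, "ppc.csv")),
            row.names = FALSE)

  # -- describe ---------------------------------------------------------
  descr <- stage("describe", rt_accuracy_table(prep$data))
  write.csv(descr, emit("descriptives", file.path(out_dir, "descriptives.csv")),
            row.names = FALSE)
  export_glmm_table(prep$data,
                    emit("glmm_table", file.path(out_dir, "glmm_table.csv")))

  files["manifest"] <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("wienerhdm")),
    seed = config$seed,
    config = config,
    converged = converged,
    max_rhat = max(fit$rhat),
    stage_timings_s = timings,
    files = as.list(files),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(manifest, files[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = data, truth = truth, cleaned = prep$data,
                 report = prep$report, fit = fit, summary = summary_tab,
                 contrasts = contrasts, ppc = ppc, descriptives = descr,
                 manifest = manifest, files = files))
}
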