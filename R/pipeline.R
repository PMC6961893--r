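#' Read a flat pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with flat keys; unknown keys are
#' rejected to catch typos. See [default_config()] for the keys and
#' defaults.
#'
#' @param path Config file path.
#' @return A named list merged over the defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}

#' Default pipeline configuration
#'
#' @return Named list of all recognised configuration keys.
#' @export
default_config <- function() {
  list(
    # synthetic cohort
    n_subjects = 10, preset = "table1", tau = 11.4, tracking_sd = 2,
    responsiveness_sdlog = 0.15, intercept_sd = 2,
    # 2AFC cohort
    n_subjects_2afc = 8, pse_intercept = 6, pse_slope = -1.6,
    # model
    ko = 0.11, kv = 0.2, go = 0.16, gv = 0.43, kf = 0.0,
    t_vs = 15, t_s = 0.74, dt = 1 / 30,
    # fitting
    free = c("ko", "go", "t_s"), n_starts = 10,
    # bookkeeping
    seed = 1L, write_trials = FALSE)
}

merge_config <- function(cfg) {
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  def[names(cfg)] <- cfg
  def
}

pipeline_stages <- c("generate", "reduce", "stats", "pse", "fit")

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in order — generate (synthetic cohort +
#' 2AFC data), reduce (rebase/fold/window means), stats (mixed-model
#' likelihood-ratio table), pse (psychometric grid and PSE slope), fit
#' (mechanistic-model SSE fit to the condition grand means) — writing CSV
#' and JSON artifacts plus a manifest into `out_dir`. Later stages re-use
#' in-memory results of earlier ones; running a later stage without its
#' upstream stage is an error naming the stage to run first.
#'
#' @param config Named list (see [default_config()]), path to a YAML file,
#'   or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("generate", "reduce", "stats", "pse", "fit")`.
#' @param seed Integer seed overriding the config's.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("svvrun"),
                         stages = pipeline_stages, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- seed
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(pipeline_stages, collapse = ", "),
         call. = FALSE)
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  set.seed(cfg$seed)
  res <- list()
  done <- character(0)
  need <- function(stage, from) {
    if (!stage %in% done) {
      stop(sprintf("stage '%s' requires stage '%s' to run first",
                   from, stage), call. = FALSE)
    }
  }
  params <- model_params(ko = cfg$ko, kv = cfg$kv, go = cfg$go,
                         gv = cfg$gv, kf = cfg$kf, t_vs = cfg$t_vs,
                         t_s = cfg$t_s)

  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      generate = {
        res$trials <- generate_cohort(
          n_subjects = cfg$n_subjects, preset = cfg$preset, tau = cfg$tau,
          tracking_sd = cfg$tracking_sd,
          responsiveness_sdlog = cfg$responsiveness_sdlog,
          intercept_sd = cfg$intercept_sd, dt = cfg$dt)
        res$afc <- generate_2afc_dataset(
          n_subjects = cfg$n_subjects_2afc,
          pse_intercept = cfg$pse_intercept, pse_slope = cfg$pse_slope)
        if (isTRUE(cfg$write_trials)) {
          utils::write.csv(trials_as_tibble(res$trials),
                           file.path(out_dir, "trials.csv"),
                           row.names = FALSE)
        }
        utils::write.csv(res$afc, file.path(out_dir, "afc_trials.csv"),
                         row.names = FALSE)
      },
      reduce = {
        need("generate", "reduce")
        res$summary <- fold_average(res$trials)
        res$grand <- grand_mean_traces(res$summary)
        res$direction <- direction_test(res$trials)
        write_summary_csv(res$summary,
                          file.path(out_dir, "condition_summary.csv"))
        utils::write.csv(res$direction,
                         file.path(out_dir, "direction_tests.csv"),
                         row.names = FALSE)
        utils::write.csv(
          cbind(res$grand$meta,
                as.data.frame(res$grand$trace) |>
                  stats::setNames(sprintf("t%04d", seq_along(res$grand$time)))),
          file.path(out_dir, "grand_mean_traces.csv"), row.names = FALSE)
      },
      stats = {
        need("reduce", "stats")
        res$lrt <- lrt_table(res$summary$meta)
        jsonlite::write_json(res$lrt, file.path(out_dir, "lrt_table.json"),
                             dataframe = "rows", pretty = TRUE,
                             digits = NA)
      },
      pse = {
        need("generate", "pse")
        res$pse <- pse_table(res$afc)
        res$pse_slope <- fit_pse_slope(res$pse)
        utils::write.csv(res$pse, file.path(out_dir, "pse_table.csv"),
                         row.names = FALSE)
        jsonlite::write_json(res$pse_slope,
                             file.path(out_dir, "pse_slope.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
      },
      fit = {
        need("reduce", "fit")
        res$fit <- fit_svv_model(res$grand, free = cfg$free,
                                 fixed = params, n_starts = cfg$n_starts,
                                 dt = cfg$dt)
        report <- list(estimates = as.list(res$fit$estimates),
                       sse = res$fit$sse,
                       r_squared = res$fit$r_squared,
                       warnings = res$fit$warnings)
        jsonlite::write_json(report, file.path(out_dir, "model_fit.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
      })
    done <- c(done, stage)
    say("stage %-8s done in %.1f s", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  manifest <- list(stages = done, seed = cfg$seed,
                   config = cfg[order(names(cfg))],
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
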