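utils::globalVariables(c("time", "x", "condition", "mean_ms", "strategy",
                         "ci_half_width_ms", "design"))

# stage output file names inside a run directory
mf_stage_files <- list(
  simulate = "session_logs.csv",
  preprocess = "trajectories.csv",
  decide = "decisions.csv",
  screen = c("decisions_screened.csv", "screening_report.json"),
  analyze = c("model_reduction.json", "model_competitor.json",
              "condition_summary.csv", "timecourse_competitor.json")
)

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate -> preprocess -> decide -> screen -> analyze. Every
#' stage writes its outputs into `out_dir` (append-only: a stage never
#' rewrites a prior stage's files) and each stage can be re-run on a prior
#' run's files via the `stages` argument. The manifest records the
#' configuration, seed, stage completion and an md5 checksum for every
#' output file; two runs with identical `(config, seed)` produce identical
#' checksums.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every source of randomness.
#' @param config A flat config list (see [mf_default_config()]) or a path
#'   to a YAML config file; `NULL` for the defaults.
#' @param stages Character vector of stages to execute, in pipeline order.
#' @param n_participants Cohort size (overrides the config when given).
#' @return The run manifest (invisibly), also written to `manifest.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL,
                         stages = c("simulate", "preprocess", "decide",
                                    "screen", "analyze"),
                         n_participants = NULL) {
  cfg <- if (is.null(config)) mf_default_config()
  else if (is.character(config)) read_config(config)
  else config
  if (!is.null(n_participants)) cfg$n_participants <- n_participants
  stages <- match.arg(stages, names(mf_stage_files), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geometry <- config_geometry(cfg)
  params <- config_kinematics(cfg)
  grid <- grid_spec(cfg$grid_t_start, cfg$grid_t_end, cfg$grid_rate)
  path <- function(f) file.path(out_dir, f)
  manifest <- list(tool = "mousefall",
                   version = as.character(utils::packageVersion("mousefall")),
                   seed = seed, config = cfg, stages = list(), files = list())

  log_msg <- function(...) message(sprintf(...))
  done <- function(stage) {
    for (f in mf_stage_files[[stage]])
      manifest$files[[f]] <<- unname(tools::md5sum(path(f)))
    manifest$stages[[stage]] <<- TRUE
  }

  if ("simulate" %in% stages) {
    log_msg("simulate: %d participants x 96 trials (seed %d)",
            cfg$n_participants, seed)
    inv <- item_inventory(seed = child_seed(seed, 1))
    plans <- generate_orders(inv, n_orders = 32, seed = child_seed(seed, 2))
    agents <- make_population(
      cfg$n_participants, seed = child_seed(seed, 3),
      clicker_prob = cfg$clicker_prob, base_mean_s = cfg$base_commit_s,
      base_sd_s = cfg$base_commit_sd_s,
      effect_map = c(reduced = cfg$effect_reduced_s,
                     similar = cfg$effect_similar_s),
      commit_sd_s = cfg$commit_sd_s, track_lag_s = cfg$track_lag_s,
      jitter_sd = cfg$jitter_sd, click_delay_s = cfg$click_delay_s,
      guess_prob = cfg$guess_prob)
    logs <- simulate_cohort(agents, plans, geometry, params,
                            seed = child_seed(seed, 4))
    for (i in seq_along(logs))
      for (j in seq_along(logs[[i]])) logs[[i]][[j]]$order_id <-
          plans[[(i - 1L) %% length(plans) + 1L]]$order_id
    write_session_log(logs, path("session_logs.csv"))
    done("simulate")
  }

  if ("preprocess" %in% stages) {
    logs <- read_session_log(path("session_logs.csv"))
    pre <- preprocess_logs(logs, grid)
    write_trajectories(pre, path("trajectories.csv"))
    log_msg("preprocess: %d trials onto the %d-point grid", nrow(pre$x),
            grid$n_points)
    done("preprocess")
  }

  if ("decide" %in% stages) {
    pre <- read_trajectories(path("trajectories.csv"))
    decisions <- decide_trials(pre, geometry, eps = cfg$eps)
    data.table::fwrite(decisions, path("decisions.csv"))
    log_msg("decide: %d decision times extracted, %d trials lost",
            sum(decisions$na_reason == "none"),
            sum(decisions$na_reason != "none"))
    done("decide")
  }

  if ("screen" %in% stages) {
    decisions <- as.data.frame(data.table::fread(path("decisions.csv"),
                                                 na.strings = c("NA", "")))
    sc <- screen_decisions(decisions, cfg$accuracy_threshold, cfg$max_trial_s)
    data.table::fwrite(sc$data, path("decisions_screened.csv"))
    write_screening_report(sc$report, path("screening_report.json"))
    print(sc$report)
    done("screen")
  }

  if ("analyze" %in% stages) {
    screened <- as.data.frame(data.table::fread(path("decisions_screened.csv"),
                                                na.strings = c("NA", "")))
    res <- tryCatch({
      m_red <- fit_decision_model(screened, "reduction")
      m_cmp <- fit_decision_model(screened, "competitor")
      summary_df <- condition_summary(screened)
      pre <- read_trajectories(path("trajectories.csv"))
      keep <- paste(pre$meta$participant, pre$meta$trial_index) %in%
        paste(screened$participant, screened$trial_index)
      pre$x <- pre$x[keep, , drop = FALSE]
      pre$meta <- pre$meta[keep, , drop = FALSE]
      tc <- timecourse_difference(pre, "competitor", B = 1000,
                                  seed = child_seed(seed, 5))
      list(m_red = m_red, m_cmp = m_cmp, summary_df = summary_df, tc = tc)
    }, mf_modelling_error = function(e) e, mf_analysis_error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages$analyze <- FALSE
      jsonlite::write_json(manifest, path("manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      mf_stop(paste("analyze stage failed:", conditionMessage(res)),
              "mf_analysis_error")
    }
    export_fit <- function(m, file) jsonlite::write_json(
      list(formula = m$formula, df_method = m$df_method,
           coefficients = cbind(term = rownames(m$coefficients),
                                m$coefficients),
           trail = lapply(m$trail, unclass)),
      path(file), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    export_fit(res$m_red, "model_reduction.json")
    export_fit(res$m_cmp, "model_competitor.json")
    data.table::fwrite(res$summary_df, path("condition_summary.csv"))
    jsonlite::write_json(
      list(levels = res$tc$levels, intervals = res$tc$intervals, B = res$tc$B),
      path("timecourse_competitor.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    print(res$m_red)
    print(res$m_cmp)
    done("analyze")
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
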