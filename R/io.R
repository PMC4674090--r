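#' Read and write trial tables
#'
#' Trial tables are tidy delimited text with one row per token opportunity
#' and a fixed column schema (see [simulate_epoch()]). Latency columns are
#' empty on no-go trials. The delimiter is taken from the file extension
#' (`.tsv`/`.tab` = tab, otherwise comma); `read_trials` also sniffs the
#' header line so a mislabelled extension still parses.
#'
#' @param path File path.
#' @param trials Trial table to write.
#' @return `read_trials` returns the validated trial table; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(out))
  if (length(missing))
    stop("trial file ", path, " is missing required columns: ",
         paste(missing, collapse = ", "))
  for (col in c("went", "correct_direction", "token_collected", "caught"))
    out[[col]] <- as.logical(out[[col]])
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  check_trial_table(trials)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' A run configuration bundles everything a full pipeline run depends on:
#' the task parameters, the agent specification, analysis options, and
#' reconstruction options, plus the master seed. It round-trips losslessly
#' through YAML or JSON (chosen by file extension).
#'
#' @param task Named list of [task_config()] arguments.
#' @param agent Named list with `type` in `"bdt"`, `"fixed"`, `"random"`,
#'   `"never"` and type-specific parameters (for `"bdt"`: `prior` with
#'   `d0`, `slope`, `anchor_t`, `anchor_p`; optional `noise_sd`,
#'   `exposure`, `always_go`, `loss` with `D`, `P_C`, `P_T`).
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed.
#' @param analysis Named list: `log_latency`, `max_loss`, plus optional
#'   [filter_latencies()] arguments.
#' @param reconstruction Named list: `min_n`, `t_max`, `exponent_mode`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = list(), agent = list(type = "bdt"),
                       n_subjects = 12L, seed = 1L,
                       analysis = list(log_latency = FALSE, max_loss = 4L),
                       reconstruction = list(min_n = 10L, t_max = 5,
                                             exponent_mode = "attempts")) {
  stopifnot(is.list(task), is.list(agent), !is.null(agent$type),
            agent$type %in% c("bdt", "bdt_simple", "fixed", "random", "never"),
            n_subjects >= 1)
  structure(list(task = task, agent = agent,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 analysis = analysis, reconstruction = reconstruction),
            class = "run_config")
}

#' @rdname run_config
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config format: ", path)
  invisible(path)
}

# build an agent from its config-file specification
agent_from_spec <- function(spec) {
  type <- spec$type
  args <- spec[setdiff(names(spec), c("type", "prior", "loss"))]
  if (type == "never") return(make_never_agent())
  if (type == "fixed") return(do.call(make_fixed_agent, args))
  if (type == "random") return(do.call(make_random_agent, args))
  if (type == "bdt_simple") return(do.call(simple_bdt_agent, args))
  # bdt: the calibrated example agent unless a prior/loss is spelled out
  if (is.null(spec$prior) && is.null(spec$loss))
    return(do.call(example_bdt_agent, args))
  prior <- if (is.null(spec$prior)) example_threat_prior() else
    quadratic_threat_prior(spec$prior$d0, spec$prior$slope,
                           spec$prior$anchor_t, spec$prior$anchor_p)
  if (is.null(spec$loss)) {
    pars <- example_observer_params()
  } else {
    pars <- ideal_observer_params(spec$loss$D, spec$loss$P_C, spec$loss$P_T)
  }
  args$loss_fun <- make_ideal_observer_loss(pars)
  do.call(make_bdt_agent, c(list(prior = prior), args))
}

#' Run the full demonstration pipeline
#'
#' Simulation, behavioural analysis and prior reconstruction in one call:
#' simulates the configured experiment, reconstructs implicit choices and
#' go rates, filters latencies, computes condition means and trend tests,
#' and inverts the latencies into a reconstructed threat prior. If
#' `out_dir` is given, all tables are written as CSV, the fitted prior and
#' trend results as JSON, and a manifest (config, seed, package version)
#' accompanies them so a run can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `trials`, `choices`, `go_rates`,
#'   `filtered`, `exclusions`, `condition_means`, `trend_approach`,
#'   `trend_return`, `prior_fit`, and `manifest`.
#' @export
run_demo <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  cfg <- stage("config", do.call(task_config, config$task))
  agent <- stage("agent", agent_from_spec(config$agent))
  trials <- stage("simulate",
                  simulate_experiment(cfg, agent, config$n_subjects,
                                      config$seed))
  choices <- stage("choices", reconstruct_choices(trials))
  go_rates <- stage("choices", go_rate_table(choices))

  an <- config$analysis
  fargs <- an[intersect(names(an), c("approach_window", "return_window",
                                     "drop_slot", "include_caught"))]
  filtered <- stage("filter", do.call(filter_latencies,
                                      c(list(trials), fargs)))
  max_loss <- if (is.null(an$max_loss)) 4L else an$max_loss
  cond <- stage("condition_means", condition_means(filtered, max_loss))

  trend_a <- trend_r <- NULL
  if (nrow(filtered)) {
    log_lat <- isTRUE(an$log_latency)
    trend_a <- stage("trend_test",
                     trend_test(filtered, "approach", log_lat))
    trend_r <- stage("trend_test", trend_test(filtered, "return", log_lat))
  } else {
    warning("no go trials survive filtering; latency analyses skipped")
  }

  fitp <- NULL
  if (nrow(filtered)) {
    rc <- config$reconstruction
    fitp <- stage("reconstruct",
                  reconstruct_prior(trials, gain = gain_prior(cfg$lambda1),
                                    min_n = if (is.null(rc$min_n)) 10L else rc$min_n,
                                    max_loss = max_loss,
                                    t_max = if (is.null(rc$t_max)) 5 else rc$t_max,
                                    exponent_mode = if (is.null(rc$exponent_mode))
                                      "attempts" else rc$exponent_mode,
                                    filter_args = fargs))
  }

  manifest <- list(config = unclass(config),
                   seed = config$seed,
                   package = "aacbdt",
                   version = as.character(utils::packageVersion("aacbdt")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  bundle <- list(trials = trials, choices = choices, go_rates = go_rates,
                 filtered = filtered,
                 exclusions = attr(filtered, "exclusions"),
                 condition_means = cond,
                 trend_approach = trend_a, trend_return = trend_r,
                 prior_fit = fitp, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                            row.names = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    wcsv(choices, "choices.csv")
    wcsv(go_rates, "go_rates.csv")
    wcsv(attr(filtered, "exclusions"), "exclusions.csv")
    wcsv(cond, "condition_means.csv")
    if (!is.null(fitp)) {
      wcsv(fitp$latency, "predicted_latencies.csv")
      wcsv(fitp$points, "prior_derivative_points.csv")
      jsonlite::write_json(list(prior = as.list(fitp$prior$pars),
                                anchor = as.list(fitp$prior$anchor),
                                ideal_observer = fitp$params[c("D", "P_C",
                                                               "P_T",
                                                               "scale_c")]),
                           file.path(out_dir, "prior_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    trend_json <- function(tr) if (is.null(tr)) NULL else
      list(slope_threat = tr$slope_threat, slope_loss = tr$slope_loss,
           F = as.list(tr$F), p = as.list(tr$p), df = tr$df,
           method = tr$method)
    jsonlite::write_json(list(approach = trend_json(trend_a),
                              return = trend_json(trend_r)),
                         file.path(out_dir, "trend_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
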