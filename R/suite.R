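# End-to-end scenario runs: configuration handling, output writers and the
# eight-run study suite.

.scenario_fields <- c("scenario", "protocol", "pre_posture", "countermeasure",
                      "fraction", "dt", "duration", "output_stride",
                      "open_loop", "param_table", "out_dir",
                      "write_timeseries")

#' Scenario configuration
#'
#' Validated configuration of one end-to-end run.  Unknown fields are
#' rejected; all units are as documented in the arguments.
#'
#' @param scenario `"normal"`, `"hfref"` or `"hfpef"`.
#' @param protocol `"supine-baseline"` or `"microgravity"`.
#' @param pre_posture posture before a microgravity transition.
#' @param countermeasure logical; apply the diuretic volume reduction.
#' @param fraction countermeasure blood-volume fraction removed.
#' @param dt integration step, s.
#' @param duration optional override of the protocol horizon, s.
#' @param output_stride output sampling interval, s.
#' @param open_loop zero all reflex gains.
#' @param param_table optional path to a compartment CSV replacing the
#'   shipped calibrated table (edges/globals stay the shipped ones).
#' @param out_dir output directory for [run_scenario()].
#' @param write_timeseries write the full sampled time series CSV.
#' @return validated list of class `cp_scenario_config`.
#' @export
scenario_config <- function(scenario = c("normal", "hfref", "hfpef"),
                            protocol = c("supine-baseline", "microgravity"),
                            pre_posture = c("standing", "supine"),
                            countermeasure = FALSE, fraction = 0.09,
                            dt = 2.5e-4, duration = NULL,
                            output_stride = 5e-3, open_loop = FALSE,
                            param_table = NULL, out_dir = ".",
                            write_timeseries = TRUE) {
  cfg <- list(scenario = match.arg(scenario),
              protocol = match.arg(protocol),
              pre_posture = match.arg(pre_posture),
              countermeasure = isTRUE(countermeasure),
              fraction = fraction, dt = dt, duration = duration,
              output_stride = output_stride, open_loop = isTRUE(open_loop),
              param_table = param_table, out_dir = out_dir,
              write_timeseries = isTRUE(write_timeseries))
  stopifnot(cfg$dt > 0, cfg$output_stride >= cfg$dt,
            cfg$fraction >= 0, cfg$fraction < 1)
  class(cfg) <- "cp_scenario_config"
  cfg
}

#' Read a scenario configuration file
#'
#' YAML or JSON (by extension).  Unknown keys fail validation before any
#' computation starts.
#'
#' @param path config file path.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .scenario_fields)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(scenario_config, raw)
}

# build the model a config describes
config_model <- function(cfg) {
  model <- default_model()
  if (!is.null(cfg$param_table)) {
    model$compartments <- read_param_table(cfg$param_table)
    attr(model, "calibrated") <- FALSE
  }
  model <- switch(cfg$scenario, normal = model,
                  hfref = apply_hfref(model), hfpef = apply_hfpef(model))
  if (cfg$countermeasure) model <- apply_countermeasure(model, cfg$fraction)
  model
}

config_protocol <- function(cfg) {
  if (cfg$protocol == "microgravity") microgravity_protocol(cfg$pre_posture)
  else supine_baseline_protocol(cfg$duration %||% 90)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run one configured scenario end to end
#'
#' Builds the model and protocol from the configuration, integrates,
#' checks pre-sample stationarity, summarizes, and writes deterministic
#' artifacts to the output directory: the sampled time series
#' (`timeseries.csv`), the beat metrics or transition report
#' (`metrics.json`), a table-formatted CSV (`table.csv`) and a run
#' manifest with config/parameter hashes and per-output checksums
#' (`manifest.json`).
#'
#' @param cfg a [scenario_config()], or a path to a YAML/JSON config file.
#' @return invisibly, a list with the simulation, the metrics object and
#'   the manifest.
#' @export
run_scenario <- function(cfg) {
  if (is.character(cfg)) cfg <- read_scenario_config(cfg)
  stopifnot(inherits(cfg, "cp_scenario_config"))
  model <- config_model(cfg)
  prot <- config_protocol(cfg)
  t_start <- Sys.time()
  sim <- simulate_model(model, prot, dt = cfg$dt,
                        output_stride = cfg$output_stride,
                        duration = cfg$duration, open_loop = cfg$open_loop)
  warn_flags <- character()
  for (lab in names(prot$sample_times)) {
    ok <- try(is_stationary(sim, prot$sample_times[[lab]]), silent = TRUE)
    if (!isTRUE(ok)) {
      warning("sample window '", lab, "' is not stationary", call. = FALSE)
      warn_flags <- c(warn_flags, paste0("non_stationary_", lab))
    }
  }
  metrics <- if (cfg$protocol == "microgravity") transition_report(sim)
             else beat_metrics(sim, prot$sample_times[["pre"]])

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$out_dir,
                     c("timeseries.csv", "metrics.json", "table.csv"))
  names(paths) <- c("timeseries", "metrics", "table")
  if (cfg$write_timeseries) {
    ts <- data.frame(t = sim$time, sim$V, sim$P, sim$Q, HR = sim$HR,
                     check.names = FALSE)
    colnames(ts) <- c("t", paste0("V_", colnames(sim$V)),
                      paste0("P_", colnames(sim$P)),
                      paste0("Q_", colnames(sim$Q)), "HR")
    utils::write.csv(ts, paths[["timeseries"]], row.names = FALSE)
  } else paths <- paths[-1]
  if (inherits(metrics, "cp_transition_report")) {
    jsonlite::write_json(
      list(pre = as.list(metrics$pre), post = as.list(metrics$post),
           delta = as.list(metrics$delta),
           spike_lap_peak = metrics$spike_lap_peak,
           spike_duration = metrics$spike_duration),
      paths[["metrics"]], auto_unbox = TRUE, digits = NA)
    tab <- rbind(pre = unlist(metrics$pre[1:13]),
                 post = unlist(metrics$post[1:13]),
                 delta = unlist(metrics$delta))
    utils::write.csv(round(t(tab), 3), paths[["table"]])
  } else {
    jsonlite::write_json(as.list(metrics), paths[["metrics"]],
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(round(t(as.matrix(metrics[1:13])), 3),
                     paths[["table"]])
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gravicor")),
    config = unclass(cfg),
    config_hash = md5_of(unclass(cfg)),
    param_table_hash = md5_of(model$compartments),
    scenario = cfg$scenario,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    flags = warn_flags,
    outputs = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, metrics = metrics, manifest = manifest))
}

# expected values embedded for the suite's summary comparison
.suite_expected <- list(
  supine = list(
    normal = c(co = 5.2, lap = 10, ef = 51, ea_ees = 0.72),
    hfref = c(co = 5.1, lap = 17, ef = 27, ea_ees = 1.89),
    hfpef = c(co = 5.3, lap = 19, ef = 55, ea_ees = 0.71)),
  delta_lap = c(normal = 5.7, hfref = 6.9, hfpef = 9.5),
  cm = list(hfref = c(pre_co = 2.64, pre_lap = 12.5, post_lap = 19.5),
            hfpef = c(pre_co = 2.8, pre_lap = 5, post_lap = 15)))

#' Run the full study suite
#'
#' Eight deterministic runs - the three supine-1G baselines, the three
#' standing-to-microgravity transitions, and the two heart-failure
#' transitions with the 9% volume countermeasure - writing per-run metrics,
#' PV-loop and transition-trace data files plus a `summary.csv` comparing
#' key cells against the embedded expected values with per-cell relative
#' error.
#'
#' @param out_dir output directory.
#' @param dry_run list the planned runs without executing.
#' @param dt integration step, s.
#' @return the plan (dry run) or invisibly the summary data.frame.
#' @export
run_paper_suite <- function(out_dir = "gravicor-suite", dry_run = FALSE,
                            dt = 2.5e-4) {
  plan <- rbind(
    expand.grid(scenario = c("normal", "hfref", "hfpef"),
                protocol = c("supine-baseline", "microgravity"),
                countermeasure = FALSE, stringsAsFactors = FALSE),
    expand.grid(scenario = c("hfref", "hfpef"), protocol = "microgravity",
                countermeasure = TRUE, stringsAsFactors = FALSE))
  plan$name <- paste0(plan$scenario,
                      ifelse(plan$protocol == "microgravity", "_transition",
                             "_supine"),
                      ifelse(plan$countermeasure, "_cm", ""))
  if (dry_run) return(plan)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- NULL
  for (i in seq_len(nrow(plan))) {
    cfg <- scenario_config(plan$scenario[i], plan$protocol[i],
                           countermeasure = plan$countermeasure[i],
                           dt = dt, out_dir = file.path(out_dir,
                                                        plan$name[i]),
                           write_timeseries = FALSE)
    res <- run_scenario(cfg)
    sc <- plan$scenario[i]
    if (plan$protocol[i] == "supine-baseline") {
      loop <- extract_pv_loop(res$sim, 80)
      utils::write.csv(loop, file.path(out_dir, plan$name[i],
                                       "pvloop.csv"), row.names = FALSE)
      exp <- .suite_expected$supine[[sc]]
      got <- unlist(res$metrics[names(exp)])
      summary <- rbind(summary, data.frame(
        run = plan$name[i], quantity = names(exp), expected = unname(exp),
        simulated = unname(got),
        rel_error = unname((got - exp) / exp)))
    } else {
      idx <- seq(1, length(res$sim$time), by = 10)
      utils::write.csv(
        data.frame(t = res$sim$time[idx],
                   map = res$sim$P[idx, "ao_th"],
                   lap = res$sim$P[idx, "la"],
                   hr = res$sim$HR[idx]),
        file.path(out_dir, plan$name[i], "transition_trace.csv"),
        row.names = FALSE)
      if (!plan$countermeasure[i]) {
        exp <- c(delta_lap = unname(.suite_expected$delta_lap[sc]))
        got <- c(delta_lap = res$metrics$delta$lap)
      } else {
        exp <- .suite_expected$cm[[sc]]
        got <- c(pre_co = res$metrics$pre$co, pre_lap = res$metrics$pre$lap,
                 post_lap = res$metrics$post$lap)
      }
      summary <- rbind(summary, data.frame(
        run = plan$name[i], quantity = names(exp), expected = unname(exp),
        simulated = unname(got),
        rel_error = unname((got - exp) / exp)))
    }
  }
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(summary)
}
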