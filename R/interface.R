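run_config_defaults <- function() {
  list(preset = "paper2026", n_subjects = 100L, master_seed = 1L,
       prevalence = 0.2,
       grid = NULL,                    # list(t0, t_end, dt) overrides
       sensitivity = list(prevalences = c(0.15, 0.20, 0.30),
                          sd_fraction = 0.15, cv = 0.10,
                          parameters = c("tau7", "tau8", "beta1", "beta2")),
       output_dir = ".")
}

#' Parse and validate a run configuration
#'
#' Accepts a YAML or JSON file path, or an inline named list; fills
#' defaults, rejects unknown keys, and returns an immutable `run_config`.
#' Defaults: preset `"paper2026"`, 100 subjects, 100-unit horizon,
#' prevalence 0.20, master seed 1.
#'
#' @param config File path (`.yaml`/`.yml`/`.json`) or named list; `NULL`
#'   gives the full defaults.
#' @return An object of class `"run_config"`.
#' @export
parse_config <- function(config = NULL) {
  raw <- if (is.null(config)) {
    list()
  } else if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("'config' must be a file path or a named list", call. = FALSE)

  defaults <- run_config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$sensitivity)) {
    bad2 <- setdiff(names(raw$sensitivity), names(defaults$sensitivity))
    if (length(bad2))
      stop("unknown config key(s): ",
           paste(paste0("sensitivity.", bad2), collapse = ", "),
           call. = FALSE)
    raw$sensitivity <- utils::modifyList(defaults$sensitivity,
                                         raw$sensitivity)
  }
  cfg <- utils::modifyList(defaults, raw)
  if (cfg$prevalence < 0 || cfg$prevalence > 1)
    stop("config: 'prevalence' must be in [0, 1]", call. = FALSE)
  if (cfg$n_subjects < 1) stop("config: 'n_subjects' must be >= 1",
                               call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Serialise a run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output file (`.yaml` or `.json`).
#' @return `path`, invisibly.  `parse_config(path)` round-trips exactly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$grid <- x$grid   # NULL grid is simply dropped by the writers
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(x, path)
  invisible(path)
}

config_model <- function(cfg) {
  grid <- if (!is.null(cfg$grid))
    time_grid(cfg$grid$t0 %||% 0, cfg$grid$t_end %||% 100,
              cfg$grid$dt %||% 0.01)
  cascade_model(cfg$preset, grid = grid)
}

#' Command-line interface
#'
#' In-process entry point behind the `delaytwin` wrapper script (see
#' `system.file("scripts", "delaytwin", package = "delaytwin")`).
#' Subcommands:
#' \describe{
#'   \item{simulate}{simulate a labelled cohort; writes `metrics.csv`,
#'     `trajectories.csv` and the resolved `config.yaml`.}
#'   \item{metrics}{summarise a metrics CSV (group means, rank test, AUC).}
#'   \item{sensitivity}{run the three-block sensitivity suite; writes a JSON
#'     report and per-condition metrics CSVs.}
#'   \item{km}{Kaplan--Meier curves by time-to-peak tertile from a metrics
#'     CSV; writes a curves CSV and a comparison JSON.}
#'   \item{proxies}{append delay-proxy ratios and tertiles to a biomarker
#'     CSV.}
#' }
#' Common flags: `--config <file>`, `--seed <int>`, `--n <int>`,
#' `--out <dir>`, `--input <csv>` (metrics/km/proxies).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success, 2 on usage errors).
#' @export
delaytwin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: delaytwin <simulate|metrics|sensitivity|km|proxies> [options]",
    "  --config <file>   YAML/JSON run configuration",
    "  --seed <int>      master seed (overrides config)",
    "  --n <int>         number of subjects (overrides config)",
    "  --out <dir>       output directory (default '.')",
    "  --input <csv>     input table (metrics, km, proxies)",
    sep = "\n")
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(if (length(args) == 0L) 2L else 0L))
  }
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  if (is.null(opts)) {
    message(usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- parse_config(opts$config)
    if (!is.null(opts$seed)) cfg$master_seed <- as.integer(opts$seed)
    if (!is.null(opts$n)) cfg$n_subjects <- as.integer(opts$n)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    switch(cmd,
           simulate = cli_simulate(cfg),
           metrics = cli_metrics(cfg, opts$input),
           sensitivity = cli_sensitivity(cfg),
           km = cli_km(cfg, opts$input),
           proxies = cli_proxies(cfg, opts$input, opts$output),
           { message("unknown subcommand: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) return(NULL)
    opts[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  known <- c("config", "seed", "n", "out", "input", "output")
  if (length(setdiff(names(opts), known))) return(NULL)
  opts
}

cli_log <- function(cfg, model = NULL) {
  message(sprintf("delaytwin %s | preset %s%s | master seed %d",
                  as.character(utils::packageVersion("delaytwin")),
                  cfg$preset,
                  if (!is.null(model))
                    paste0(" (", substr(model$preset_hash, 1, 8), ")")
                  else "",
                  cfg$master_seed))
}

cli_simulate <- function(cfg) {
  model <- config_model(cfg)
  cli_log(cfg, model)
  cohort <- simulate(model, nsim = cfg$n_subjects, seed = cfg$master_seed,
                     prevalence = cfg$prevalence)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$metrics,
                   file.path(cfg$output_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort, what = "paths"),
                   file.path(cfg$output_dir, "trajectories.csv"),
                   row.names = FALSE)
  write_config(cfg, file.path(cfg$output_dir, "config.yaml"))
  print(summary(cohort))
  0L
}

read_metrics_csv <- function(path, need = c("subject_id", "max_y",
                                            "time_to_peak_y", "event_cv")) {
  if (is.null(path)) stop("--input <metrics.csv> is required", call. = FALSE)
  m <- utils::read.csv(path)
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("input lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m
}

cli_metrics <- function(cfg, input) {
  m <- read_metrics_csv(input)
  ev <- m$event_cv == 1L
  cat(sprintf("%d subjects, %d events\n", nrow(m), sum(ev)))
  cat(sprintf("mean time-to-peak Y: %.2f (events) vs %.2f (non-events)\n",
              mean(m$time_to_peak_y[ev]), mean(m$time_to_peak_y[!ev])))
  ht <- rank_sum_test(m$time_to_peak_y[ev], m$time_to_peak_y[!ev])
  cat(sprintf("rank-sum p = %.3g; AUC = %.3f\n", ht$p_value,
              roc_auc(m$time_to_peak_y, m$event_cv)))
  0L
}

cli_sensitivity <- function(cfg) {
  model <- config_model(cfg)
  cli_log(cfg, model)
  s <- cfg$sensitivity
  rep <- run_sensitivity_suite(model, master_seed = cfg$master_seed,
                               n_subjects = cfg$n_subjects,
                               prevalences = s$prevalences,
                               sd_fraction = s$sd_fraction, cv = s$cv,
                               parameters = s$parameters)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- rep
  out$base$summary <- unclass(out$base$summary)
  jsonlite::write_json(unclass(out),
                       file.path(cfg$output_dir, "sensitivity.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  write_config(cfg, file.path(cfg$output_dir, "config.yaml"))
  print(rep)
  0L
}

cli_km <- function(cfg, input) {
  m <- read_metrics_csv(input)
  # rebuild a minimal cohort wrapper around the metrics table
  model <- config_model(cfg)
  cohort <- structure(list(model = model, trajectories = NULL, metrics = m,
                           threshold = NA_real_,
                           normalization_factor = NA_real_,
                           prevalence = mean(m$event_cv),
                           master_seed = cfg$master_seed),
                      class = "cascade_cohort")
  km <- km_by_delay_tertiles(cohort)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- do.call(rbind, lapply(names(km$curves), function(nm)
    cbind(group = nm, km$curves[[nm]])))
  utils::write.csv(curves, file.path(cfg$output_dir, "km_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(event_fraction = km$event_fraction,
         log_rank = if (!is.null(km$comparison)) unclass(km$comparison)),
    file.path(cfg$output_dir, "km_comparison.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  cat(sprintf("event fraction by tertile: %s\n",
              paste(sprintf("%.2f", km$event_fraction), collapse = ", ")))
  if (!is.null(km$comparison))
    cat(sprintf("log-rank chi-square = %.2f (df %d), p = %.3g\n",
                km$comparison$statistic, km$comparison$df,
                km$comparison$p_value))
  0L
}

cli_proxies <- function(cfg, input, output) {
  if (is.null(input)) stop("--input <table.csv> is required", call. = FALSE)
  tab <- utils::read.csv(input)
  out <- proxy_table(tab)
  dest <- output %||% file.path(cfg$output_dir, "proxies.csv")
  utils::write.csv(out, dest, row.names = FALSE)
  excl <- attr(out, "exclusions")
  cat(sprintf("wrote %s (%d rows; excluded %d for tau_composite, %d for delta_ratio)\n",
              dest, nrow(out), excl[["tau_composite"]],
              excl[["delta_ratio"]]))
  0L
}
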