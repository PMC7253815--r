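#' Before/after-optimization parameter report
#'
#' For each target: the pattern's canonical ("without optimization")
#' quadruple, the GA-fitted ("with optimization") quadruple, and the trace
#' MSE of both against the target.  Errors in one target are logged and the
#' run continues with the rest.
#'
#' @param targets list of entries, each
#'   `list(name, target, stimulus, config, canonical)` where `target` is a
#'   `membrane_trace`, `canonical` a [neuron_params()]
#' @param ga_config a [ga_config()]; its `bounds` are recentred on each
#'   target's canonical quadruple via [bounds_around()] unless
#'   `recentre_bounds = FALSE`
#' @param recentre_bounds recentre the search box per pattern
#' @param out_dir optional directory; writes `fit_report.csv` and
#'   `fit_report.json` when given
#' @return data.frame with one row per pattern: canonical and fitted
#'   (a, b, c, d), `mse_before`, `mse_after`, `generations_run`
#' @export
fit_report <- function(targets, ga_config = ga_config(),
                       recentre_bounds = TRUE, out_dir = NULL) {
  rows <- list()
  for (tg in targets) {
    row <- tryCatch({
      cfg <- ga_config
      if (recentre_bounds) cfg$bounds <- bounds_around(tg$canonical)
      before <- simulate_neuron(tg$canonical, tg$stimulus, tg$config)
      mse_before <- mse_fitness(before$trace, tg$target)
      fr <- fit_izhikevich(tg$target, tg$stimulus, tg$config, cfg)
      cp <- as.numeric(tg$canonical)
      fp <- as.numeric(fr$best_params)
      data.frame(pattern = tg$name,
                 a_canonical = cp[1], b_canonical = cp[2],
                 c_canonical = cp[3], d_canonical = cp[4],
                 a_fitted = fp[1], b_fitted = fp[2],
                 c_fitted = fp[3], d_fitted = fp[4],
                 mse_before = mse_before, mse_after = fr$best_fitness,
                 generations_run = fr$generations_run)
    }, error = function(e) {
      message("fit_report: pattern '", tg$name, "' failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pattern = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report, file.path(out_dir, "fit_report.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                         digits = NA, dataframe = "rows")
  }
  report
}

#' Run the whole pipeline on synthetic data
#'
#' Generates the standard 3-unit recording, sorts it, and writes
#' per-cluster spike trains; then builds synthetic stand-in neurons (the
#' reference optimized quadruples plus membrane noise) as fitting targets,
#' fits each from a search box around its canonical quadruple, classifies
#' the target traces, and writes before/after-parameter and
#' possible-pattern reports plus three-curve comparison CSVs
#' (target vs canonical vs fitted trace).
#'
#' @param out_dir output directory (created if absent)
#' @param seed master seed
#' @param patterns registry names to fit; default a trio whose stand-ins
#'   still express their pattern class
#' @param ga_generations generation cap for the demo fits
#' @param noise_sd_mv membrane noise on the synthetic targets
#' @param recording_duration_s length of the generated recording
#' @param ga_population population size for the demo fits
#' @return invisibly, a list with the sort score, fit report, and pattern
#'   table
#' @export
run_demo <- function(out_dir, seed = 1234,
                     patterns = c("tonic spiking", "phasic spiking",
                                  "rebound spiking"),
                     ga_generations = 60, noise_sd_mv = 0.5,
                     recording_duration_s = 60, ga_population = 60) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, patterns = patterns,
                   ga_generations = ga_generations,
                   noise_sd_mv = noise_sd_mv,
                   r_version = as.character(getRversion()),
                   stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    res
  }

  rec <- stage("generate",
               standard_recording(seed = seed,
                                  duration_s = recording_duration_s))
  sorted <- stage("sort", sort_recording(rec, k = 3, seed = seed))
  score <- stage("score", score_sort(sorted, rec))
  for (nm in names(sorted$trains)) {
    write_spike_train(sorted$trains[[nm]],
                      file.path(out_dir, paste0(nm, "_spikes.txt")))
  }

  reg <- canonical_registry()
  standins <- reference_optimized_params()
  targets <- stage("targets", lapply(patterns, function(nm) {
    e <- reg[[nm]]
    tt <- make_target_trace(standins[[nm]], e$stimulus, e$config,
                            noise_sd_mv = noise_sd_mv, seed = seed)
    list(name = e$name, label = e$label, target = tt$trace,
         stimulus = e$stimulus, config = e$config, canonical = e$params)
  }))
  cfg <- ga_config(population_size = ga_population,
                   max_generations = ga_generations, seed = seed)
  report <- stage("fit", fit_report(targets, cfg, out_dir = out_dir))

  labels <- stage("classify", {
    labs <- lapply(targets, function(tg) {
      # apex samples of a noisy trace carry noise, so detect below +30
      train <- spike_times_from_trace(tg$target, peak_cutoff = 25)
      f <- extract_features(tg$target, train, tg$stimulus)
      classify_pattern(f, tg$stimulus)
    })
    names(labs) <- paste0("cluster_", seq_along(labs))
    labs
  })
  tab <- pattern_table(list(synthetic = labels))
  write_pattern_matrix_csv(tab, file.path(out_dir, "pattern_matrix.csv"))

  stage("curves", for (i in seq_along(targets)) {
    tg <- targets[[i]]
    canonical <- simulate_neuron(tg$canonical, tg$stimulus, tg$config)
    fitted <- simulate_neuron(
      neuron_params(report$a_fitted[i], report$b_fitted[i],
                    report$c_fitted[i], report$d_fitted[i]),
      tg$stimulus, tg$config)
    df <- data.frame(time_ms = tg$target$times, target_mV = tg$target$v,
                     canonical_mV = canonical$trace$v,
                     fitted_mV = fitted$trace$v)
    safe <- gsub("[^a-z0-9]+", "_", tolower(tg$name))
    write.csv(df, file.path(out_dir, paste0("curves_", safe, ".csv")),
              row.names = FALSE, quote = FALSE)
  })

  manifest$sort_score <- score[c("recall", "accuracy")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sort_score = score, fit_report = report,
                 pattern_table = tab))
}

#' Validate a JSON run configuration
#'
#' Schema-checks a stage configuration file, reporting every violation at
#' once, and fills documented defaults.
#'
#' @param path JSON file with at least a `stage` key; optional blocks
#'   `ga` (crossover_fraction, mutation_rate, population_size,
#'   max_generations), `seed`, `out_dir`
#' @return a list of class `run_config` on success; otherwise signals an
#'   error listing every violation
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse JSON config ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  stages <- c("simulate", "sort", "fit", "classify", "report", "demo")
  errors <- character(0)
  if (is.null(cfg$stage)) {
    errors <- c(errors, paste0("missing 'stage'; allowed: ",
                               paste(stages, collapse = ", ")))
  } else if (!cfg$stage %in% stages) {
    errors <- c(errors, paste0("unknown stage '", cfg$stage, "'; allowed: ",
                               paste(stages, collapse = ", ")))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    errors <- c(errors, "'seed' must be a single number")
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "results"
  if (!is.null(cfg$ga)) {
    in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
    if (!is.null(cfg$ga$crossover_fraction) &&
        !in01(cfg$ga$crossover_fraction)) {
      errors <- c(errors, "'ga.crossover_fraction' must lie in [0, 1]")
    }
    if (!is.null(cfg$ga$mutation_rate) && !in01(cfg$ga$mutation_rate)) {
      errors <- c(errors, "'ga.mutation_rate' must lie in [0, 1]")
    }
    if (!is.null(cfg$ga$population_size) && cfg$ga$population_size < 2) {
      errors <- c(errors, "'ga.population_size' must be >= 2")
    }
  }
  if (length(errors) > 0) {
    stop("invalid config ", path, ":\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}
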