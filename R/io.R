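# Configuration, deterministic seeding, result persistence and logging
# shared by all stages.

.run_config_defaults <- function() {
  list(term = "product2d",
       points_per_dim = NA_integer_,    # NA -> per-arity default
       n_granules = 60L,
       n_projections = 2L,
       max_iterations = 2000L,
       max_lm_iterations = 100L,
       restarts = 3L,
       restart_perturbation = 0.1,
       tolerance = 1e-8,
       optimize_directions = FALSE,
       n_screen = 40L,
       experiment = NA_character_,      # fig4 | fig5 | fig6 | capacity | baseline
       q_list = c(1L, 2L, 3L, 4L, 5L),
       N_list = c(20L, 60L, 120L),
       n_reps = 20L,
       master_seed = 1L,
       output_dir = "results",
       full_scale = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (dispatched on extension; `.json`
#' is parsed with jsonlite, everything else with yaml), fills in defaults,
#' and rejects unknown keys by name.  An empty file yields the full default
#' configuration.  Per-repetition seeds are derived from `master_seed` with
#' [derive_seed()] and are therefore a pure function of the configuration.
#'
#' @param path path to the configuration file.
#' @return a named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("load_config(): no such file: ", path, call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) {
    list()
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(txt)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    stop("load_config(): configuration must be a mapping of keys to values",
         call. = FALSE)
  }
  defaults <- .run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("load_config(): unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  .validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_run_config <- function(cfg) {
  if (!cfg$term %in% .term_names) {
    stop("load_config(): key 'term' must be one of: ",
         paste(.term_names, collapse = ", "), call. = FALSE)
  }
  if (!is.na(cfg$experiment) &&
      !cfg$experiment %in% c("fig4", "fig5", "fig6", "capacity", "baseline")) {
    stop("load_config(): key 'experiment' must be one of fig4, fig5, fig6, ",
         "capacity, baseline", call. = FALSE)
  }
  num_keys <- c("n_granules", "n_projections", "max_iterations",
                "max_lm_iterations", "restarts", "n_reps", "master_seed",
                "n_screen")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] < 0) {
      stop("load_config(): key '", k, "' must be a non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$n_granules < cfg$n_projections) {
    stop("load_config(): n_granules must be >= n_projections", call. = FALSE)
  }
  invisible(cfg)
}

#' Turn a run configuration into a fit configuration
#'
#' @param cfg a `run_config` (from [load_config()]).
#' @param rng_seed seed to embed (defaults to the master seed).
#' @return a [fit_config()].
#' @export
as_fit_config <- function(cfg, rng_seed = cfg$master_seed) {
  fit_config(n_granules = cfg$n_granules,
             n_projections = cfg$n_projections,
             max_iterations = cfg$max_iterations,
             max_lm_iterations = cfg$max_lm_iterations,
             restarts = cfg$restarts,
             restart_perturbation = cfg$restart_perturbation,
             tolerance = cfg$tolerance,
             rng_seed = rng_seed,
             optimize_directions = cfg$optimize_directions,
             n_screen = cfg$n_screen)
}

# one row per repetition across all boxes of an experiment_summary_list
.summaries_to_reps_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(term = s$term_name, q = s$q, N = s$N,
               repetition = seq_len(s$n_repetitions),
               seed = if (is.null(s$seeds)) NA_integer_ else s$seeds,
               rmse_rel = s$rmse_rel,
               converged = if (is.null(s$converged)) NA else s$converged)
  }))
}

.summaries_to_stats_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    st <- s$stats
    data.frame(term = s$term_name, q = s$q, N = s$N,
               n_repetitions = s$n_repetitions,
               mean = st$mean, median = st$median, q25 = st$q25,
               q75 = st$q75, whisker_low = st$whisker_low,
               whisker_high = st$whisker_high,
               n_outliers = length(st$outliers),
               best = st$best, worst = st$worst)
  }))
}

#' Persist experiment results with a manifest
#'
#' Writes each element of `results` (experiment summary lists, sweep data
#' frames, approximation results, capacity reports) to CSV/JSON artifacts in
#' `directory`, then a `manifest.json` recording every artifact with its MD5
#' checksum, the configuration (and its hash) when attached as
#' `attr(results, "config")`, and the master seeds encountered.  On any
#' write failure the partial outputs are removed before the error
#' propagates.  Identical inputs produce byte-identical artifacts: all
#' doubles are formatted with 17 significant digits.
#'
#' @param results a named list of result objects.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_results <- function(results, directory) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("write_results(): results must be a fully named list", call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  seeds <- integer(0)
  emit <- function(path, writer) {
    writer(path)
    written <<- c(written, path)
  }
  tryCatch({
    for (nm in names(results)) {
      obj <- results[[nm]]
      if (inherits(obj, "experiment_summary_list")) {
        emit(file.path(directory, paste0(nm, "_repetitions.csv")),
             function(p) .write_csv_full(.summaries_to_reps_df(obj), p))
        emit(file.path(directory, paste0(nm, "_summary.csv")),
             function(p) .write_csv_full(.summaries_to_stats_df(obj), p))
        seeds <- c(seeds, unlist(lapply(obj, `[[`, "seeds")))
      } else if (inherits(obj, "approximation_result")) {
        emit(file.path(directory, paste0(nm, ".json")),
             function(p) result_to_json(obj, p))
        seeds <- c(seeds, obj$seed)
      } else if (inherits(obj, "capacity_report")) {
        emit(file.path(directory, paste0(nm, ".json")),
             function(p) writeLines(jsonlite::toJSON(unclass(obj),
                                                     digits = I(17),
                                                     auto_unbox = TRUE), p))
      } else if (is.data.frame(obj)) {
        emit(file.path(directory, paste0(nm, ".csv")),
             function(p) .write_csv_full(obj, p))
      } else {
        stop("write_results(): no writer for element '", nm, "' of class ",
             paste(class(obj), collapse = "/"), call. = FALSE)
      }
    }
    cfg <- attr(results, "config")
    cfg_entry <- NULL
    if (!is.null(cfg)) {
      cfg_path <- file.path(directory, "config.json")
      emit(cfg_path, function(p) {
        writeLines(jsonlite::toJSON(unclass(cfg), digits = I(17),
                                    auto_unbox = TRUE), p)
      })
      cfg_entry <- list(file = basename(cfg_path),
                        md5 = unname(tools::md5sum(cfg_path)))
    }
    manifest <- list(
      artifacts = lapply(written, function(p) {
        list(file = basename(p), md5 = unname(tools::md5sum(p)))
      }),
      config = cfg_entry,
      seeds = sort(unique(seeds)))
    manifest_path <- file.path(directory, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, digits = I(17), auto_unbox = TRUE),
               manifest_path)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop("write_results(): ", conditionMessage(e), call. = FALSE)
  })
}

.log <- function(..., run_id = NULL) {
  prefix <- if (is.null(run_id)) "" else sprintf("[%s] ", run_id)
  message(prefix, sprintf(...))
}
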