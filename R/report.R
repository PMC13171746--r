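# Reproducible report runs: one entry point that composes the scenario
# table, sensitivity sweeps, event-crossing comparison and a synthetic
# population summary, and writes them as CSV/JSON with a run manifest.
# Files are written atomically (write to a temp name, then rename) so a
# failed run never leaves partial output behind.

#' Assemble a run configuration
#'
#' @param scenarios Named list of [scenario_spec()] (default
#'   [builtin_scenarios()]), or a character vector of builtin ids to select.
#' @param grids Sensitivity grids for the `sensitivity_on` scenario (default
#'   [default_grids()]).
#' @param sensitivity_on Id of the scenario the sweeps run on (default
#'   `"main"`).
#' @param events Event catalog (default [builtin_events()]).
#' @param population A [population_config()]; its seed is overridden by the
#'   run seed. Default: 1000 neurons with default dispersion.
#' @param formats Output formats, non-empty subset of `c("csv", "json")`.
#' @param seed Run seed (population generation and bootstrap).
#' @param strict If `TRUE`, a non-reconstructed scenario that misses its
#'   published expected value makes the run fail (`ok = FALSE`, nonzero CLI
#'   exit).
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenarios = builtin_scenarios(),
                       grids = default_grids(),
                       sensitivity_on = "main",
                       events = builtin_events(),
                       population = population_config(1000),
                       formats = c("csv", "json"),
                       seed = 1L,
                       strict = TRUE) {
  if (is.character(scenarios)) {
    all <- builtin_scenarios()
    missing <- setdiff(scenarios, names(all))
    if (length(missing)) {
      stop("unknown scenario id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    scenarios <- all[scenarios]
  }
  formats <- match.arg(formats, c("csv", "json"), several.ok = TRUE)
  if (!length(formats)) stop("at least one output format", call. = FALSE)
  if (!is.null(sensitivity_on) && !sensitivity_on %in% names(scenarios)) {
    stop("sensitivity_on references absent scenario '", sensitivity_on, "'",
         call. = FALSE)
  }
  structure(list(scenarios = scenarios, grids = grids,
                 sensitivity_on = sensitivity_on, events = events,
                 population = population, formats = formats,
                 seed = as.integer(seed), strict = isTRUE(strict)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `scenarios` (as in [read_scenarios()], or a
#' vector of builtin ids), `sensitivity_on`, `grids` (list of
#' `{parameter, values}`), `events` (list of `{name, model: {type, mean, sd}
#' or {type, low, high}, provenance}`), `population` (fields of
#' [population_config()]), `formats`, `seed`, `strict`. Missing keys fall
#' back to the defaults of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$scenarios)) {
    args$scenarios <- if (is.character(y$scenarios)) {
      y$scenarios
    } else {
      read_scenarios(path)
    }
  }
  if (!is.null(y$grids)) {
    args$grids <- lapply(y$grids, function(g) {
      parameter_grid(g$parameter, as.numeric(unlist(g$values)))
    })
  }
  if (!is.null(y$sensitivity_on)) args$sensitivity_on <- y$sensitivity_on
  if (!is.null(y$events)) {
    args$events <- lapply(y$events, function(e) {
      m <- e$model
      am <- if (identical(m$type, "gaussian")) {
        gaussian_amplitude(as.numeric(m$mean), as.numeric(m$sd))
      } else {
        range_amplitude(as.numeric(m$low), as.numeric(m$high))
      }
      event_class(e$name, am,
                  provenance = if (is.null(e$provenance)) "" else e$provenance)
    })
    names(args$events) <- vapply(args$events, `[[`, character(1), "name")
  }
  if (!is.null(y$population)) {
    args$population <- do.call(population_config, y$population)
  }
  if (!is.null(y$formats)) args$formats <- unlist(y$formats)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$strict)) args$strict <- y$strict
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly. Loading the written file with
#'   [read_run_config()] reproduces an identical run.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    scenarios = lapply(unname(config$scenarios), function(s) {
      list(id = s$id, baseline_margin = s$baseline_margin,
           modifiers = lapply(s$modifiers, function(m) {
             list(name = m$name, kind = m$kind, magnitude = m$magnitude,
                  provenance = m$provenance, enabled = m$enabled)
           }),
           expected = if (is.finite(s$expected)) s$expected else NULL,
           provenance = s$provenance, reconstructed = s$reconstructed)
    }),
    sensitivity_on = config$sensitivity_on,
    grids = lapply(config$grids, function(g) {
      list(parameter = g$parameter, values = g$values)
    }),
    events = lapply(unname(config$events), function(e) {
      list(name = e$name, model = e$amplitude_model,
           provenance = e$provenance)
    }),
    population = unclass(config$population),
    formats = config$formats,
    seed = config$seed,
    strict = config$strict)
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(path)
}

# atomic file write: build content via `writer(tmp)`, then rename into place
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place at ", path, call. = FALSE)
  }
  invisible(path)
}

write_table <- function(df, out_dir, stem, formats) {
  if ("csv" %in% formats) {
    atomic_write(file.path(out_dir, paste0(stem, ".csv")), function(p) {
      utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    })
  }
  if ("json" %in% formats) {
    atomic_write(file.path(out_dir, paste0(stem, ".json")), function(p) {
      jsonlite::write_json(df, p, dataframe = "rows", digits = NA,
                           na = "null", pretty = TRUE)
    })
  }
}

#' Run the full analysis and write a report bundle
#'
#' Writes, under `out_dir`: `scenarios.csv/json` (the [run_all()] table,
#' with a `footnote` column marking reconstructed scenarios),
#' `sensitivity.csv/json` (per-evaluation rows of the one-at-a-time and
#' combined sweeps), `events.csv/json` (crossing status and analytic
#' exceedance probability for every scenario margin x event class),
#' `population_summary.json` (margin summary and recovered compression ratio
#' of a synthetic population), and `run_manifest.json` (all parameters, the
#' seed, and the package version).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the computed tables, `mismatches` (ids of
#'   non-reconstructed scenarios that missed their published value) and `ok`
#'   (`FALSE` iff strict and mismatches exist).
#' @export
run_report <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory ", out_dir, " is not writable", call. = FALSE)
  }

  message("running ", length(config$scenarios), " scenario(s)")
  scen <- run_all(config$scenarios)
  scen$footnote <- ifelse(scen$reconstructed,
                          "reconstructed modifier magnitude", "")
  mismatches <- scen$id[!is.na(scen$matches_expected) & !scen$matches_expected]
  write_table(scen, out_dir, "scenarios", config$formats)

  sens_tbl <- NULL
  if (!is.null(config$sensitivity_on) && length(config$grids)) {
    message("sensitivity sweeps on '", config$sensitivity_on, "'")
    target <- config$scenarios[[config$sensitivity_on]]
    oat <- oat_sweep(target, config$grids)
    comb <- combined_sweep(target, config$grids)
    comb_rows <- data.frame(
      mode = "combined",
      parameter = "combined",
      value = apply(comb$evaluations[, setdiff(names(comb$evaluations),
                                               c("mode", "effective_margin")),
                                     drop = FALSE],
                    1L, function(r) paste(format(r, trim = TRUE),
                                          collapse = "; ")),
      effective_margin = comb$evaluations$effective_margin,
      stringsAsFactors = FALSE)
    sens_tbl <- rbind(
      cbind(oat$evaluations[, c("mode", "parameter")],
            value = as.character(oat$evaluations$value),
            effective_margin = oat$evaluations$effective_margin),
      comb_rows)
    sens_tbl$effective_printed <- round_half_up(sens_tbl$effective_margin, 1)
    write_table(sens_tbl, out_dir, "sensitivity", config$formats)
  }

  ev_tbl <- NULL
  if (length(config$events) && nrow(scen)) {
    message("event-crossing comparison")
    ev_tbl <- do.call(rbind, lapply(seq_len(nrow(scen)), function(i) {
      tb <- crossing_table(scen$effective_margin[i], config$events)
      cbind(scenario = scen$id[i], tb)
    }))
    rownames(ev_tbl) <- NULL
    write_table(ev_tbl, out_dir, "events", config$formats)
  }

  message("synthetic population (n = ", config$population$n_neurons, ")")
  pop_cfg <- config$population
  pop_cfg$seed <- config$seed
  pop <- generate_population(pop_cfg)
  rec <- recover_gamma(pop, seed = config$seed)
  pop_summary <- list(
    n_neurons = pop_cfg$n_neurons,
    seed = config$seed,
    margin_mean = mean(pop$margin),
    margin_sd = stats::sd(pop$margin),
    gamma_true = pop_cfg$gamma_true,
    gamma_estimate = rec$estimate,
    gamma_ci = rec$ci)
  atomic_write(file.path(out_dir, "population_summary.json"), function(p) {
    jsonlite::write_json(pop_summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  manifest <- list(
    package = "excitmargin",
    version = as.character(utils::packageVersion("excitmargin")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    formats = config$formats,
    strict = config$strict,
    scenario_ids = names(config$scenarios),
    sensitivity_on = config$sensitivity_on,
    grids = lapply(config$grids, function(g) {
      list(parameter = g$parameter, values = g$values)
    }),
    population = unclass(pop_cfg),
    mismatches = as.list(mismatches))
  atomic_write(file.path(out_dir, "run_manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  ok <- !(config$strict && length(mismatches) > 0L)
  if (!ok) {
    warning("scenario(s) missed their published value: ",
            paste(mismatches, collapse = ", "), call. = FALSE)
  }
  invisible(list(scenarios = scen, sensitivity = sens_tbl, events = ev_tbl,
                 population_summary = pop_summary, mismatches = mismatches,
                 ok = ok))
}
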