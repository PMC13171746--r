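# One-at-a-time and full-factorial sensitivity sweeps of the effective margin
# over parameter grids, in the style of a local parameter-sensitivity
# analysis: vary parameters around their nominal values and report the
# resulting margin extrema.

#' Construct a parameter grid
#'
#' @param parameter Which scenario parameter the grid varies:
#'   `"baseline_margin"`, `"compression"` (the single enabled compression
#'   modifier), or `"chronic_shift:<name>"` / `"acute_shift:<name>"`
#'   addressing a shift modifier by name.
#' @param values Finite ascending numeric vector within the parameter's
#'   validity domain (fractions in (0, 1] for compression, mV otherwise).
#' @return An object of class `parameter_grid`.
#' @examples
#' parameter_grid("compression", c(0.50, 0.56, 0.62))
#' parameter_grid("chronic_shift:inflammation", c(0, 2, 6))
#' @export
parameter_grid <- function(parameter, values) {
  stopifnot(is.character(parameter), length(parameter) == 1L,
            is.numeric(values))
  if (!length(values) || any(!is.finite(values))) {
    stop("grid for '", parameter, "' must be non-empty and finite",
         call. = FALSE)
  }
  if (is.unsorted(values, strictly = TRUE)) {
    stop("grid values for '", parameter, "' must be strictly ascending",
         call. = FALSE)
  }
  base <- sub(":.*$", "", parameter)
  if (!base %in% c("baseline_margin", "compression", "chronic_shift",
                   "acute_shift")) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  if (base %in% c("chronic_shift", "acute_shift") &&
      !grepl(":", parameter, fixed = TRUE)) {
    stop("shift parameters must name a modifier, e.g. '", base, ":hot_spot'",
         call. = FALSE)
  }
  if (base == "compression" && (any(values <= 0) || any(values > 1))) {
    stop("compression grid values must lie in (0, 1]", call. = FALSE)
  }
  if (base == "baseline_margin" && any(values <= 0)) {
    stop("baseline_margin grid values must be > 0 mV", call. = FALSE)
  }
  if (base %in% c("chronic_shift", "acute_shift") && any(values < 0)) {
    stop("shift grid values must be >= 0 mV", call. = FALSE)
  }
  structure(list(parameter = parameter, values = as.numeric(values)),
            class = "parameter_grid")
}

# Nominal value of a grid's parameter in a scenario; errors if the grid
# addresses a modifier the scenario does not carry.
nominal_value <- function(spec, parameter) {
  base <- sub(":.*$", "", parameter)
  if (base == "baseline_margin") return(spec$baseline_margin)
  if (base == "compression") {
    idx <- which(vapply(spec$modifiers, function(m) {
      m$kind == "compression" && m$enabled
    }, logical(1)))
    if (length(idx) != 1L) {
      stop("scenario '", spec$id, "' must carry exactly one enabled ",
           "compression modifier to sweep 'compression' (found ",
           length(idx), ")", call. = FALSE)
    }
    return(spec$modifiers[[idx]]$magnitude)
  }
  nm <- sub("^[^:]*:", "", parameter)
  idx <- which(vapply(spec$modifiers, function(m) {
    m$kind == base && m$name == nm && m$enabled
  }, logical(1)))
  if (length(idx) != 1L) {
    stop("scenario '", spec$id, "' has no enabled ", base,
         " modifier named '", nm, "'", call. = FALSE)
  }
  spec$modifiers[[idx]]$magnitude
}

# Return a copy of the scenario with one parameter set to `value`.
set_parameter <- function(spec, parameter, value) {
  base <- sub(":.*$", "", parameter)
  if (base == "baseline_margin") {
    spec$baseline_margin <- value
    return(spec)
  }
  nominal_value(spec, parameter)  # existence + uniqueness check
  for (i in seq_along(spec$modifiers)) {
    m <- spec$modifiers[[i]]
    hit <- if (base == "compression") {
      m$kind == "compression" && m$enabled
    } else {
      m$kind == base && m$name == sub("^[^:]*:", "", parameter) && m$enabled
    }
    if (hit) {
      spec$modifiers[[i]]$magnitude <- value
      return(spec)
    }
  }
  stop("unreachable: parameter '", parameter, "' not found", call. = FALSE)
}

eval_margin <- function(spec) {
  apply_scenario(spec$baseline_margin, spec$modifiers)$effective_margin
}

new_sensitivity_report <- function(mode, per_parameter, evaluations,
                                   overall_min, overall_max, n_evaluated) {
  structure(list(mode = mode, per_parameter = per_parameter,
                 evaluations = evaluations,
                 overall = c(min = overall_min, max = overall_max),
                 n_evaluated = n_evaluated),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> mode: %s, %d evaluation(s)\n", x$mode,
              x$n_evaluated))
  cat(sprintf("  overall effective margin: %.4g - %.4g mV\n",
              x$overall[["min"]], x$overall[["max"]]))
  if (nrow(x$per_parameter)) {
    print(x$per_parameter, row.names = FALSE)
  }
  invisible(x)
}

#' One-at-a-time sensitivity sweep
#'
#' Varies each gridded parameter alone, all others held at their nominal
#' scenario values, and records the effective-margin extrema. The nominal
#' value is inserted into any grid that omits it, so the nominal margin is
#' always among the evaluations.
#'
#' @param spec A [scenario_spec()].
#' @param grids List of [parameter_grid()] objects; each must address a
#'   parameter present in the scenario.
#' @return A `sensitivity_report` with `mode = "oat"`: `per_parameter` rows
#'   (parameter, min/max margin and the grid values attaining them — ties
#'   report the smallest value — plus the margin at nominal), `overall`
#'   extrema, `n_evaluated`, and an `evaluations` data.frame (mode,
#'   parameter, value, effective_margin).
#' @examples
#' main <- builtin_scenarios()$main
#' oat_sweep(main, list(parameter_grid("compression", c(0.50, 0.56, 0.62))))
#' @export
oat_sweep <- function(spec, grids) {
  stopifnot(inherits(spec, "scenario_spec"), is.list(grids))
  if (!length(grids)) stop("at least one grid is required", call. = FALSE)
  per <- list()
  evals <- list()
  nominal_margin <- eval_margin(spec)
  for (g in grids) {
    stopifnot(inherits(g, "parameter_grid"))
    nom <- nominal_value(spec, g$parameter)
    values <- sort(unique(c(g$values, nom)))
    margins <- vapply(values, function(v) {
      eval_margin(set_parameter(spec, g$parameter, v))
    }, numeric(1))
    i_min <- which.min(margins)  # first index = smallest value on ties
    i_max <- which.max(margins)
    per[[length(per) + 1L]] <- data.frame(
      parameter = g$parameter, n_values = length(values),
      min_margin = margins[i_min], value_at_min = values[i_min],
      max_margin = margins[i_max], value_at_max = values[i_max],
      nominal_margin = nominal_margin, stringsAsFactors = FALSE)
    evals[[length(evals) + 1L]] <- data.frame(
      mode = "oat", parameter = g$parameter, value = values,
      effective_margin = margins, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  evals <- do.call(rbind, evals)
  rownames(per) <- rownames(evals) <- NULL
  new_sensitivity_report("oat", per, evals,
                         min(per$min_margin), max(per$max_margin),
                         nrow(evals))
}

#' Full-factorial (combined) sensitivity sweep
#'
#' Enumerates the Cartesian product of the grids exactly as supplied (unlike
#' [oat_sweep()], nominal values are not inserted) and reports the overall
#' effective-margin extrema. Rows are enumerated in lexicographic order of
#' the grid values, so tied extrema report the lexicographically first grid
#' point.
#'
#' @inheritParams oat_sweep
#' @param cap Maximum allowed product size (default `1e6`).
#' @return A `sensitivity_report` with `mode = "combined"`, an empty
#'   `per_parameter` section, `overall` extrema over the full product, and
#'   per-cell `evaluations` (one column per parameter plus
#'   `effective_margin`).
#' @examples
#' main <- builtin_scenarios()$main
#' combined_sweep(main, list(
#'   parameter_grid("compression", c(0.50, 0.62)),
#'   parameter_grid("chronic_shift:inflammation", c(0, 2, 6))))
#' @export
combined_sweep <- function(spec, grids, cap = 1e6) {
  stopifnot(inherits(spec, "scenario_spec"), is.list(grids))
  if (!length(grids)) stop("at least one grid is required", call. = FALSE)
  value_sets <- lapply(grids, function(g) {
    stopifnot(inherits(g, "parameter_grid"))
    nominal_value(spec, g$parameter)  # parameter-existence check
    g$values
  })
  params <- vapply(grids, `[[`, character(1), "parameter")
  if (anyDuplicated(params)) {
    stop("duplicate grids for parameter '", params[duplicated(params)][1],
         "'", call. = FALSE)
  }
  size <- prod(vapply(value_sets, length, integer(1)))
  if (size > cap) {
    stop("combined grid size ", format(size, scientific = FALSE),
         " exceeds the cap of ", format(cap, scientific = FALSE),
         call. = FALSE)
  }
  # expand.grid varies the first factor fastest; reverse so rows come out in
  # lexicographic order of (param1, param2, ...)
  cells <- rev(expand.grid(rev(value_sets), KEEP.OUT.ATTRS = FALSE))
  names(cells) <- params
  margins <- vapply(seq_len(nrow(cells)), function(i) {
    s <- spec
    for (j in seq_along(params)) {
      s <- set_parameter(s, params[j], cells[i, j])
    }
    eval_margin(s)
  }, numeric(1))
  evals <- cbind(data.frame(mode = "combined", stringsAsFactors = FALSE),
                 cells, effective_margin = margins)
  rownames(evals) <- NULL
  per <- data.frame(parameter = character(), n_values = integer(),
                    min_margin = numeric(), value_at_min = numeric(),
                    max_margin = numeric(), value_at_max = numeric(),
                    nominal_margin = numeric(), stringsAsFactors = FALSE)
  new_sensitivity_report("combined", per, evals,
                         min(margins), max(margins), length(margins))
}

#' Default illustrative sensitivity grids for the main scenario
#'
#' Compression \{0.50, 0.56, 0.62\}, inflammatory shift \{0, 2, 6\} mV,
#' hot-spot shift \{0, 3.2\} mV — an illustrative local neighbourhood of the
#' main scenario's nominal parameters, consistent with the published
#' low-millivolt sensitivity ranges.
#'
#' @return List of [parameter_grid()] objects.
#' @export
default_grids <- function() {
  list(parameter_grid("compression", c(0.50, 0.56, 0.62)),
       parameter_grid("chronic_shift:inflammation", c(0, 2.0, 6.0)),
       parameter_grid("acute_shift:hot_spot", c(0, 3.2)))
}
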