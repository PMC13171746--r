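# Core margin model: membrane states, pro-excitatory modifiers, and the
# cumulative margin equation  gamma * (M0 - sum(chronic)) - sum(acute),
# floored at zero.

#' Compute the excitability margin from threshold and resting potential
#'
#' The excitability margin is the distance from resting membrane potential to
#' spike threshold, i.e. the minimal depolarization needed to fire an action
#' potential.
#'
#' @param v_thr Spike threshold in mV.
#' @param v_rest Resting membrane potential in mV (typically negative).
#' @return Margin in mV (`v_thr - v_rest`), strictly positive.
#' @examples
#' compute_margin(v_thr = -50, v_rest = -68.4) # 18.4
#' @export
compute_margin <- function(v_thr, v_rest) {
  stopifnot(is.numeric(v_thr), is.numeric(v_rest),
            length(v_thr) == 1L, length(v_rest) == 1L)
  if (!is.finite(v_thr) || !is.finite(v_rest)) {
    stop("non-finite membrane potentials: v_thr = ", v_thr,
         ", v_rest = ", v_rest, call. = FALSE)
  }
  if (v_thr <= v_rest) {
    stop("spike threshold must exceed resting potential: v_thr = ", v_thr,
         " mV, v_rest = ", v_rest, " mV (margin would be <= 0)",
         call. = FALSE)
  }
  v_thr - v_rest
}

#' Construct a membrane state
#'
#' A membrane state carries resting potential, spike threshold, and the derived
#' static margin. It may also be constructed margin-only, for baselines that
#' are published as a threshold distance without the underlying potentials.
#'
#' @param v_rest,v_thr Resting potential and spike threshold, mV. Omit both to
#'   construct a margin-only state.
#' @param margin Margin in mV; required when potentials are omitted, and must
#'   equal `v_thr - v_rest` exactly when they are given.
#' @return An object of class `membrane_state` with fields `v_rest`, `v_thr`
#'   and `margin`.
#' @examples
#' membrane_state(v_rest = -68.4, v_thr = -50)
#' membrane_state(margin = 18.4)
#' @export
membrane_state <- function(v_rest = NULL, v_thr = NULL, margin = NULL) {
  if (!is.null(v_rest) || !is.null(v_thr)) {
    if (is.null(v_rest) || is.null(v_thr)) {
      stop("provide both v_rest and v_thr, or a margin alone", call. = FALSE)
    }
    derived <- compute_margin(v_thr, v_rest)
    if (!is.null(margin) && margin != derived) {
      stop("margin (", margin, ") does not equal v_thr - v_rest (",
           derived, ")", call. = FALSE)
    }
    margin <- derived
  } else {
    if (is.null(margin)) stop("a margin is required", call. = FALSE)
    stopifnot(is.numeric(margin), length(margin) == 1L)
    if (!is.finite(margin) || margin <= 0) {
      stop("margin must be finite and > 0 mV, got ", margin, call. = FALSE)
    }
    v_rest <- NA_real_
    v_thr <- NA_real_
  }
  structure(list(v_rest = v_rest, v_thr = v_thr, margin = margin),
            class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat("<membrane_state>  margin:", format(x$margin), "mV")
  if (is.finite(x$v_rest)) {
    cat("  (v_rest:", format(x$v_rest), "mV, v_thr:", format(x$v_thr), "mV)")
  }
  cat("\n")
  invisible(x)
}

.modifier_kinds <- c("compression", "chronic_shift", "acute_shift")

#' Construct a pro-excitatory modifier ("hit")
#'
#' A modifier is one influence that narrows the margin: a `compression` scales
#' the remaining reserve by a dimensionless fraction in (0, 1] (e.g. the
#' stress-derived rheobase ratio), while `chronic_shift` and `acute_shift`
#' modifiers subtract depolarizing voltage-equivalent amounts in mV, before and
#' after compression respectively.
#'
#' @param name Short label (used to address the modifier in sensitivity grids).
#' @param kind One of `"compression"`, `"chronic_shift"`, `"acute_shift"`.
#' @param magnitude Fraction in (0, 1] for compression; mV >= 0 for shifts
#'   (depolarizing shifts are stored as positive margin-reducing quantities).
#' @param provenance Free-text citation note.
#' @param enabled Logical; disabled modifiers are ignored by [apply_scenario()].
#' @return An object of class `modifier`.
#' @examples
#' modifier("stress", "compression", 0.56)
#' modifier("inflammation", "chronic_shift", 2.0)
#' @export
modifier <- function(name, kind, magnitude, provenance = "", enabled = TRUE) {
  kind <- match.arg(kind, .modifier_kinds)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(magnitude), length(magnitude) == 1L,
            is.logical(enabled), length(enabled) == 1L)
  if (!is.finite(magnitude)) {
    stop("modifier '", name, "': magnitude must be finite", call. = FALSE)
  }
  if (kind == "compression") {
    if (magnitude <= 0 || magnitude > 1) {
      stop("modifier '", name, "': compression magnitude must lie in (0, 1], ",
           "got ", magnitude,
           if (magnitude > 1) " (margin-widening ratios are rejected)" else "",
           call. = FALSE)
    }
  } else if (magnitude < 0) {
    stop("modifier '", name, "': shift magnitude must be >= 0 mV, got ",
         magnitude, call. = FALSE)
  }
  structure(list(name = name, kind = kind, magnitude = magnitude,
                 provenance = provenance, enabled = enabled),
            class = "modifier")
}

#' @export
print.modifier <- function(x, ...) {
  unit <- if (x$kind == "compression") "" else " mV"
  cat(sprintf("<modifier> %s [%s] %s%s%s\n", x$name, x$kind,
              format(x$magnitude), unit,
              if (x$enabled) "" else " (disabled)"))
  invisible(x)
}

is_modifier <- function(x) inherits(x, "modifier")

# revalidate a modifier that may have been edited (e.g. by a sweep)
validate_modifier <- function(m) {
  modifier(m$name, m$kind, m$magnitude, m$provenance, m$enabled)
}

#' Stress compression coefficient from paired rheobase currents
#'
#' The stress module parameterizes chronic-stress excitability change as the
#' ratio of stressed to control rheobase, used downstream as a phenomenological
#' compression coefficient for the remaining excitability reserve (a chronic
#' restraint stress value of about 0.56 is the reference).
#'
#' @param i_rh_stress,i_rh_ctrl Rheobase currents under stress and control, in
#'   the same (arbitrary) units; both must be > 0.
#' @return The dimensionless ratio. Ratios > 1 are returned with a warning
#'   (margin-widening: a compression [modifier()] will not accept them).
#' @examples
#' gamma_from_rheobase(56, 100) # 0.56
#' @export
gamma_from_rheobase <- function(i_rh_stress, i_rh_ctrl) {
  stopifnot(is.numeric(i_rh_stress), is.numeric(i_rh_ctrl),
            length(i_rh_stress) == 1L, length(i_rh_ctrl) == 1L)
  if (!is.finite(i_rh_stress) || !is.finite(i_rh_ctrl) ||
      i_rh_stress <= 0 || i_rh_ctrl <= 0) {
    stop("rheobase currents must be finite and > 0: i_rh_stress = ",
         i_rh_stress, ", i_rh_ctrl = ", i_rh_ctrl, call. = FALSE)
  }
  gamma <- i_rh_stress / i_rh_ctrl
  if (gamma > 1) {
    warning("rheobase ratio ", format(gamma), " > 1 is margin-widening and ",
            "cannot be used as a compression modifier", call. = FALSE)
  }
  gamma
}

#' Apply a scenario of modifiers to a baseline margin
#'
#' Composes the enabled modifiers in a fixed phase order, regardless of the
#' order supplied: (1) all chronic shifts are subtracted from the baseline
#' margin; (2) the remainder is multiplied by the product of the compression
#' coefficients; (3) all acute shifts are subtracted. Negative results are
#' floored at 0 mV and flagged. With one compression `g`, one chronic shift
#' `c` and one acute shift `a` this is `g * (M0 - c) - a`, the cumulative
#' margin equation.
#'
#' @param baseline A [membrane_state()] or a baseline margin in mV (> 0).
#' @param modifiers A list of [modifier()] objects (may be empty).
#' @return An object of class `margin_result` with fields `baseline_margin`,
#'   `effective_margin`, `percent_reduction`, `clamped`, and `decomposition`
#'   (a data.frame chaining each applied modifier's margin before/after).
#' @examples
#' apply_scenario(18.4, list(
#'   modifier("stress", "compression", 0.56),
#'   modifier("inflammation", "chronic_shift", 2.0),
#'   modifier("hot_spot", "acute_shift", 3.2)
#' ))
#' @export
apply_scenario <- function(baseline, modifiers = list()) {
  if (inherits(baseline, "membrane_state")) baseline <- baseline$margin
  stopifnot(is.numeric(baseline), length(baseline) == 1L)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline margin must be finite and > 0 mV, got ", baseline,
         call. = FALSE)
  }
  if (is_modifier(modifiers)) modifiers <- list(modifiers)
  stopifnot(is.list(modifiers))
  modifiers <- lapply(modifiers, validate_modifier)
  enabled <- Filter(function(m) m$enabled, modifiers)

  by_kind <- function(k) Filter(function(m) m$kind == k, enabled)
  chronic <- by_kind("chronic_shift")
  compress <- by_kind("compression")
  acute <- by_kind("acute_shift")

  chronic_sum <- sum(vapply(chronic, `[[`, numeric(1), "magnitude"))
  if (chronic_sum >= baseline) {
    stop("chronic shifts sum to ", chronic_sum, " mV >= baseline margin ",
         baseline, " mV; pre-compression reserve would not be positive",
         call. = FALSE)
  }

  steps <- list()
  m <- baseline
  clamped <- FALSE
  record <- function(mod, before, after) {
    steps[[length(steps) + 1L]] <<- data.frame(
      name = mod$name, kind = mod$kind, magnitude = mod$magnitude,
      before = before, after = after, stringsAsFactors = FALSE)
  }
  for (mod in chronic) {
    after <- m - mod$magnitude
    record(mod, m, after)
    m <- after
  }
  for (mod in compress) {
    after <- m * mod$magnitude
    record(mod, m, after)
    m <- after
  }
  for (mod in acute) {
    after <- m - mod$magnitude
    if (after < 0) {
      after <- 0
      clamped <- TRUE
    }
    record(mod, m, after)
    m <- after
  }

  decomposition <- if (length(steps)) {
    do.call(rbind, steps)
  } else {
    data.frame(name = character(), kind = character(), magnitude = numeric(),
               before = numeric(), after = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(
    baseline_margin = baseline,
    effective_margin = m,
    percent_reduction = 100 * (baseline - m) / baseline,
    decomposition = decomposition,
    clamped = clamped
  ), class = "margin_result")
}

#' Percent of baseline margin lost
#'
#' @param baseline Baseline margin in mV, > 0.
#' @param effective Effective margin in mV, in `[0, baseline]`.
#' @return `100 * (baseline - effective) / baseline`.
#' @examples
#' percent_reduction(18.4, 5.984) # 67.478...
#' @export
percent_reduction <- function(baseline, effective) {
  stopifnot(is.numeric(baseline), is.numeric(effective),
            length(baseline) == 1L, length(effective) == 1L,
            is.finite(baseline), is.finite(effective))
  if (baseline <= 0) {
    stop("baseline margin must be > 0 mV, got ", baseline, call. = FALSE)
  }
  if (effective < 0 || effective > baseline) {
    stop("effective margin ", effective, " mV outside [0, ", baseline,
         "] mV; margin-widening scenarios are out of the reduction metric's ",
         "domain", call. = FALSE)
  }
  100 * (baseline - effective) / baseline
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("<margin_result>  %.4g -> %.4g mV  (-%.1f%%)%s\n",
              x$baseline_margin, x$effective_margin, x$percent_reduction,
              if (x$clamped) "  [clamped at 0]" else ""))
  if (nrow(x$decomposition)) {
    for (i in seq_len(nrow(x$decomposition))) {
      d <- x$decomposition[i, ]
      cat(sprintf("  %-20s %-13s %8.4g -> %.4g mV\n",
                  d$name, paste0("[", d$kind, "]"), d$before, d$after))
    }
  }
  invisible(x)
}

#' Half-up rounding for paper-facing printed values
#'
#' Published margin and percent values are rounded half-up to one decimal;
#' base [round()] is round-half-even. Internal arithmetic stays unrounded —
#' this is only for the `*_printed` report columns and comparisons against
#' published one-decimal values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return `x` rounded half-up.
#' @examples
#' round_half_up(0.25, 1) # 0.3 (round() gives 0.2)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) / p * sign(x)
}
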