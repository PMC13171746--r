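# Transient depolarizing event classes and their comparison against a
# residual effective margin: crossing classification at the amplitude scale,
# and exceedance probability under each class's amplitude model.

#' Amplitude models for transient depolarizing events
#'
#' `gaussian_amplitude()` describes an event class reported as mean +/- SD;
#' amplitudes are physically positive, so the law is a normal distribution
#' truncated below at 0 and renormalized. `range_amplitude()` describes a
#' class reported only as a min-max range, modeled uniform on `[low, high]`
#' (the maximum-entropy choice given a range).
#'
#' @param mean,sd Gaussian mean and SD in mV (`sd > 0`).
#' @param low,high Range bounds in mV (`0 <= low < high`).
#' @return A list with `type` (`"gaussian"` or `"range"`) and parameters.
#' @export
gaussian_amplitude <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd),
            length(mean) == 1L, length(sd) == 1L,
            is.finite(mean), is.finite(sd))
  if (sd <= 0) stop("gaussian amplitude sd must be > 0 mV", call. = FALSE)
  list(type = "gaussian", mean = mean, sd = sd)
}

#' @rdname gaussian_amplitude
#' @export
range_amplitude <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high),
            length(low) == 1L, length(high) == 1L,
            is.finite(low), is.finite(high))
  if (low < 0 || low >= high) {
    stop("range amplitude requires 0 <= low < high, got [", low, ", ", high,
         "]", call. = FALSE)
  }
  list(type = "range", low = low, high = high)
}

#' Construct a transient depolarizing event class
#'
#' @param name Label.
#' @param amplitude_model A [gaussian_amplitude()] or [range_amplitude()].
#' @param provenance Free-text citation note.
#' @return An object of class `event_class`.
#' @examples
#' event_class("nmda_spike_somatic", gaussian_amplitude(5.9, 1.5))
#' @export
event_class <- function(name, amplitude_model, provenance = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(amplitude_model),
            amplitude_model$type %in% c("gaussian", "range"))
  if (amplitude_model$type == "gaussian") {
    amplitude_model <- gaussian_amplitude(amplitude_model$mean,
                                          amplitude_model$sd)
  } else {
    amplitude_model <- range_amplitude(amplitude_model$low,
                                       amplitude_model$high)
  }
  structure(list(name = name, amplitude_model = amplitude_model,
                 provenance = provenance),
            class = "event_class")
}

#' @export
print.event_class <- function(x, ...) {
  m <- x$amplitude_model
  desc <- if (m$type == "gaussian") {
    sprintf("gaussian(%.4g +/- %.4g mV, truncated at 0)", m$mean, m$sd)
  } else {
    sprintf("uniform on [%.4g, %.4g] mV", m$low, m$high)
  }
  cat(sprintf("<event_class> %s  %s\n", x$name, desc))
  invisible(x)
}

#' Built-in catalog of transient depolarizing events
#'
#' The consolidated list of physiologically reported subthreshold
#' depolarization amplitudes the residual margin is compared against: somatic
#' equivalents of local NMDA spikes (5.9 +/- 1.5 mV), location-dependent NMDA
#' spike/plateau amplitudes (3-23 mV), sharp wave-associated depolarizations
#' (4.1 +/- 2.3 mV), intracellular ripple amplitudes (1-4 mV),
#' burst-associated depolarizations (10-25 mV), and place-field subthreshold
#' "hills" (5-20 mV).
#'
#' @return Named list of six [event_class()] objects.
#' @export
builtin_events <- function() {
  evts <- list(
    event_class("nmda_spike_somatic", gaussian_amplitude(5.9, 1.5),
                provenance = "somatic equivalent of local NMDA spikes"),
    event_class("nmda_plateau", range_amplitude(3, 23),
                provenance = "location-dependent NMDA spike/plateau amplitudes"),
    event_class("sharp_wave", gaussian_amplitude(4.1, 2.3),
                provenance = "sharp wave-associated depolarizations"),
    event_class("ripple", range_amplitude(1, 4),
                provenance = "intracellular ripple amplitudes"),
    event_class("burst", range_amplitude(10, 25),
                provenance = "burst-associated depolarizations"),
    event_class("place_field_hill", range_amplitude(5, 20),
                provenance = "place-field subthreshold hills")
  )
  names(evts) <- vapply(evts, `[[`, character(1), "name")
  evts
}

# Effective amplitude support of an event class. Gaussian classes use the
# mean +/- 2 SD interval (an artifact convention, flagged in reports),
# clamped below at 0 since amplitudes are positive.
effective_support <- function(model) {
  if (model$type == "range") {
    c(model$low, model$high)
  } else {
    c(max(0, model$mean - 2 * model$sd), model$mean + 2 * model$sd)
  }
}

#' Classify whether an event class can cross a residual margin
#'
#' Compares the event's amplitude support against the margin: `exceeds` when
#' even the smallest supported amplitude reaches the margin, `cannot_cross`
#' when even the largest falls short, `partially_within` otherwise. Gaussian
#' classes use the mean +/- 2 SD interval (clamped at 0) as effective
#' support — a stated convention, not a distributional fact.
#'
#' @param margin Residual effective margin in mV, >= 0.
#' @param event An [event_class()].
#' @param probability If `TRUE`, also attach the analytic
#'   [exceedance_probability()].
#' @return An object of class `crossing_assessment`: `event`, `margin`,
#'   `status`, `support_convention`, and `exceedance_probability` (`NA`
#'   unless requested).
#' @examples
#' classify_crossing(5.984, builtin_events()$ripple) # cannot_cross
#' classify_crossing(5.984, builtin_events()$burst)  # exceeds
#' @export
classify_crossing <- function(margin, event, probability = FALSE) {
  stopifnot(is.numeric(margin), length(margin) == 1L, is.finite(margin),
            inherits(event, "event_class"))
  if (margin < 0) stop("margin must be >= 0 mV, got ", margin, call. = FALSE)
  sup <- effective_support(event$amplitude_model)
  status <- if (sup[1] >= margin) {
    "exceeds"
  } else if (sup[2] < margin) {
    "cannot_cross"
  } else {
    "partially_within"
  }
  structure(list(
    event = event$name,
    margin = margin,
    status = status,
    support_convention = if (event$amplitude_model$type == "gaussian") {
      "mean +/- 2 SD, clamped at 0"
    } else "reported range",
    exceedance_probability = if (probability) {
      exceedance_probability(margin, event)
    } else NA_real_
  ), class = "crossing_assessment")
}

#' @export
print.crossing_assessment <- function(x, ...) {
  cat(sprintf("<crossing_assessment> %s at margin %.4g mV: %s", x$event,
              x$margin, x$status))
  if (is.finite(x$exceedance_probability)) {
    cat(sprintf("  (P[amplitude >= margin] = %.3f)",
                x$exceedance_probability))
  }
  cat("\n")
  invisible(x)
}

#' Probability that one event amplitude reaches the margin
#'
#' For a gaussian class the analytic value is the upper tail of the normal
#' law truncated below at 0 and renormalized; for a range class it is the
#' uniform mass at or above the margin. `monte_carlo` draws from the same
#' amplitude model; at large `n_samples` the two agree to within binomial
#' sampling error.
#'
#' @param margin Residual effective margin in mV, >= 0.
#' @param event An [event_class()].
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param n_samples Monte Carlo sample count (>= 1).
#' @param seed Integer seed, required for `monte_carlo` (reproducibility
#'   contract); the global RNG state is left untouched.
#' @return Probability in `[0, 1]`.
#' @examples
#' exceedance_probability(5.984, builtin_events()$nmda_spike_somatic)
#' @export
exceedance_probability <- function(margin, event,
                                   method = c("analytic", "monte_carlo"),
                                   n_samples = 1e5, seed = NULL) {
  stopifnot(is.numeric(margin), length(margin) == 1L, is.finite(margin),
            inherits(event, "event_class"))
  if (margin < 0) stop("margin must be >= 0 mV, got ", margin, call. = FALSE)
  method <- match.arg(method)
  model <- event$amplitude_model
  if (method == "analytic") {
    if (model$type == "gaussian") {
      # upper tail of N(mean, sd) truncated below at 0
      upper <- stats::pnorm(max(margin, 0), model$mean, model$sd,
                            lower.tail = FALSE)
      mass_pos <- stats::pnorm(0, model$mean, model$sd, lower.tail = FALSE)
      upper / mass_pos
    } else {
      if (margin <= model$low) {
        1
      } else if (margin >= model$high) {
        0
      } else {
        (model$high - margin) / (model$high - model$low)
      }
    }
  } else {
    if (is.null(seed)) {
      stop("monte_carlo requires an explicit seed", call. = FALSE)
    }
    stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
    draws <- local_seed(seed, sample_amplitudes(model, n_samples))
    mean(draws >= margin)
  }
}

# Draw amplitudes from an event amplitude model (truncated-gaussian by
# inverse-CDF, so no rejection loop).
sample_amplitudes <- function(model, n) {
  n <- as.integer(n)
  if (model$type == "gaussian") {
    p0 <- stats::pnorm(0, model$mean, model$sd)
    stats::qnorm(stats::runif(n, p0, 1), model$mean, model$sd)
  } else {
    stats::runif(n, model$low, model$high)
  }
}

#' Crossing table for a margin against an event catalog
#'
#' @param margin Residual effective margin in mV.
#' @param events List of [event_class()] objects (default [builtin_events()]).
#' @param probability Attach analytic exceedance probabilities (default
#'   `TRUE`).
#' @return data.frame: `event`, `model`, `margin`, `status`, `probability`.
#' @export
crossing_table <- function(margin, events = builtin_events(),
                           probability = TRUE) {
  rows <- lapply(events, function(ev) {
    a <- classify_crossing(margin, ev, probability = probability)
    m <- ev$amplitude_model
    data.frame(
      event = ev$name,
      model = if (m$type == "gaussian") {
        sprintf("gaussian(%.4g, %.4g)", m$mean, m$sd)
      } else {
        sprintf("range(%.4g, %.4g)", m$low, m$high)
      },
      margin = margin,
      status = a$status,
      probability = a$exceedance_probability,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
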