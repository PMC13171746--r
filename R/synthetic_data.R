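# Synthetic neuron populations: per-neuron baseline margins and paired
# control/stress rheobase values with the statistical structure the margin
# analysis assumes, so scenario composition and parameter recovery can be
# exercised without any experimental recordings.

#' Configuration for a synthetic neuron population
#'
#' Central values default to the published ventral CA1 summary (mean margin
#' 18.4 mV, stress rheobase ratio 0.56); the dispersion defaults
#' (`margin_sd = 2` mV, `rheobase_cv = 0.2`) are artifact conventions for
#' plausible cell-to-cell variability, not published quantities.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param margin_mean Mean baseline margin, mV (> 0).
#' @param margin_sd SD of the baseline margin, mV (>= 0).
#' @param gamma_true True stress compression ratio in (0, 1].
#' @param rheobase_ctrl_mean Mean control rheobase, arbitrary current units.
#' @param rheobase_cv Coefficient of variation of control rheobase (>= 0);
#'   stress rheobase carries multiplicative noise at half this CV.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_neurons, margin_mean = 18.4, margin_sd = 2.0,
                              gamma_true = 0.56, rheobase_ctrl_mean = 100,
                              rheobase_cv = 0.2, seed = 1L) {
  stopifnot(is.numeric(n_neurons), length(n_neurons) == 1L,
            is.numeric(margin_mean), is.numeric(margin_sd),
            is.numeric(gamma_true), is.numeric(rheobase_ctrl_mean),
            is.numeric(rheobase_cv), is.numeric(seed))
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L) {
    stop("n_neurons must be >= 1", call. = FALSE)
  }
  if (!is.finite(margin_mean) || margin_mean <= 0) {
    stop("margin_mean must be > 0 mV", call. = FALSE)
  }
  if (!is.finite(margin_sd) || margin_sd < 0) {
    stop("margin_sd must be >= 0 mV", call. = FALSE)
  }
  if (!is.finite(gamma_true) || gamma_true <= 0 || gamma_true > 1) {
    stop("gamma_true must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(rheobase_ctrl_mean) || rheobase_ctrl_mean <= 0) {
    stop("rheobase_ctrl_mean must be > 0", call. = FALSE)
  }
  if (!is.finite(rheobase_cv) || rheobase_cv < 0) {
    stop("rheobase_cv must be >= 0", call. = FALSE)
  }
  structure(list(n_neurons = n_neurons, margin_mean = margin_mean,
                 margin_sd = margin_sd, gamma_true = gamma_true,
                 rheobase_ctrl_mean = rheobase_ctrl_mean,
                 rheobase_cv = rheobase_cv, seed = as.integer(seed)),
            class = "population_config")
}

# Lognormal meanlog/sdlog for a given mean and CV; cv = 0 degenerates to the
# mean exactly.
lognormal_params <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic neuron population
#'
#' Baseline margins are drawn from a gaussian truncated below at 1 mV (by
#' inverse CDF, so `sd = 0` is exact). Spike threshold is fixed at -50 mV (a
#' typical CA1 first-spike threshold; only the margin is a published
#' quantity) and the resting potential derived from it. Control rheobase is
#' lognormal with the configured mean and CV; stress rheobase is
#' `gamma_true x control` with mean-1 multiplicative lognormal noise at
#' CV/2. Identical configs (including seed) yield identical populations, and
#' the caller's RNG state is untouched.
#'
#' @param config A [population_config()].
#' @return data.frame of class `neuron_population` with columns `neuron_id`,
#'   `v_rest`, `v_thr`, `margin`, `i_rh_ctrl`, `i_rh_stress`; the config is
#'   attached as attribute `"config"`.
#' @examples
#' pop <- generate_population(population_config(5, seed = 42))
#' pop$margin
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  local_seed(config$seed, {
    n <- config$n_neurons
    if (config$margin_sd == 0) {
      margin <- rep(config$margin_mean, n)
      if (any(margin < 1)) {
        stop("degenerate margin ", config$margin_mean,
             " mV below the 1 mV truncation bound", call. = FALSE)
      }
    } else {
      # truncated-below-at-1 gaussian via inverse CDF
      p_lo <- stats::pnorm(1, config$margin_mean, config$margin_sd)
      margin <- stats::qnorm(stats::runif(n, p_lo, 1),
                             config$margin_mean, config$margin_sd)
    }
    v_thr <- rep(-50, n)
    v_rest <- v_thr - margin

    if (config$rheobase_cv == 0) {
      i_ctrl <- rep(config$rheobase_ctrl_mean, n)
      noise <- rep(1, n)
    } else {
      lp <- lognormal_params(config$rheobase_ctrl_mean, config$rheobase_cv)
      i_ctrl <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
      np <- lognormal_params(1, config$rheobase_cv / 2)
      noise <- stats::rlnorm(n, np$meanlog, np$sdlog)
    }
    i_stress <- config$gamma_true * i_ctrl * noise

    out <- data.frame(neuron_id = seq_len(n), v_rest = v_rest, v_thr = v_thr,
                      margin = margin, i_rh_ctrl = i_ctrl,
                      i_rh_stress = i_stress)
    attr(out, "config") <- config
    class(out) <- c("neuron_population", "data.frame")
    out
  })
}

#' Recover the compression ratio from paired rheobase values
#'
#' Point estimate is the mean of per-neuron stress/control rheobase ratios;
#' the interval is a seeded percentile bootstrap over neurons.
#'
#' @param pairs A data.frame (or [generate_population()] output) with columns
#'   `i_rh_ctrl` and `i_rh_stress`, at least 2 rows, all values > 0.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed for the bootstrap resampling.
#' @return List with `estimate`, `ci` (length-2 vector), `n`, `n_boot`.
#' @examples
#' pop <- generate_population(population_config(200, seed = 7))
#' recover_gamma(pop)$estimate
#' @export
recover_gamma <- function(pairs, n_boot = 1000L, conf = 0.95, seed = 1L) {
  stopifnot(is.data.frame(pairs),
            all(c("i_rh_ctrl", "i_rh_stress") %in% names(pairs)))
  ctrl <- pairs$i_rh_ctrl
  stress <- pairs$i_rh_stress
  if (nrow(pairs) < 2L) {
    stop("at least 2 rheobase pairs are required, got ", nrow(pairs),
         call. = FALSE)
  }
  if (any(!is.finite(ctrl)) || any(!is.finite(stress)) ||
      any(ctrl <= 0) || any(stress <= 0)) {
    stop("all rheobase values must be finite and > 0", call. = FALSE)
  }
  ratios <- stress / ctrl
  est <- mean(ratios)
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(ratios[sample.int(length(ratios), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n = length(ratios), n_boot = as.integer(n_boot))
}

#' Write a population to CSV
#'
#' Plain CSV with one `# seed: <n>` comment line ahead of the header, so the
#' generating seed travels with the file.
#'
#' @param pop A `neuron_population` (see [generate_population()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  stopifnot(inherits(pop, "neuron_population"))
  config <- attr(pop, "config")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# seed: ", config$seed), con)
  utils::write.csv(as.data.frame(pop), con, row.names = FALSE)
  invisible(path)
}

#' Read a population CSV written by [write_population_csv()]
#'
#' @param path File path.
#' @return data.frame with the population columns; the recorded seed is
#'   attached as attribute `"seed"`.
#' @export
read_population_csv <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- if (grepl("^# seed:", first)) {
    as.integer(sub("^# seed:\\s*", "", first))
  } else NA_integer_
  out <- utils::read.csv(path, comment.char = "#")
  attr(out, "seed") <- seed
  out
}
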