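# Brute-force enumeration oracle: evaluate the closed-form margin at every
# grid point directly, without going through the sweep machinery.
brute_force_extrema <- function(spec, value_sets, params) {
  cells <- expand.grid(value_sets, KEEP.OUT.ATTRS = FALSE)
  margins <- apply(cells, 1L, function(row) {
    s <- spec
    for (j in seq_along(params)) {
      s <- set_param_for_test(s, params[j], row[[j]])
    }
    oracle_margin(s$baseline_margin, s$modifiers)
  })
  c(min = min(margins), max = max(margins))
}

set_param_for_test <- function(spec, parameter, value) {
  base <- sub(":.*$", "", parameter)
  if (base == "baseline_margin") {
    spec$baseline_margin <- value
    return(spec)
  }
  nm <- sub("^[^:]*:", "", parameter)
  for (i in seq_along(spec$modifiers)) {
    m <- spec$modifiers[[i]]
    if ((base == "compression" && m$kind == "compression") ||
        (m$kind == base && m$name == nm)) {
      spec$modifiers[[i]]$magnitude <- value
      return(spec)
    }
  }
  stop("no such parameter in test helper: ", parameter)
}

test_that("parameter_grid validates domains and ordering", {
  g <- parameter_grid("compression", c(0.5, 0.56, 0.62))
  expect_s3_class(g, "parameter_grid")
  expect_error(parameter_grid("compression", c(0.62, 0.5)), "ascending")
  expect_error(parameter_grid("compression", c(0.5, 1.1)), "\\(0, 1\\]")
  expect_error(parameter_grid("compression", numeric()), "non-empty")
  expect_error(parameter_grid("chronic_shift", c(0, 2)), "name a modifier")
  expect_error(parameter_grid("acute_shift:hot", c(-1, 0)), ">= 0")
  expect_error(parameter_grid("wobble", 1), "unknown parameter")
})

test_that("oat compression sweep reproduces the low-millivolt local range", {
  main <- builtin_scenarios()$main
  rep <- oat_sweep(main, list(parameter_grid("compression",
                                             c(0.50, 0.56, 0.62))))
  expect_equal(rep$mode, "oat")
  # 0.50 * 16.4 - 3.2 = 5.0 and 0.62 * 16.4 - 3.2 = 6.968, hand-evaluated
  expect_equal(rep$per_parameter$min_margin, 5.0)
  expect_equal(rep$per_parameter$max_margin, 6.968)
  expect_equal(round_half_up(rep$per_parameter$min_margin, 1), 5.0)
  expect_equal(round_half_up(rep$per_parameter$max_margin, 1), 7.0)
  expect_equal(rep$per_parameter$nominal_margin, 5.984)
  expect_equal(rep$n_evaluated, 3L)
})

test_that("oat inserts the nominal value into grids that omit it", {
  main <- builtin_scenarios()$main
  rep <- oat_sweep(main, list(parameter_grid("acute_shift:hot_spot", 0)))
  # hot spot removed: 0.56 * 16.4 = 9.184; nominal 3.2 added back
  expect_equal(rep$per_parameter$max_margin, 9.184)
  expect_equal(rep$per_parameter$min_margin, 5.984)
  expect_equal(rep$n_evaluated, 2L)
})

test_that("single-point grids at nominal collapse min = max = nominal", {
  main <- builtin_scenarios()$main
  rep <- oat_sweep(main, list(parameter_grid("compression", 0.56),
                              parameter_grid("chronic_shift:inflammation", 2.0)))
  expect_equal(rep$per_parameter$min_margin, rep(5.984, 2))
  expect_equal(rep$per_parameter$max_margin, rep(5.984, 2))
  expect_equal(unname(rep$overall), c(5.984, 5.984))
})

test_that("grids referencing absent modifiers are configuration errors", {
  main <- builtin_scenarios()$main
  expect_error(oat_sweep(main, list(parameter_grid("chronic_shift:lps", 1))),
               "no enabled chronic_shift")
  expect_error(combined_sweep(main,
                              list(parameter_grid("acute_shift:zap", c(0, 1)))),
               "no enabled acute_shift")
  baseline_only <- builtin_scenarios()$baseline
  expect_error(oat_sweep(baseline_only,
                         list(parameter_grid("compression", 0.5))),
               "exactly one enabled compression")
})

test_that("combined sweep enumerates the full product exactly", {
  main <- builtin_scenarios()$main
  rep <- combined_sweep(main, list(
    parameter_grid("compression", c(0.50, 0.62)),
    parameter_grid("chronic_shift:inflammation", c(0, 2.0, 6.0))))
  expect_equal(rep$mode, "combined")
  expect_equal(rep$n_evaluated, 6L)
  expect_equal(nrow(rep$per_parameter), 0L)
  # independent hand enumeration of all six cells
  cells <- sort(c(0.50 * 18.4 - 3.2, 0.50 * 16.4 - 3.2, 0.50 * 12.4 - 3.2,
                  0.62 * 18.4 - 3.2, 0.62 * 16.4 - 3.2, 0.62 * 12.4 - 3.2))
  expect_equal(sort(rep$evaluations$effective_margin), cells)
  expect_equal(unname(rep$overall), c(3.0, 8.208))
  # rows enumerate in lexicographic order of the grid values
  expect_equal(rep$evaluations$compression, rep(c(0.50, 0.62), each = 3))
})

test_that("single-cell products report that cell for both extrema", {
  main <- builtin_scenarios()$main
  rep <- combined_sweep(main, list(
    parameter_grid("compression", 0.5),
    parameter_grid("acute_shift:hot_spot", 0)))
  expect_equal(unname(rep$overall), rep(0.5 * 16.4, 2))
  expect_equal(rep$n_evaluated, 1L)
})

test_that("the product-size cap aborts oversized sweeps by name", {
  main <- builtin_scenarios()$main
  big <- parameter_grid("chronic_shift:inflammation", seq(0, 1.5, by = 0.01))
  expect_error(combined_sweep(main, list(big), cap = 100), "151")
})

test_that("sweep extrema match brute-force enumeration on random grids", {
  main <- builtin_scenarios()$main
  params <- c("baseline_margin", "compression", "chronic_shift:inflammation",
              "acute_shift:hot_spot")
  nominal <- c(18.4, 0.56, 2.0, 3.2)
  set.seed(405)
  for (rep_i in 1:10) {
    picks <- sort(sample(length(params), sample(2:3, 1)))
    grids <- list()
    sets <- list()
    for (k in picks) {
      vals <- switch(params[k],
        baseline_margin = sort(runif(3, 12, 25)),
        compression = sort(runif(3, 0.3, 1)),
        sort(runif(3, 0, 4)))
      vals <- unique(c(vals, nominal[k]))
      vals <- sort(vals)
      grids <- c(grids, list(parameter_grid(params[k], vals)))
      sets <- c(sets, list(vals))
    }
    comb <- combined_sweep(main, grids)
    bf <- brute_force_extrema(main, sets, params[picks])
    expect_equal(unname(comb$overall), unname(bf))

    oat <- oat_sweep(main, grids)
    # oat-by-hand: vary each axis alone
    for (j in seq_along(picks)) {
      margins <- vapply(sets[[j]], function(v) {
        s <- set_param_for_test(main, params[picks[j]], v)
        oracle_margin(s$baseline_margin, s$modifiers)
      }, numeric(1))
      expect_equal(oat$per_parameter$min_margin[j], min(margins))
      expect_equal(oat$per_parameter$max_margin[j], max(margins))
    }
    # the product contains the one-at-a-time axes, so it brackets them
    expect_lte(comb$overall[["min"]], oat$overall[["min"]] + 1e-12)
    expect_gte(comb$overall[["max"]], oat$overall[["max"]] - 1e-12)
  }
})

test_that("monotone shift grids yield monotone margin sequences", {
  main <- builtin_scenarios()$main
  rep <- oat_sweep(main, list(
    parameter_grid("chronic_shift:inflammation", c(0, 1, 2, 4, 8))))
  ev <- rep$evaluations
  expect_false(is.unsorted(rev(ev$effective_margin)))
  rep2 <- oat_sweep(main, list(
    parameter_grid("acute_shift:hot_spot", c(0, 2, 4, 8))))
  expect_false(is.unsorted(rev(rep2$evaluations$effective_margin)))
})
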