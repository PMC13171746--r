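test_that("compute_margin is threshold minus rest and rejects bad pairs", {
  expect_equal(compute_margin(v_thr = -50, v_rest = -68.4), 18.4)
  expect_equal(compute_margin(v_thr = 0, v_rest = -10), 10)
  expect_error(compute_margin(-50, -50), "-50")
  expect_error(compute_margin(-60, -50), "exceed")
  expect_error(compute_margin(Inf, -60), "non-finite")
  expect_error(compute_margin(NA_real_, -60))
})

test_that("membrane_state derives the margin and accepts margin-only", {
  st <- membrane_state(v_rest = -68.4, v_thr = -50)
  expect_s3_class(st, "membrane_state")
  expect_equal(st$margin, 18.4)
  st2 <- membrane_state(margin = 18.4)
  expect_equal(st2$margin, 18.4)
  expect_true(is.na(st2$v_rest))
  expect_error(membrane_state(v_rest = -50), "both")
  expect_error(membrane_state(margin = 0), "> 0")
  expect_error(membrane_state(v_rest = -68, v_thr = -50, margin = 5),
               "does not equal")
})

test_that("modifier constructor enforces kind-specific magnitude domains", {
  expect_equal(modifier("g", "compression", 0.56)$magnitude, 0.56)
  expect_equal(modifier("s", "chronic_shift", 0)$magnitude, 0)
  expect_error(modifier("g", "compression", 0), "\\(0, 1\\]")
  expect_error(modifier("g", "compression", 1.2), "margin-widening")
  expect_error(modifier("s", "acute_shift", -1), ">= 0")
  expect_error(modifier("s", "sideways", 1))
})

test_that("gamma_from_rheobase returns the ratio and polices its domain", {
  expect_equal(gamma_from_rheobase(56, 100), 0.56)
  expect_equal(gamma_from_rheobase(100, 100), 1.0)
  expect_error(gamma_from_rheobase(0, 100), "> 0")
  expect_error(gamma_from_rheobase(50, -1), "> 0")
  expect_warning(g <- gamma_from_rheobase(120, 100), "margin-widening")
  expect_equal(g, 1.2)
  expect_error(modifier("g", "compression",
                        suppressWarnings(gamma_from_rheobase(120, 100))))
})

test_that("apply_scenario reproduces the cumulative-equation scenarios", {
  main <- apply_scenario(18.4, main_modifiers())
  expect_equal(main$effective_margin, 5.984)
  expect_false(main$clamped)

  strong <- apply_scenario(18.4, list(
    modifier("stress", "compression", 0.56),
    modifier("inflammation", "chronic_shift", 6.0),
    modifier("hot_spot", "acute_shift", 3.2)))
  expect_equal(strong$effective_margin, 3.744)

  idty <- apply_scenario(18.4, list())
  expect_equal(idty$effective_margin, 18.4)
  expect_equal(idty$percent_reduction, 0)
  expect_equal(nrow(idty$decomposition), 0L)

  # a membrane_state baseline behaves like its margin
  st <- membrane_state(v_rest = -68.4, v_thr = -50)
  expect_equal(apply_scenario(st, main_modifiers())$effective_margin, 5.984)
})

test_that("negative raw margins floor at 0 with the clamped flag", {
  res <- apply_scenario(18.4, list(
    modifier("stress", "compression", 0.56),
    modifier("inflammation", "chronic_shift", 2.0),
    modifier("huge", "acute_shift", 100)))
  expect_equal(res$effective_margin, 0)
  expect_true(res$clamped)
  expect_equal(res$percent_reduction, 100)
})

test_that("apply_scenario rejects undefined-equation inputs", {
  expect_error(apply_scenario(0, list()), "> 0")
  expect_error(apply_scenario(-5, list()), "> 0")
  expect_error(
    apply_scenario(10, list(modifier("c", "chronic_shift", 10))),
    "reserve")
  expect_error(
    apply_scenario(10, list(modifier("c1", "chronic_shift", 6),
                            modifier("c2", "chronic_shift", 5))),
    "reserve")
})

test_that("disabled modifiers are skipped but valid", {
  res <- apply_scenario(18.4, list(
    modifier("stress", "compression", 0.56, enabled = FALSE),
    modifier("inflammation", "chronic_shift", 2.0)))
  expect_equal(res$effective_margin, 16.4)
  expect_equal(res$decomposition$name, "inflammation")
})

test_that("decomposition chains: each after feeds the next before", {
  set.seed(401)
  for (rep in 1:25) {
    baseline <- runif(1, 5, 30)
    mods <- random_modifiers(baseline)
    res <- apply_scenario(baseline, mods)
    d <- res$decomposition
    if (nrow(d) >= 1L) {
      expect_equal(d$before[1], baseline)
      expect_equal(d$after[nrow(d)], res$effective_margin)
      if (nrow(d) > 1L) {
        expect_equal(d$after[-nrow(d)], d$before[-1])
      }
      # phases are canonical: chronic, then compression, then acute
      expect_false(is.unsorted(match(d$kind, c("chronic_shift", "compression",
                                               "acute_shift"))))
    } else {
      expect_equal(res$effective_margin, baseline)
    }
  }
})

test_that("modifier input order never changes the result", {
  set.seed(402)
  for (rep in 1:25) {
    baseline <- runif(1, 5, 30)
    mods <- random_modifiers(baseline)
    if (length(mods) < 2) next
    ref <- apply_scenario(baseline, mods)$effective_margin
    for (k in 1:3) {
      perm <- sample(mods)
      expect_equal(apply_scenario(baseline, perm)$effective_margin, ref)
    }
  }
})

test_that("scenario composition equals the closed-form oracle", {
  set.seed(403)
  for (rep in 1:50) {
    baseline <- runif(1, 5, 30)
    mods <- random_modifiers(baseline)
    expect_equal(apply_scenario(baseline, mods)$effective_margin,
                 oracle_margin(baseline, mods))
  }
})

test_that("adding a pro-excitatory modifier never widens the margin", {
  set.seed(404)
  for (rep in 1:25) {
    baseline <- runif(1, 5, 30)
    mods <- random_modifiers(baseline)
    before <- apply_scenario(baseline, mods)$effective_margin
    extra <- switch(sample(3, 1),
                    modifier("xg", "compression", runif(1, 0.2, 1)),
                    modifier("xc", "chronic_shift",
                             runif(1, 0, max(0, (baseline -
                               oracle_chronic_sum(mods)) * 0.9))),
                    modifier("xa", "acute_shift", runif(1, 0, 10)))
    after <- apply_scenario(baseline, c(mods, list(extra)))$effective_margin
    expect_lte(after, before + 1e-12)
  }
})

test_that("effective margin is affine in the compression coefficient", {
  # for fixed shifts and a single compression g: margin = g * (M0 - C) - A
  # (unclamped), so the slope over g is (M0 - C)
  baseline <- 18.4
  shifts <- list(modifier("inflammation", "chronic_shift", 2.0),
                 modifier("hot_spot", "acute_shift", 3.2))
  at <- function(g) {
    apply_scenario(baseline, c(list(modifier("g", "compression", g)),
                               shifts))$effective_margin
  }
  gs <- c(0.4, 0.56, 0.7, 0.9)
  vals <- vapply(gs, at, numeric(1))
  slopes <- diff(vals) / diff(gs)
  expect_equal(slopes, rep(baseline - 2.0, length(slopes)))
})

test_that("percent_reduction matches the published reduction and its domain", {
  expect_equal(percent_reduction(18.4, 5.984), 100 * (18.4 - 5.984) / 18.4)
  expect_equal(round_half_up(percent_reduction(18.4, 5.984), 1), 67.5)
  expect_equal(percent_reduction(18.4, 18.4), 0)
  expect_equal(percent_reduction(10, 0), 100)
  expect_error(percent_reduction(0, 0), "> 0")
  expect_error(percent_reduction(10, 12), "margin-widening")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(3.744, 1), 3.7)
  expect_equal(round_half_up(5.984, 1), 6.0)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(67.45, 1), 67.5)
})
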