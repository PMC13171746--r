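# Shared helpers: an independent closed-form oracle for scenario
# composition, and a generator of random valid modifier sets.

# Direct evaluation of gamma_prod * (M0 - sum(chronic)) - sum(acute),
# floored at 0 — written against the equation, not the implementation.
oracle_margin <- function(baseline, modifiers) {
  mods <- Filter(function(m) m$enabled, modifiers)
  mag <- function(kind) {
    vapply(Filter(function(m) m$kind == kind, mods), `[[`, numeric(1),
           "magnitude")
  }
  gamma <- prod(mag("compression"))
  raw <- gamma * (baseline - sum(mag("chronic_shift"))) - sum(mag("acute_shift"))
  max(0, raw)
}

# Random valid modifier set for a given baseline: 0-2 compressions, 0-2
# chronic shifts (kept well below baseline), 0-2 acute shifts.
random_modifiers <- function(baseline) {
  mods <- list()
  for (i in seq_len(sample(0:2, 1))) {
    mods <- c(mods, list(modifier(paste0("g", i), "compression",
                                  runif(1, 0.3, 1))))
  }
  n_chronic <- sample(0:2, 1)
  if (n_chronic > 0) {
    shifts <- runif(n_chronic, 0, baseline * 0.8 / n_chronic)
    for (i in seq_len(n_chronic)) {
      mods <- c(mods, list(modifier(paste0("c", i), "chronic_shift",
                                    shifts[i])))
    }
  }
  for (i in seq_len(sample(0:2, 1))) {
    mods <- c(mods, list(modifier(paste0("a", i), "acute_shift",
                                  runif(1, 0, baseline))))
  }
  mods
}

oracle_chronic_sum <- function(modifiers) {
  sum(vapply(Filter(function(m) m$enabled && m$kind == "chronic_shift",
                    modifiers), `[[`, numeric(1), "magnitude"))
}

main_modifiers <- function() {
  list(modifier("stress", "compression", 0.56),
       modifier("inflammation", "chronic_shift", 2.0),
       modifier("hot_spot", "acute_shift", 3.2))
}
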