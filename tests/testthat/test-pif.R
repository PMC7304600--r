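test_that("distribution-shift PIF vanishes for null shifts and flat RRs", {
  expect_equal(pif_distribution_shift(log(27), 0.16, 0, 1.1, 22), 0)
  expect_equal(pif_distribution_shift(log(27), 0.16, -1, 1, 22), 0)
})

test_that("distribution-shift PIF matches the no-kink closed form", {
  # with the whole support above TMREL, a shift of -d gives
  # pif = 1 - rr^(-d) exactly
  pif <- pif_distribution_shift(log(25), 0.15, -1, 1.1, tmrel = 0)
  expect_equal(pif, 1 - 1.1^(-1), tolerance = 1e-4)
  pif2 <- pif_distribution_shift(log(25), 0.15, -0.5, 1.07, tmrel = 0)
  expect_equal(pif2, 1 - 1.07^(-0.5), tolerance = 1e-4)
})

test_that("trapezoid integration is stable under 10x refinement", {
  for (sh in c(-2, -0.5, 0.7)) {
    a <- pif_distribution_shift(log(27), 0.16, sh, 1.1, 22,
                                n_nodes = 2001)
    b <- pif_distribution_shift(log(27), 0.16, sh, 1.1, 22,
                                n_nodes = 20001)
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("out-of-grid shifts raise a tolerance error", {
  expect_error(pif_distribution_shift(log(27), 0.16, -40, 1.1, 22),
               "outside the integration grid")
})

test_that("RR-shift PIF evaluates the categorical formula, sign included", {
  expect_equal(pif_rr_shift(c(0.2, 0.8), c(0.2, 0.8), c(1.5, 1)), 0)
  expect_equal(pif_rr_shift(c(0.2, 0.8), c(0.1, 0.9), c(1.5, 1)),
               0.05 / 1.10)
  expect_equal(pif_rr_shift(c(0.1, 0.9), c(0.2, 0.8), c(1.5, 1)),
               -0.05 / 1.05)
  expect_error(pif_rr_shift(c(0.5, 0.5), c(0.3, 0.3, 0.4), c(1.2, 1)),
               "equal length")
  expect_error(pif_rr_shift(c(0.5, 0.4), c(0.5, 0.5), c(1.2, 1)), "sum to 1")
})

test_that("multiplicative combination is commutative, associative, identity-0", {
  expect_equal(combine_pifs(0, 0.3), 0.3)
  expect_equal(combine_pifs(0.1, 0.2), 0.28)
  set.seed(7)
  a <- runif(20, -0.5, 0.9); b <- runif(20, -0.5, 0.9)
  cc <- runif(20, -0.5, 0.9)
  expect_equal(combine_pifs(a, b), combine_pifs(b, a))
  expect_equal(combine_pifs(combine_pifs(a, b), cc),
               combine_pifs(a, combine_pifs(b, cc)))
})

test_that("intervention PIF table routes paths and respects zero shifts", {
  b <- toy_bundle()
  spec <- b$interventions[1, ]
  eb <- energy_balance_params()
  z <- spec; z$uptake <- 0
  d0 <- build_risk_deltas(z, b$population, b$growth_reference, eb)
  expect_true(all(pifs_for_intervention(d0, b) == 0))

  d <- build_risk_deltas(spec, b$population, b$growth_reference, eb)
  pif <- pifs_for_intervention(d, b)
  expect_true(all(pif <= 1))
  expect_true(all(pif[, , 1] > 0))  # BMI-related: both diseases respond
})

test_that("fast PIF table agrees with the exact-node operation", {
  b <- generate_bundle(default_config(), seed = 1)
  spec <- b$interventions[b$interventions$name == "ssb_tax", ]
  eb <- do.call(energy_balance_params, b$settings$energy_balance)
  d <- build_risk_deltas(spec, b$population, b$growth_reference, eb)
  pif <- pifs_for_intervention(d, b)
  rrb <- b$rr[b$rr$risk_factor == "bmi", ]
  for (s in c(10, 60, 120, 190)) {
    for (dd in seq_len(nrow(b$diseases))) {
      id <- b$diseases$disease_id[dd]
      restr <- b$diseases$sex_restriction[dd]
      if (!is.na(restr) && b$population$sex[s] != restr) next
      rrq <- rrb[rrb$disease_id == id, ]
      ref <- pif_distribution_shift(b$population$bmi_mu[s],
                                    b$population$bmi_sigma[s],
                                    d$bmi_shift[s, 1], rrq$rr, rrq$tmrel)
      expect_lt(abs(pif[s, dd, 1] - ref), 1e-5)
    }
  }
})

test_that("PIF is monotone in the size of a beneficial shift when RR > 1", {
  shifts <- seq(-0.2, -3, by = -0.2)
  vals <- vapply(shifts, function(sh)
    pif_distribution_shift(log(27), 0.16, sh, 1.1, 22), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("activity and joint paths combine multiplicatively in the table", {
  b <- toy_bundle()
  met <- b$interventions[1, ]
  met$effect_type <- "met_min_per_week"; met$effect_size <- 600
  eb <- energy_balance_params()
  d <- build_risk_deltas(met, b$population, b$growth_reference, eb)
  pif <- pifs_for_intervention(d, b)
  # disease_a: BMI path only; disease_b: both, so strictly larger than
  # either single path
  s <- 1
  rrb <- b$rr[b$rr$risk_factor == "bmi" & b$rr$disease_id == "disease_b", ]
  p_bmi <- pif_distribution_shift(b$population$bmi_mu[s],
                                  b$population$bmi_sigma[s],
                                  d$bmi_shift[s, 1], rrb$rr, rrb$tmrel)
  p0 <- as.numeric(b$population[s, paste0("pa_", c("inactive", "low",
                                                   "moderate", "high"))])
  p1 <- pmslt:::shift_pa_prevalence(p0, d$pa_frac[s, 1])
  rrpa <- b$rr[b$rr$risk_factor == "pa", ]
  p_pa <- pif_rr_shift(p0, p1, rrpa$rr[match(c("inactive", "low",
                                               "moderate", "high"),
                                             rrpa$category)])
  expect_equal(unname(pif[s, 2, 1]), combine_pifs(p_bmi, p_pa),
               tolerance = 1e-5)
  expect_gt(pif[s, 2, 1], pif[s, 1, 1])
})

test_that("PIF tables serialise to a long data frame", {
  b <- toy_bundle()
  d <- build_risk_deltas(b$interventions[1, ], b$population,
                         b$growth_reference, energy_balance_params())
  pif <- pifs_for_intervention(d, b)
  df <- pif_table_to_df(pif, b$population)
  expect_named(df, c("disease", "age", "sex", "year", "pif"))
  expect_equal(nrow(df), prod(dim(pif)))
  expect_equal(df$pif[df$disease == "disease_a" & df$age == 50 &
                        df$year == 0], unname(pif[1, 1, 1]))
})
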