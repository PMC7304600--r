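test_that("generated population covers the full age-sex grid with valid strata", {
  pop <- generate_population(default_config(), seed = 1)
  expect_equal(nrow(pop), 99 * 2)
  expect_setequal(unique(pop$age), 2:100)
  pa <- rowSums(pop[grep("^pa_", names(pop))])
  expect_true(all(abs(pa - 1) < 1e-9))
  expect_true(all(pop$bmi_sigma > 0))
  expect_true(all(pop$yld_all_cause >= 0 & pop$yld_all_cause < 1))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  b1 <- generate_bundle(default_config(), seed = 1)
  b2 <- generate_bundle(default_config(), seed = 1)
  b3 <- generate_bundle(default_config(), seed = 2)
  expect_identical(b1, b2)
  expect_false(identical(b1$population$bmi_mu, b3$population$bmi_mu))
})

test_that("invalid configuration is rejected with the field named", {
  cfg <- default_config()
  cfg$population$bmi$sigma_adult <- -0.1
  expect_error(generate_population(cfg), "sigma")
  cfg2 <- default_config()
  cfg2$diseases$params$tmrel[1] <- 30
  expect_error(validate_config(cfg2), "tmrel")
})

test_that("disease catalogue has nine diseases, five activity-related", {
  cat9 <- generate_disease_catalogue(default_config())
  expect_equal(nrow(cat9$diseases), 9)
  expect_equal(sum(cat9$diseases$pa_related), 5)
  expect_true(all(cat9$disease_rates$incidence >= 0))
  # every disease carries a BMI RR; activity RRs have a unit reference band
  expect_equal(sum(cat9$rr$risk_factor == "bmi"), 9)
  ref <- tapply(cat9$rr$rr[cat9$rr$risk_factor == "pa"],
                cat9$rr$disease_id[cat9$rr$risk_factor == "pa"], min)
  expect_true(all(ref == 1))
})

test_that("steady-state prevalence matches the cumulative-incidence closed form", {
  # remission-free, fatality-free disease with constant incidence i:
  # prevalence at age a is 1 - (1 - q)^(a - a0), q = 1 - exp(-i)
  b <- toy_bundle()
  b$disease_rates$case_fatality <- 0
  ss <- steady_state_prevalence(b)
  i <- 0.02
  q <- 1 - exp(-i)
  sa <- ss[ss$disease_id == "disease_a", ]
  expected <- 1 - (1 - q)^(sa$age - 50)
  expect_lt(max(abs(sa$prevalence - expected)), 1e-8)
})

test_that("steady-state prevalence of the default catalogue is finite and below 0.5", {
  ss <- steady_state_prevalence(generate_bundle(default_config(), seed = 1))
  expect_true(all(is.finite(ss$prevalence)))
  expect_lt(max(ss$prevalence), 0.5)
})

test_that("default interventions mirror the study mix", {
  iv <- generate_interventions(default_config())
  expect_equal(nrow(iv$interventions), 16)
  expect_equal(sum(iv$interventions$classification == "regulatory"), 9)
  expect_equal(sum(iv$interventions$classification == "program"), 7)
  child <- iv$interventions$target_age_hi <= 17
  expect_equal(sum(child), 4)
  expect_equal(sum(iv$interventions$effect_type == "met_min_per_week"), 4)
})

test_that("invalid intervention templates are rejected", {
  cfg <- default_config()
  cfg$interventions$specs$uptake[1] <- 1.2
  expect_error(generate_interventions(cfg), "uptake")
  cfg2 <- default_config()
  cfg2$interventions$specs$effect_type[1] <- "calories"
  expect_error(generate_interventions(cfg2), "effect_type")
  cfg3 <- default_config()
  i <- which(cfg3$interventions$specs$effect_type == "bmi_z_delta")[1]
  cfg3$interventions$specs$target_age_hi[i] <- 30
  expect_error(generate_interventions(cfg3), "child")
})

test_that("bundle save/load round-trips losslessly and is column-order free", {
  b <- generate_bundle(default_config(), seed = 1)
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  for (el in c("population", "diseases", "disease_rates", "rr",
               "growth_reference", "interventions", "cost_components"))
    expect_equal(b2[[el]], b[[el]], ignore_attr = FALSE)
  expect_equal(b2$settings$energy_balance$rho_adult,
               b$settings$energy_balance$rho_adult)

  # shuffled column order loads identically
  f <- file.path(dir, "population.csv")
  df <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
  utils::write.csv(df[rev(names(df))], f, row.names = FALSE)
  b3 <- load_bundle(dir)
  expect_equal(b3$population, b2$population)
})

test_that("saving the same seed twice is byte-identical; truncated files are named", {
  b <- generate_bundle(default_config(), seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_bundle(b, d1); save_bundle(generate_bundle(default_config(), 5), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  df <- utils::read.csv(file.path(d1, "diseases.csv"))
  utils::write.csv(df[setdiff(names(df), "disability_weight")],
                   file.path(d1, "diseases.csv"), row.names = FALSE)
  expect_error(load_bundle(d1), "diseases.csv.*disability_weight")
})

test_that("partial YAML configuration overrides defaults", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("seed: 7", "discount_rate: 0.05"), f)
  cfg <- read_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$discount_rate, 0.05)
  expect_equal(cfg$wtp, default_config()$wtp)
})

test_that("bundle validator enforces the epidemiological invariants", {
  b <- toy_bundle()
  expect_silent(validate_bundle(b))
  b_bad <- b
  b_bad$population$pa_inactive <- b_bad$population$pa_inactive + 0.1
  expect_error(validate_bundle(b_bad), "sum to 1")
  b_bad2 <- b
  b_bad2$population$mortality_all_cause <- 1e-4
  # the residual-mortality floor warns before the validator rejects
  expect_error(suppressWarnings(validate_bundle(b_bad2)),
               "all-cause mortality")
  b_bad3 <- b
  b_bad3$disease_rates$incidence <- 0.9  # prevalence blows past 0.5
  expect_error(suppressWarnings(validate_bundle(b_bad3)), "prevalence")
})
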