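test_that("intervention costing applies loadings, indexing and discounting", {
  rules <- costing_rules(wage_rate = 40)
  expect_equal(cost_intervention(NULL, rules)$total_discounted, 0)

  one <- data.frame(sector = "federal_govt", amount = 100, year_first = 0,
                    year_last = 0, health_related = FALSE,
                    time_cost = FALSE)
  r <- cost_intervention(one, rules, discount_rate = 0.03)
  expect_equal(r$total_discounted, 100)
  expect_equal(r$first3y_undiscounted, 100)

  # 10 person-hours at wage 40, public sector: 10*40*1.13*1.175
  tc <- data.frame(sector = "state_govt", amount = 10, year_first = 0,
                   year_last = 0, health_related = FALSE, time_cost = TRUE)
  expect_equal(cost_intervention(tc, rules)$total_discounted, 531.10)
  tcp <- tc; tcp$sector <- "industry"
  expect_equal(cost_intervention(tcp, rules)$total_discounted,
               10 * 40 * 1.14 * 1.175)

  # price indexing to the reference year
  rules_idx <- costing_rules(health_price_index = c("2008" = 0.9,
                                                    "2010" = 1),
                             gdp_index = c("2008" = 0.95, "2010" = 1))
  hh <- data.frame(sector = "federal_govt", amount = 90, year_first = 0,
                   year_last = 0, health_related = TRUE, time_cost = FALSE,
                   price_year = 2008)
  expect_equal(cost_intervention(hh, rules_idx)$total_discounted, 100)
  hh$price_year <- 1999
  expect_error(cost_intervention(hh, rules_idx), "1999")

  # a flat stream discounts as an annuity
  st <- data.frame(sector = "federal_govt", amount = 1, year_first = 0,
                   year_last = 2, health_related = FALSE,
                   time_cost = FALSE)
  expect_equal(cost_intervention(st, rules, 0.03)$total_discounted,
               1 + 1 / 1.03 + 1 / 1.03^2, tolerance = 1e-12)
  expect_equal(cost_intervention(st, rules, 0.03)$first3y_undiscounted, 3)
})

test_that("ICER and dominance classification cover the sign partition", {
  expect_equal(compute_icer(-100, 50)$dominance_class, "dominant")
  r <- compute_icer(1e6, 100)
  expect_equal(r$icer, 10000)
  expect_equal(r$dominance_class, "cost_effective")
  expect_equal(compute_icer(6e6, 100)$dominance_class,
               "not_cost_effective")
  expect_equal(compute_icer(100, -5)$dominance_class, "dominated")
  expect_equal(compute_icer(-100, -5)$dominance_class,
               "not_cost_effective")
  expect_equal(compute_icer(10, 0)$icer, Inf)
  expect_equal(compute_icer(-10, 0)$dominance_class,
               "cost_saving_health_neutral")
  # the published menu-labelling row: costs 170M, offsets 672M -> dominant
  expect_equal(compute_icer(170e6 - 672e6, 63492)$dominance_class,
               "dominant")
})

test_that("ICERs scale with currency while dominance is invariant", {
  set.seed(3)
  for (k in c(0.5, 2, 10)) {
    net <- runif(5, -1e6, 1e7); hal <- runif(5, 1, 1e4)
    for (i in seq_along(net)) {
      a <- compute_icer(net[i], hal[i])
      bk <- compute_icer(net[i] * k, hal[i], wtp = 50000 * k)
      if (!is.na(a$icer) && is.finite(a$icer))
        expect_equal(bk$icer, a$icer * k)
      expect_equal(bk$dominance_class, a$dominance_class)
    }
  }
})

test_that("league table ranks dominant-by-HALYs then ICER, preserving rows", {
  res <- league_table_fixture()
  lt <- build_league_table(res)
  expect_equal(lt$name[1], "Alcohol price increase: uniform volumetric tax")
  expect_equal(lt$name[16],
               "Workplace intervention to reduce sedentary behaviour")
  expect_equal(sum(lt$dominance_class[1:11] == "dominant"), 11)
  expect_setequal(lt$name, res$name)          # permutation, nothing lost
  lt2 <- build_league_table(lt[, names(res)]) # idempotent
  expect_equal(lt2$name, lt$name)

  same <- data.frame(name = c("b", "a"), halys_gained = c(10, 10),
                     icer = NA_real_, dominance_class = "dominant")
  expect_equal(build_league_table(same)$name, c("a", "b"))
  single <- data.frame(name = "x", halys_gained = 1, icer = 5,
                       dominance_class = "cost_effective")
  expect_equal(build_league_table(single)$rank, 1)
})

test_that("mid-50% ranges match a brute-force rank-dropping oracle", {
  brute <- function(x) {
    x <- sort(x); k <- floor(length(x) / 4)
    kept <- x[(k + 1):(length(x) - k)]
    c(low = min(kept), high = max(kept))
  }
  set.seed(9)
  for (n in c(5, 9, 16, 17, 31)) {
    x <- rnorm(n)
    expect_equal(pmslt:::mid50_range(x), brute(x))
  }
})

test_that("portfolio summary reproduces the published aggregate arithmetic", {
  res <- league_table_fixture()
  ps <- portfolio_summary(res)
  expect_equal(ps$n_dominant, 11)
  expect_equal(ps$n_cost_effective, 16)
  expect_equal(unname(ps$mid50$halys), c(28981, 73883))
  expect_equal(unname(ps$mid50$intervention_cost), c(15e6, 170e6))
  expect_equal(unname(ps$mid50$net_cost), c(-638e6, 2e6))
  expect_equal(ps$icer_range_nondominant, c(1728, 28703))
  expect_equal(ps$first3y_total, 3101.5e6)
  # the cost and health-gain contrasts behind the dominance discussion
  expect_gt(ps$ratios$cost_nondominant_over_dominant, 9)
  expect_lt(ps$ratios$halys_dominant_over_nondominant, 3)
})
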