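# A small two-disease bundle: one real cohort (age 50, female, 50,000
# persons) followed to age 100, with zero-count rows supplying the age
# schedules. Rates are moderate so the proportional (additive-hazard)
# approximation the life table makes is well inside its validity range.
toy_bundle <- function(start_age = 50, count = 5e4,
                       effect_size = -2, uptake = 1) {
  ages <- start_age:100
  pop <- data.frame(
    age = as.integer(ages), sex = "female",
    count = ifelse(ages == start_age, count, 0),
    bmi_mu = log(27), bmi_sigma = 0.15,
    pa_inactive = 0.3, pa_low = 0.3, pa_moderate = 0.25, pa_high = 0.15,
    mean_height = 1.65,
    mortality_all_cause = 0.01 + 0.001 * (ages - start_age),
    yld_all_cause = 0.05, stringsAsFactors = FALSE)
  diseases <- data.frame(
    disease_id = c("disease_a", "disease_b"),
    pa_related = c(FALSE, TRUE), sex_restriction = NA_character_,
    onset_age = c(30, 30), disability_weight = c(0.2, 0.1),
    annual_cost_per_case = c(5000, 3000), bmi_related = TRUE,
    stringsAsFactors = FALSE)
  dr <- expand.grid(disease_id = diseases$disease_id,
                    age = as.integer(ages), sex = "female",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dr$incidence <- ifelse(dr$disease_id == "disease_a", 0.02, 0.015)
  dr$case_fatality <- ifelse(dr$disease_id == "disease_a", 0.05, 0.03)
  dr$remission <- 0
  rr <- rbind(
    data.frame(disease_id = diseases$disease_id, risk_factor = "bmi",
               form = "loglinear_per_unit", category = NA_character_,
               rr = c(1.12, 1.08), log_se = 0.03, tmrel = c(20, 22),
               stringsAsFactors = FALSE),
    data.frame(disease_id = "disease_b", risk_factor = "pa",
               form = "categorical",
               category = c("inactive", "low", "moderate", "high"),
               rr = c(1.4, 1.2, 1.1, 1), log_se = 0.06, tmrel = NA_real_,
               stringsAsFactors = FALSE))
  iv <- data.frame(
    name = "toy_iv", classification = "program",
    target_age_lo = 18, target_age_hi = 100, target_sexes = "both",
    effect_type = "bmi_delta", effect_size = effect_size,
    effect_se = abs(effect_size) * 0.15, uptake = uptake,
    implementation_years = 1, maintenance = "sustained",
    maintenance_end_year = NA_real_, stringsAsFactors = FALSE)
  cc <- data.frame(
    intervention = "toy_iv", label = "delivery", sector = "federal_govt",
    amount = 1e6, year_first = 0, year_last = 0, health_related = TRUE,
    time_cost = FALSE, price_year = 2010, stringsAsFactors = FALSE)
  structure(list(
    population = pop, diseases = diseases, disease_rates = dr, rr = rr,
    growth_reference = data.frame(age = integer(), sex = character(),
                                  L = numeric(), M = numeric(),
                                  S = numeric()),
    interventions = iv, cost_components = cc,
    settings = list(seed = 1L,
                    energy_balance = list(rho_adult = 94, rho_child = 100,
                                          met_kcal_coeff = 0.0175,
                                          kj_per_kcal = 4.184),
                    flags = list(pa_affects_bmi = TRUE, net_mets = FALSE),
                    child_hrql_coeff = 0.005, discount_rate = 0.03,
                    wtp = 50000,
                    pa_bands = c("inactive", "low", "moderate", "high"),
                    pa_met_midpoints = c(0, 300, 900, 1800))
  ), class = "pmslt_bundle")
}

# Individual-level microsimulation oracle for the toy bundle: annual
# cycles with the same update order and rate-to-probability conversion as
# the cohort engine, but simulated agent by agent. Returns discounted
# HALYs per person with its Monte Carlo standard error.
microsim_halys <- function(bundle, incidence_scale, n_agents, seed,
                           discount_rate = 0.03) {
  eng <- pmslt:::prepare_engine(bundle)
  base <- run_lifetable(bundle, discount_rate = discount_rate)
  s0 <- which(bundle$population$count > 0)
  stopifnot(length(s0) == 1)
  nd <- eng$nd; Y <- eng$Y
  dw <- eng$dw
  # residual morbidity so absolute yld matches the cohort convention
  p_base <- base$P[s0, , , drop = FALSE]
  dim(p_base) <- c(nd, Y)
  yld_resid <- eng$yld_sy[s0, ] - as.vector(dw %*% p_base)
  disc <- (1 + discount_rate)^(-(0:(Y - 1)))
  set.seed(seed)
  alive <- rep(TRUE, n_agents)
  sick <- matrix(FALSE, n_agents, nd)
  haly <- numeric(n_agents)
  for (y in seq_len(Y)) {
    if (!eng$active[s0, y]) break
    cf_y <- eng$cf_cube[s0, , y]
    yld_a <- pmin(1, pmax(0, yld_resid[y] + as.vector(sick %*% dw)))
    haz <- eng$resid_sy[s0, y] + as.vector(sick %*% cf_y)
    die <- alive & (stats::runif(n_agents) < 1 - exp(-haz))
    w <- ifelse(alive, ifelse(die, 0.5, 1), 0)
    haly <- haly + w * (1 - yld_a) * disc[y]
    alive <- alive & !die
    for (d in seq_len(nd)) {
      qi <- 1 - exp(-eng$inc_cube[s0, d, y] * incidence_scale[d, y])
      newly <- alive & !sick[, d] & (stats::runif(n_agents) < qi)
      sick[newly, d] <- TRUE
    }
  }
  list(mean = mean(haly), se = stats::sd(haly) / sqrt(n_agents))
}

# Incidence scale matrix (1 - PIF) for the toy cohort under its
# intervention, via the package's own PIF machinery.
toy_incidence_scale <- function(bundle) {
  spec <- bundle$interventions[1, ]
  eb <- do.call(energy_balance_params, bundle$settings$energy_balance)
  deltas <- build_risk_deltas(spec, bundle$population,
                              bundle$growth_reference, eb)
  pif <- pifs_for_intervention(deltas, bundle)
  s0 <- which(bundle$population$count > 0)
  sc <- pif[s0, , , drop = FALSE]
  dim(sc) <- dim(pif)[2:3]
  1 - sc
}
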