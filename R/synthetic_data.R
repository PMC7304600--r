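#' Generate the synthetic population strata
#'
#' Builds one stratum per age (2--100) and sex: cohort size, log-normal BMI
#' distribution parameters (`bmi_mu`, `bmi_sigma` on the log scale),
#' prevalence across four ordered physical-activity bands, mean height,
#' all-cause mortality (Gompertz with a childhood floor) and an all-cause
#' background morbidity (YLD) rate. Deterministic given `seed`; only the
#' stratum-level BMI location parameters carry seeded jitter.
#'
#' @param config a configuration list, see [default_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a data.frame with one row per stratum (199 ages x sexes by
#'   default config: 99 ages x 2 sexes = 198 rows) and columns `age`,
#'   `sex`, `count`, `bmi_mu`, `bmi_sigma`, `pa_<band>` prevalence columns,
#'   `mean_height`, `mortality_all_cause`, `yld_all_cause`.
#' @export
#' @examples
#' pop <- generate_population(default_config(), seed = 1)
#' nrow(pop)  # 198
generate_population <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  p <- config$population
  grid <- expand.grid(age = config$ages, sex = config$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sex, grid$age), , drop = FALSE]
  rownames(grid) <- NULL
  age <- grid$age
  sex <- grid$sex

  # age pyramid: flat to 50, exponential decline after
  w <- ifelse(age <= 50, 1, exp(-(age - 50) / 15))
  w <- w * ifelse(age < 18, 0.9, 1)
  grid$count <- round(p$total_persons * w / sum(w))

  # BMI median trajectory: child medians track the growth reference median
  # plus an overweight offset; adult medians rise to a peak at 60 then ease
  med <- numeric(nrow(grid))
  child <- age < 18
  med[child] <- growth_median_bmi(age[child]) + 0.8
  a <- age[!child]
  med[!child] <- p$bmi$adult_median_young +
    (p$bmi$adult_median_peak - p$bmi$adult_median_young) *
      pmin(1, (a - 18) / 42) - pmax(0, a - 80) * 0.02
  sigma <- ifelse(child, p$bmi$sigma_child, p$bmi$sigma_adult)
  jitter <- local_seed(seed, stats::rnorm(nrow(grid), 0, p$bmi$jitter_sd))
  grid$bmi_mu <- log(med) + jitter
  grid$bmi_sigma <- sigma

  # physical-activity band prevalences (inactive, low, moderate, high):
  # children more active, inactivity rising with adult age
  base_child <- c(0.10, 0.20, 0.30, 0.40)
  base_adult <- c(0.30, 0.30, 0.25, 0.15)
  tilt <- pmin(0.25, pmax(0, (age - 40) / 240))  # shifts mass toward inactive
  pa <- t(vapply(seq_along(age), function(i) {
    b <- if (child[i]) base_child else base_adult
    b <- b + c(tilt[i], 0, -tilt[i] / 2, -tilt[i] / 2)
    b / sum(b)
  }, numeric(4)))
  colnames(pa) <- paste0("pa_", p$pa_bands)
  grid <- cbind(grid, pa)

  adult_h <- ifelse(sex == "female", p$height$adult_female, p$height$adult_male)
  h <- ifelse(child,
              adult_h * (0.45 + 0.55 * stats::plogis((age - 10.5) / 2.8)),
              adult_h * (1 - 0.0005 * pmax(0, age - 70)))
  grid$mean_height <- round(h, 4)

  m <- config$population$mortality
  mort <- m$gompertz_a * exp(m$gompertz_b * age)
  mort <- pmax(mort, m$child_floor)
  mort <- mort * ifelse(sex == "male", 1.15, 0.88)
  grid$mortality_all_cause <- mort

  y <- config$population$yld
  grid$yld_all_cause <- pmin(y$cap,
                             y$base + y$slope_per_year * pmax(0, age - y$onset_age))
  grid
}

# Growth-reference BMI median (M parameter) by age in years, 2-17; dips to
# the adiposity rebound near age 5 then rises.
growth_median_bmi <- function(age) {
  ifelse(age < 5, 15.3 + 0.3 * (5 - age), 15.3 + 0.035 * (age - 5)^2)
}

#' Generate the LMS growth reference
#'
#' LMS (lambda-mu-sigma) parameters mapping BMI z-scores to BMI for ages
#' 2--17 by sex. The reference is synthetic: a smooth median curve with a
#' dip at the adiposity rebound, constant skewness parameter L and an
#' age-linear coefficient of variation S. BMI is monotone in z over
#' z in [-4, 4].
#'
#' @inheritParams generate_population
#' @return data.frame with columns `age`, `sex`, `L`, `M`, `S`.
#' @export
generate_growth_reference <- function(config = default_config(),
                                      seed = config$seed) {
  grid <- expand.grid(age = 2:17, sex = config$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sex, grid$age), , drop = FALSE]
  rownames(grid) <- NULL
  g <- config$growth
  grid$L <- g$L
  grid$M <- growth_median_bmi(grid$age) * ifelse(grid$sex == "male", 1.01, 1)
  grid$S <- g$S_base + g$S_slope * grid$age
  stopifnot(all(grid$M > 0), all(grid$S > 0))
  grid
}

#' Generate the nine-disease catalogue and relative-risk specifications
#'
#' Produces the scalar disease table (disability weight, annual healthcare
#' cost per prevalent case, activity-relatedness, sex restriction), the
#' per-age x sex rate table (incidence, case fatality, remission) and the
#' relative-risk table: a log-linear RR per BMI unit above TMREL for all
#' nine diseases, plus categorical physical-activity RRs (reference band
#' 'high') for the five activity-related diseases.
#'
#' @inheritParams generate_population
#' @return a list with data.frames `diseases`, `disease_rates`, `rr`.
#' @export
#' @examples
#' cat9 <- generate_disease_catalogue(default_config())
#' nrow(cat9$diseases)              # 9
#' sum(cat9$diseases$pa_related)    # 5
generate_disease_catalogue <- function(config = default_config(),
                                       seed = config$seed) {
  dp <- config$diseases$params
  diseases <- dp[, c("disease_id", "pa_related", "sex_restriction",
                     "onset_age", "disability_weight", "annual_cost_per_case")]
  diseases$bmi_related <- TRUE
  rownames(diseases) <- NULL

  grid <- expand.grid(disease_id = dp$disease_id, age = config$ages,
                      sex = config$sexes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$disease_id, grid$sex, grid$age), , drop = FALSE]
  rownames(grid) <- NULL
  i <- match(grid$disease_id, dp$disease_id)
  inc <- dp$imax[i] * stats::plogis((grid$age - dp$a50[i]) / dp$w[i])
  inc[grid$age < dp$onset_age[i]] <- 0
  inc <- inc * ifelse(grid$sex == "female", dp$female_mult[i],
                      2 - dp$female_mult[i])
  restricted <- !is.na(dp$sex_restriction[i]) &
    grid$sex != dp$sex_restriction[i]
  inc[restricted] <- 0
  cf <- dp$fmax[i] * stats::plogis((grid$age - 65) / 10)
  cf[inc == 0 & grid$age < dp$onset_age[i]] <- 0
  grid$incidence <- inc
  grid$case_fatality <- cf
  grid$remission <- 0

  rr_bmi <- data.frame(
    disease_id = dp$disease_id, risk_factor = "bmi",
    form = "loglinear_per_unit", category = NA_character_,
    rr = dp$rr_bmi, log_se = dp$rr_bmi_log_se, tmrel = dp$tmrel,
    stringsAsFactors = FALSE
  )
  pa_rr <- config$diseases$pa_rr
  bands <- config$population$pa_bands
  rr_pa <- do.call(rbind, lapply(names(pa_rr), function(d) {
    data.frame(disease_id = d, risk_factor = "pa", form = "categorical",
               category = bands, rr = pa_rr[[d]],
               log_se = config$diseases$pa_rr_log_se, tmrel = NA_real_,
               stringsAsFactors = FALSE)
  }))
  rr <- rbind(rr_bmi, rr_pa)
  rownames(rr) <- NULL
  list(diseases = diseases, disease_rates = grid, rr = rr)
}

# The 16 bundled intervention templates: 9 regulatory / 7 program, four
# child-targeted, two sedentary-behaviour types among the four
# activity-modelled interventions. Effect sizes are in the unit of
# effect_type (kJ/day, MET-min/week, BMI units, BMI z units); negative kJ
# and BMI effects and positive MET effects are beneficial.
default_intervention_templates <- function() {
  iv <- function(name, classification, lo, hi, type, eff, se, uptake,
                 impl, maint, end = NA_real_) {
    data.frame(name = name, classification = classification,
               target_age_lo = lo, target_age_hi = hi, target_sexes = "both",
               effect_type = type, effect_size = eff, effect_se = se,
               uptake = uptake, implementation_years = impl,
               maintenance = maint, maintenance_end_year = end,
               stringsAsFactors = FALSE)
  }
  specs <- rbind(
    iv("alcohol_volumetric_tax", "regulatory", 14, 100, "kj_per_day",
       -40, 6, 1, 1, "sustained"),
    iv("community_programs", "program", 5, 17, "bmi_z_delta",
       -0.15, 0.04, 0.5, 3, "sustained"),
    iv("weight_loss_incentives", "program", 18, 100, "bmi_delta",
       -1.0, 0.2, 0.25, 5, "linear_decay", 11),
    iv("fuel_excise_increase", "regulatory", 18, 64, "met_min_per_week",
       8, 2, 1, 1, "sustained"),
    iv("menu_kj_labelling", "regulatory", 2, 100, "kj_per_day",
       -10, 2, 1, 1, "sustained"),
    iv("ssb_mass_media_campaign", "program", 18, 100, "kj_per_day",
       -12, 2.5, 1, 3, "step_to_zero", 3),
    iv("ssb_package_size_cap", "regulatory", 2, 100, "kj_per_day",
       -15, 3, 1, 1, "sustained"),
    iv("hsr_reformulation", "regulatory", 2, 100, "kj_per_day",
       -4, 1, 1, 1, "sustained"),
    iv("ssb_sugar_reduction", "regulatory", 2, 100, "kj_per_day",
       -8, 1.5, 1, 1, "sustained"),
    iv("tv_ad_restrictions", "regulatory", 5, 15, "kj_per_day",
       -25, 5, 1, 1, "sustained"),
    iv("ssb_price_promo_restrictions", "regulatory", 2, 100, "kj_per_day",
       -6, 1.2, 1, 1, "sustained"),
    iv("school_sedentary_program", "program", 8, 9, "met_min_per_week",
       140, 30, 0.8, 3, "sustained"),
    iv("school_activity_program", "program", 8, 9, "met_min_per_week",
       160, 35, 0.8, 3, "sustained"),
    iv("ssb_tax", "regulatory", 2, 100, "kj_per_day", -20, 4, 1, 1,
       "sustained"),
    iv("supermarket_shelf_tags", "program", 2, 100, "kj_per_day",
       -5, 1, 0.6, 3, "step_to_zero", 3),
    iv("workplace_sedentary_program", "program", 18, 65, "met_min_per_week",
       250, 40, 0.15, 1, "linear_decay", 5)
  )
  rownames(specs) <- NULL

  cc <- function(intervention, label, sector, amount, first, last,
                 health_related = FALSE, time_cost = FALSE, price_year = 2010) {
    data.frame(intervention = intervention, label = label, sector = sector,
               amount = amount, year_first = first, year_last = last,
               health_related = health_related, time_cost = time_cost,
               price_year = price_year, stringsAsFactors = FALSE)
  }
  costs <- rbind(
    cc("alcohol_volumetric_tax", "legislation", "federal_govt", 8e6, 0, 0),
    cc("alcohol_volumetric_tax", "administration", "federal_govt", 8e5, 0, 98),
    cc("community_programs", "program_delivery", "local_govt", 2.6e8, 0, 2,
       health_related = TRUE),
    cc("community_programs", "coordination", "state_govt", 3e7, 0, 2,
       health_related = TRUE),
    cc("weight_loss_incentives", "incentive_payments", "industry", 2.8e8, 0, 4),
    cc("weight_loss_incentives", "program_fees", "individual", 2.4e8, 0, 0),
    cc("fuel_excise_increase", "legislation", "federal_govt", 4e6, 0, 0),
    cc("fuel_excise_increase", "administration", "federal_govt", 4e4, 1, 98),
    cc("menu_kj_labelling", "legislation", "federal_govt", 8e6, 0, 0),
    cc("menu_kj_labelling", "menu_changes", "industry", 2e7, 0, 1),
    cc("menu_kj_labelling", "education_campaign", "state_govt", 3e6, 0, 2,
       health_related = TRUE),
    cc("menu_kj_labelling", "compliance", "state_govt", 2e6, 1, 98),
    cc("ssb_mass_media_campaign", "media_buy", "federal_govt", 9e6, 0, 2,
       health_related = TRUE),
    cc("ssb_mass_media_campaign", "campaign_development", "federal_govt",
       1.3e6, 0, 2, health_related = TRUE),
    cc("ssb_package_size_cap", "legislation", "federal_govt", 8e6, 0, 0),
    cc("ssb_package_size_cap", "production_changes", "industry", 4.3e7, 0, 2),
    cc("ssb_package_size_cap", "compliance", "federal_govt", 1.5e6, 1, 98),
    cc("hsr_reformulation", "scheme_administration", "federal_govt", 3e6,
       0, 98),
    cc("hsr_reformulation", "reformulation", "industry", 9e6, 0, 2),
    cc("ssb_sugar_reduction", "target_setting", "federal_govt", 2e6, 0, 2),
    cc("ssb_sugar_reduction", "reformulation", "industry", 8e6, 0, 2),
    cc("ssb_sugar_reduction", "monitoring", "federal_govt", 5e5, 3, 98),
    cc("tv_ad_restrictions", "legislation", "federal_govt", 1.2e6, 0, 0),
    cc("tv_ad_restrictions", "compliance_monitoring", "federal_govt",
       3e5, 0, 98),
    cc("ssb_price_promo_restrictions", "legislation", "federal_govt",
       1.5e6, 0, 0),
    cc("ssb_price_promo_restrictions", "retail_systems", "industry",
       1.1e6, 0, 2),
    cc("ssb_price_promo_restrictions", "compliance", "state_govt", 4e5, 1, 98),
    cc("school_sedentary_program", "teacher_training", "state_govt",
       3.5e6, 0, 2, health_related = TRUE),
    cc("school_sedentary_program", "equipment", "state_govt", 1.2e6, 0, 2),
    cc("school_activity_program", "teacher_training", "state_govt",
       2.4e6, 0, 2, health_related = TRUE),
    cc("school_activity_program", "equipment", "state_govt", 9e5, 0, 2),
    cc("ssb_tax", "legislation", "federal_govt", 8e6, 0, 0),
    cc("ssb_tax", "tax_administration", "federal_govt", 1.3e6, 0, 98),
    cc("supermarket_shelf_tags", "tag_installation", "industry", 1.9e6, 0, 2),
    cc("supermarket_shelf_tags", "program_support", "state_govt", 1.1e6, 0, 2,
       health_related = TRUE),
    cc("workplace_sedentary_program", "standing_desks", "industry", 7.5e7,
       0, 0),
    cc("workplace_sedentary_program", "health_coaching", "industry", 1e7,
       0, 0, health_related = TRUE),
    cc("workplace_sedentary_program", "employee_time", "industry", 2.5e5,
       0, 0, time_cost = TRUE)
  )
  rownames(costs) <- NULL
  list(specs = specs, cost_components = costs)
}

#' Generate intervention specifications
#'
#' Instantiates the intervention templates in `config$interventions`
#' (by default 16 interventions: 9 regulatory, 7 program-based, four
#' child-targeted, four modelled through physical activity of which two are
#' sedentary-behaviour programs) together with their yearly cost
#' components by sector.
#'
#' @inheritParams generate_population
#' @return list with data.frames `interventions` and `cost_components`.
#' @export
#' @examples
#' iv <- generate_interventions(default_config())
#' table(iv$interventions$classification)
generate_interventions <- function(config = default_config(),
                                   seed = config$seed) {
  tmpl <- config$interventions
  specs <- tmpl$specs
  ok_types <- c("kj_per_day", "met_min_per_week", "bmi_delta", "bmi_z_delta")
  bad <- setdiff(unique(specs$effect_type), ok_types)
  if (length(bad))
    stop("unknown effect_type: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(specs$uptake < 0 | specs$uptake > 1))
    stop_field("interventions$specs$uptake", "must lie in [0, 1]")
  if (any(specs$implementation_years < 1))
    stop_field("interventions$specs$implementation_years", "must be >= 1")
  dec <- specs$maintenance == "linear_decay"
  if (any(dec & (is.na(specs$maintenance_end_year) |
                 specs$maintenance_end_year < specs$implementation_years)))
    stop_field("interventions$specs$maintenance_end_year",
               "linear_decay end year must be >= implementation_years")
  zz <- specs$effect_type == "bmi_z_delta"
  if (any(zz & specs$target_age_hi > 17))
    stop("bmi_z_delta effects require a child target (ages <= 17): ",
         paste(specs$name[zz & specs$target_age_hi > 17], collapse = ", "),
         call. = FALSE)
  cc <- tmpl$cost_components
  if (any(cc$amount < 0))
    stop_field("interventions$cost_components$amount", "must be >= 0")
  if (any(cc$year_last < cc$year_first))
    stop_field("interventions$cost_components$year_last",
               "year range must be well ordered")
  list(interventions = specs, cost_components = cc)
}

#' Generate a complete synthetic data bundle
#'
#' Runs all generators and assembles the bundle consumed by the modelling
#' pipeline. The result passes [validate_bundle()].
#'
#' @inheritParams generate_population
#' @return a list of class `pmslt_bundle` with elements `population`,
#'   `diseases`, `disease_rates`, `rr`, `growth_reference`,
#'   `interventions`, `cost_components`, `config`.
#' @export
#' @examples
#' b <- generate_bundle(default_config(), seed = 1)
#' names(b)
generate_bundle <- function(config = default_config(), seed = config$seed) {
  cat9 <- generate_disease_catalogue(config, seed)
  iv <- generate_interventions(config, seed)
  bundle <- structure(list(
    population = generate_population(config, seed),
    diseases = cat9$diseases,
    disease_rates = cat9$disease_rates,
    rr = cat9$rr,
    growth_reference = generate_growth_reference(config, seed),
    interventions = iv$interventions,
    cost_components = iv$cost_components,
    settings = list(
      seed = as.integer(seed),
      energy_balance = config$energy_balance,
      flags = config$flags,
      child_hrql_coeff = config$child_hrql_coeff,
      discount_rate = config$discount_rate,
      wtp = config$wtp,
      pa_bands = config$population$pa_bands,
      pa_met_midpoints = config$population$pa_met_midpoints
    )
  ), class = "pmslt_bundle")
  validate_bundle(bundle)
  bundle
}

#' @export
print.pmslt_bundle <- function(x, ...) {
  cat("<pmslt_bundle>\n")
  cat(sprintf("  %d population strata (ages %d-%d, %s)\n",
              nrow(x$population), min(x$population$age), max(x$population$age),
              paste(unique(x$population$sex), collapse = "/")))
  cat(sprintf("  %d diseases (%d physical-activity-related)\n",
              nrow(x$diseases), sum(x$diseases$pa_related)))
  cat(sprintf("  %d interventions (%d regulatory / %d program)\n",
              nrow(x$interventions),
              sum(x$interventions$classification == "regulatory"),
              sum(x$interventions$classification == "program")))
  invisible(x)
}
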