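#' Default study configuration
#'
#' Returns the configuration list that drives the synthetic-data generator
#' and the model defaults. All values are in the units stated: BMI in
#' kg/m^2 (log-normal `mu`/`sigma` on the log scale), physical activity in
#' MET-minutes/week, rates per person-year, costs in 2010 AUD.
#'
#' Key entries:
#' \describe{
#'   \item{ages, sexes}{the modelled grid: single years of age 2--100, two
#'     sexes, i.e. 198 population strata.}
#'   \item{population}{BMI median/sigma trajectories by age, physical
#'     activity band prevalences, mean heights, a Gompertz all-cause
#'     mortality schedule and an age-linear background morbidity (YLD) rate.}
#'   \item{diseases}{per-disease parameters of the nine-disease catalogue:
#'     sigmoid age curves for incidence and case fatality, disability
#'     weight, annual healthcare cost per prevalent case, BMI relative risk
#'     per kg/m^2 with TMREL, and categorical physical-activity relative
#'     risks for the five activity-related diseases.}
#'   \item{energy_balance}{steady-state energy-balance coefficients:
#'     `rho_adult`/`rho_child` in kJ/day per kg of weight change, the MET
#'     energy coefficient (kcal per kg per MET-minute) and kJ per kcal.}
#'   \item{flags}{`pa_affects_bmi` (physical-activity interventions also
#'     shift BMI through the uncompensated energy deficit) and `net_mets`
#'     (subtract 1 MET of resting expenditure before conversion).}
#'   \item{child_hrql_coeff}{utility decrement per BMI unit above the
#'     age--sex reference for ages 2--17 (default 0.005).}
#'   \item{discount_rate, wtp}{3\% annual discounting; willingness to pay
#'     AUD 50,000 per HALY.}
#' }
#'
#' @param seed integer seed stored in the configuration (also settable per
#'   generator call).
#' @return a named list, class `pmslt_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    ages = 2:100,
    sexes = c("female", "male"),
    population = list(
      total_persons = 22e6,
      bmi = list(
        sigma_adult = 0.16,
        sigma_child = 0.12,
        adult_median_peak = 27.5,
        adult_median_young = 24.0,
        jitter_sd = 0.01
      ),
      pa_bands = c("inactive", "low", "moderate", "high"),
      pa_met_midpoints = c(0, 300, 900, 1800),
      mortality = list(gompertz_a = 2e-5, gompertz_b = 0.095,
                       child_floor = 1.5e-4),
      yld = list(base = 0.02, slope_per_year = 0.0022, onset_age = 20,
                 cap = 0.35),
      height = list(adult_female = 1.62, adult_male = 1.76)
    ),
    diseases = default_disease_params(),
    growth = list(L = -1.5, S_base = 0.09, S_slope = 0.002),
    energy_balance = list(rho_adult = 94, rho_child = 100,
                          met_kcal_coeff = 0.0175, kj_per_kcal = 4.184),
    flags = list(pa_affects_bmi = TRUE, net_mets = FALSE),
    child_hrql_coeff = 0.005,
    discount_rate = 0.03,
    wtp = 50000,
    interventions = default_intervention_templates()
  )
  class(cfg) <- c("pmslt_config", "list")
  cfg
}

# Nine-disease catalogue parameters. Incidence and case fatality follow
# logistic age curves i(a) = imax * plogis((a - a50)/w) above the onset age;
# f(a) = fmax * plogis((a - 65)/10). All diseases are BMI-related; exactly
# five are physical-activity-related. RRs are per BMI unit above TMREL on
# the log-linear path, and per activity band (reference = 'high') on the
# categorical path.
default_disease_params <- function() {
  d <- data.frame(
    disease_id = c("kidney_cancer", "colorectal_cancer", "endometrial_cancer",
                   "breast_cancer", "type2_diabetes",
                   "hypertensive_heart_disease", "ischaemic_heart_disease",
                   "stroke", "osteoarthritis"),
    pa_related = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    sex_restriction = c(NA, NA, "female", "female", NA, NA, NA, NA, NA),
    onset_age = c(30, 30, 35, 30, 20, 40, 30, 35, 30),
    imax = c(4e-4, 1.2e-3, 5e-4, 2e-3, 8e-3, 1.5e-3, 6e-3, 4e-3, 6e-3),
    a50 = c(65, 68, 64, 60, 55, 70, 65, 70, 58),
    w = c(8, 8, 7, 10, 9, 7, 9, 8, 10),
    fmax = c(0.08, 0.07, 0.05, 0.04, 0.006, 0.03, 0.035, 0.05, 0),
    female_mult = c(0.8, 0.9, 1, 1, 0.95, 1.05, 0.7, 0.85, 1.25),
    disability_weight = c(0.29, 0.24, 0.22, 0.21, 0.07, 0.09, 0.12, 0.18, 0.10),
    annual_cost_per_case = c(12000, 15000, 11000, 14000, 4000, 5000, 7000,
                             9000, 3000),
    rr_bmi = c(1.06, 1.03, 1.10, 1.02, 1.10, 1.07, 1.05, 1.04, 1.06),
    rr_bmi_log_se = c(0.03, 0.02, 0.04, 0.015, 0.03, 0.035, 0.02, 0.02, 0.03),
    tmrel = c(22, 22, 22, 22, 21, 22, 22, 22, 23),
    stringsAsFactors = FALSE
  )
  pa_rr <- list(
    colorectal_cancer = c(1.25, 1.15, 1.07, 1),
    breast_cancer = c(1.20, 1.12, 1.05, 1),
    type2_diabetes = c(1.40, 1.25, 1.10, 1),
    ischaemic_heart_disease = c(1.50, 1.30, 1.12, 1),
    stroke = c(1.35, 1.22, 1.10, 1)
  )
  list(params = d, pa_rr = pa_rr, pa_rr_log_se = 0.06)
}

#' Read a study configuration from a YAML file
#'
#' Entries present in the file override the corresponding entries of
#' [default_config()]; everything else keeps its default. The file may be
#' partial -- a file containing only `seed: 7` is valid.
#'
#' @param path path to a YAML file.
#' @return a `pmslt_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- modify_list_deep(default_config(), user)
  class(cfg) <- c("pmslt_config", "list")
  validate_config(cfg)
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Validate a study configuration
#'
#' Checks the ranges the generator relies on; errors name the offending
#' field.
#'
#' @param config a configuration list as from [default_config()].
#' @return the configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  p <- config$population
  if (min(config$ages) < 2 || max(config$ages) > 100)
    stop_field("ages", "must lie within [2, 100]")
  if (!all(config$sexes %in% c("female", "male")))
    stop_field("sexes", "must be a subset of {female, male}")
  if (p$bmi$sigma_adult <= 0 || p$bmi$sigma_child <= 0)
    stop_field("population$bmi$sigma", "bmi_sigma must be > 0")
  if (p$total_persons <= 0)
    stop_field("population$total_persons", "must be positive")
  if (length(p$pa_bands) != length(p$pa_met_midpoints))
    stop_field("population$pa_met_midpoints",
               "must have one midpoint per activity band")
  eb <- config$energy_balance
  if (any(unlist(eb) <= 0))
    stop_field("energy_balance", "all coefficients must be > 0")
  if (config$discount_rate < 0)
    stop_field("discount_rate", "must be >= 0")
  if (config$wtp <= 0) stop_field("wtp", "must be > 0")
  tm <- config$diseases$params$tmrel
  if (any(tm < 18 | tm > 25))
    stop_field("diseases$params$tmrel", "must lie in [18, 25]")
  invisible(config)
}
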