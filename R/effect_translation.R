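# Conversion of intervention effect sizes (kJ/day, MET-min/week, BMI
# z-scores) into per-stratum BMI and activity-band changes. All
# conversions are pure functions, linear in the effect size except the LMS
# path which is monotone in the z change.

#' Energy-balance conversion parameters
#'
#' Steady-state energy-balance coefficients. `rho_adult` and `rho_child`
#' are kJ/day of sustained intake change per kg of steady-state weight
#' change (defaults 94 and 100); `met_kcal_coeff` is kcal expended per kg
#' body mass per MET-minute (default 0.0175); `kj_per_kcal` is 4.184.
#' The linear steady-state coefficient is a configurable stand-in for a
#' full dynamic energy-balance model.
#'
#' @param rho_adult,rho_child kJ/day per kg, > 0.
#' @param met_kcal_coeff kcal per kg per MET-minute, > 0.
#' @param kj_per_kcal kJ per kcal.
#' @return a named list.
#' @export
energy_balance_params <- function(rho_adult = 94, rho_child = 100,
                                  met_kcal_coeff = 0.0175,
                                  kj_per_kcal = 4.184) {
  p <- list(rho_adult = rho_adult, rho_child = rho_child,
            met_kcal_coeff = met_kcal_coeff, kj_per_kcal = kj_per_kcal)
  if (any(unlist(p) <= 0))
    stop("all energy-balance parameters must be > 0", call. = FALSE)
  p
}

#' Convert a sustained kJ/day intake change to a weight change
#'
#' @param delta_kj_per_day signed change in daily energy intake (kJ/day);
#'   negative = reduced intake.
#' @param age_group `"adult"` (18+) or `"child"`.
#' @param params see [energy_balance_params()].
#' @return steady-state weight change in kg, sign preserved.
#' @export
#' @examples
#' kj_to_weight(-94, "adult")   # -1 kg
kj_to_weight <- function(delta_kj_per_day, age_group = c("adult", "child"),
                         params = energy_balance_params()) {
  age_group <- match.arg(age_group)
  rho <- if (age_group == "adult") params$rho_adult else params$rho_child
  delta_kj_per_day / rho
}

#' Convert a weight change to a BMI change
#'
#' @param delta_kg signed weight change in kg.
#' @param mean_height_m mean height of the stratum in metres (> 0).
#' @return BMI change in kg/m^2.
#' @export
weight_to_bmi_delta <- function(delta_kg, mean_height_m) {
  if (any(mean_height_m <= 0))
    stop("mean_height_m must be > 0", call. = FALSE)
  delta_kg / mean_height_m^2
}

# LMS transform: BMI at z-score z given L, M, S.
lms_bmi <- function(z, L, M, S) {
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Convert a BMI z-score change to a BMI change via an LMS growth reference
#'
#' Uses the LMS transform BMI(z) = M (1 + L S z)^(1/L) (or M exp(S z) when
#' L = 0) at the child's age and sex.
#'
#' @param z0 starting z-score.
#' @param delta_z signed change in z-score.
#' @param age age in years, 2--17.
#' @param sex `"female"` or `"male"`.
#' @param growth_ref growth-reference data.frame (`age`, `sex`, `L`, `M`,
#'   `S`), see [generate_growth_reference()].
#' @return BMI change in kg/m^2.
#' @export
zscore_delta_to_bmi_delta <- function(z0, delta_z, age, sex, growth_ref) {
  if (any(age < 2 | age > 17))
    stop("z-score conversion applies to ages 2-17 only", call. = FALSE)
  if (any(abs(z0) > 4) || any(abs(z0 + delta_z) > 4))
    stop("z-scores must stay within [-4, 4]", call. = FALSE)
  i <- match(paste(age, sex), paste(growth_ref$age, growth_ref$sex))
  if (anyNA(i))
    stop("growth reference has no row for the requested age/sex",
         call. = FALSE)
  L <- growth_ref$L[i]; M <- growth_ref$M[i]; S <- growth_ref$S[i]
  lms_bmi(z0 + delta_z, L, M, S) - lms_bmi(z0, L, M, S)
}

#' Convert a MET-minutes/week change to daily energy expenditure
#'
#' Positive MET-minute increases yield positive additional expenditure in
#' kJ/day. Downstream, an expenditure increase is treated as an
#' uncompensated energy deficit, i.e. the caller flips the sign before
#' feeding it into the intake-to-weight conversion. With `net_mets = TRUE`
#' the resting component is removed assuming activity at `met_intensity`
#' METs (factor (met_intensity - 1)/met_intensity).
#'
#' @param delta_met_min_per_week signed change in MET-minutes/week.
#' @param body_mass_kg mean body mass of the stratum, > 0.
#' @param params see [energy_balance_params()].
#' @param net_mets subtract resting expenditure? Default FALSE (gross).
#' @param met_intensity assumed intensity of the added activity, METs.
#' @return change in energy expenditure, kJ/day.
#' @export
#' @examples
#' met_to_kj_per_day(600, 70)  # 439.32 kJ/day
met_to_kj_per_day <- function(delta_met_min_per_week, body_mass_kg,
                              params = energy_balance_params(),
                              net_mets = FALSE, met_intensity = 4) {
  if (any(body_mass_kg <= 0)) stop("body_mass_kg must be > 0", call. = FALSE)
  out <- delta_met_min_per_week * body_mass_kg * params$met_kcal_coeff *
    params$kj_per_kcal / 7
  if (net_mets) out <- out * (met_intensity - 1) / met_intensity
  out
}

#' Maintenance-of-effect scaling at a given year
#'
#' Fraction of the full intervention effect present in model year `year`
#' (year 0 = first year). `sustained` effects persist for the lifetime of
#' the modelled population; `step_to_zero` effects end abruptly at the
#' stated year; `linear_decay` effects hold at 1 through the
#' implementation years then decay linearly to 0 at the end year.
#'
#' @param spec one intervention specification (a one-row data.frame or a
#'   list with `maintenance`, `implementation_years`,
#'   `maintenance_end_year`).
#' @param year integer year(s) since intervention start, >= 0.
#' @return effect scale in `[0, 1]`, vectorised over `year`.
#' @export
effect_at_time <- function(spec, year) {
  if (any(year < 0)) stop("year must be >= 0", call. = FALSE)
  m <- spec$maintenance
  if (m == "sustained") return(rep(1, length(year)))
  E <- spec$maintenance_end_year
  if (m == "step_to_zero") return(as.numeric(year < E))
  if (m == "linear_decay") {
    impl <- spec$implementation_years
    s <- ifelse(year < impl, 1, pmax(0, (E - year) / (E - impl)))
    return(pmin(1, s))
  }
  stop("unknown maintenance profile: ", m, call. = FALSE)
}

# Row-stochastic transition matrix moving `frac` of each band's mass one
# band upward (toward higher activity); the top band is absorbing.
pa_transition_matrix <- function(frac, n_bands) {
  Tm <- diag(1 - frac, n_bands)
  for (k in seq_len(n_bands - 1)) Tm[k, k + 1] <- frac
  Tm[n_bands, n_bands] <- 1
  Tm
}

# Apply the one-band-up shift to a prevalence vector.
shift_pa_prevalence <- function(p0, frac) {
  n <- length(p0)
  moved <- p0 * frac
  p1 <- p0 - moved
  p1[2:n] <- p1[2:n] + moved[1:(n - 1)]
  p1[n] <- p1[n] + moved[n]  # top band keeps its mass
  p1
}

#' Build per-stratum, per-year risk-factor deltas for an intervention
#'
#' Routes the intervention's effect size through the conversion chain for
#' its effect type, applies uptake and the maintenance profile, and zeroes
#' strata outside the target age/sex range (targeting is by age at model
#' start; cohorts keep their delta as they age while the effect lasts).
#' Physical-activity effects also produce a BMI shift through the
#' uncompensated energy deficit unless `pa_affects_bmi` is `FALSE`; the
#' activity-band shift moves `uptake x scale x min(1, effect/600)` of each
#' band's mass one band upward.
#'
#' @param spec one intervention specification row.
#' @param population population strata table.
#' @param growth_ref growth reference (needed for `bmi_z_delta` effects).
#' @param params energy-balance parameters.
#' @param pa_affects_bmi do MET effects shift BMI? Default TRUE.
#' @param net_mets see [met_to_kj_per_day()].
#' @param n_years number of model years (default: to age 100 of the
#'   youngest stratum).
#' @return a list of class `risk_factor_delta`: `bmi_shift` and `pa_frac`
#'   matrices (strata x years), `years`, `target` logical vector.
#' @export
build_risk_deltas <- function(spec, population, growth_ref = NULL,
                              params = energy_balance_params(),
                              pa_affects_bmi = TRUE, net_mets = FALSE,
                              n_years = 101 - min(population$age)) {
  n <- nrow(population)
  years <- 0:(n_years - 1)
  target <- population$age >= spec$target_age_lo &
    population$age <= spec$target_age_hi &
    (spec$target_sexes == "both" | population$sex == spec$target_sexes)

  base_bmi <- numeric(n)
  pa_step <- 0
  h <- population$mean_height
  child <- population$age < 18
  if (spec$effect_type == "kj_per_day") {
    kg <- ifelse(child,
                 kj_to_weight(spec$effect_size, "child", params),
                 kj_to_weight(spec$effect_size, "adult", params))
    base_bmi <- weight_to_bmi_delta(kg, h)
  } else if (spec$effect_type == "bmi_delta") {
    base_bmi <- rep(spec$effect_size, n)
  } else if (spec$effect_type == "bmi_z_delta") {
    if (spec$target_age_hi > 17)
      stop("bmi_z_delta effects cannot target adults (ages > 17)",
           call. = FALSE)
    if (is.null(growth_ref))
      stop("bmi_z_delta effects require a growth reference", call. = FALSE)
    idx <- which(target)
    base_bmi[idx] <- zscore_delta_to_bmi_delta(
      0, spec$effect_size, population$age[idx], population$sex[idx],
      growth_ref)
  } else if (spec$effect_type == "met_min_per_week") {
    mean_bmi <- exp(population$bmi_mu + population$bmi_sigma^2 / 2)
    mass <- mean_bmi * h^2
    kj_out <- met_to_kj_per_day(spec$effect_size, mass, params,
                                net_mets = net_mets)
    if (pa_affects_bmi) {
      kg <- ifelse(child,
                   kj_to_weight(-kj_out, "child", params),
                   kj_to_weight(-kj_out, "adult", params))
      base_bmi <- weight_to_bmi_delta(kg, h)
    }
    pa_step <- min(1, abs(spec$effect_size) / 600) * sign(spec$effect_size)
  } else {
    stop("unknown effect_type: ", spec$effect_type, call. = FALSE)
  }

  base_bmi[!target] <- 0
  scale <- effect_at_time(spec, years)
  base_eff <- base_bmi * spec$uptake
  bmi_shift <- outer(base_eff, scale)
  pa_frac <- outer(as.numeric(target) * spec$uptake * max(0, pa_step), scale)
  dimnames(bmi_shift) <- dimnames(pa_frac) <-
    list(NULL, paste0("y", years))
  structure(list(bmi_shift = bmi_shift, pa_frac = pa_frac, years = years,
                 target = target, effect_type = spec$effect_type,
                 base_eff = base_eff, scale_by_year = scale),
            class = "risk_factor_delta")
}
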