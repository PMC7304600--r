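# Bundle container: a list of data.frames (population, diseases,
# disease_rates, rr, growth_reference, interventions, cost_components)
# plus a flat `settings` list of runtime constants. Bundles are saved as a
# directory of UTF-8 CSV files with a header row and '.' decimal separator,
# plus settings.yml.

bundle_files <- list(
  population = "population.csv",
  diseases = "diseases.csv",
  disease_rates = "disease_rates.csv",
  rr = "rr.csv",
  growth_reference = "growth_reference.csv",
  interventions = "interventions.csv",
  cost_components = "cost_components.csv"
)

bundle_col_classes <- list(
  population = c(age = "integer", sex = "character", count = "numeric",
                 bmi_mu = "numeric", bmi_sigma = "numeric",
                 mean_height = "numeric", mortality_all_cause = "numeric",
                 yld_all_cause = "numeric"),
  diseases = c(disease_id = "character", pa_related = "logical",
               sex_restriction = "character", onset_age = "numeric",
               disability_weight = "numeric", annual_cost_per_case = "numeric",
               bmi_related = "logical"),
  disease_rates = c(disease_id = "character", age = "integer",
                    sex = "character", incidence = "numeric",
                    case_fatality = "numeric", remission = "numeric"),
  rr = c(disease_id = "character", risk_factor = "character",
         form = "character", category = "character", rr = "numeric",
         log_se = "numeric", tmrel = "numeric"),
  growth_reference = c(age = "integer", sex = "character", L = "numeric",
                       M = "numeric", S = "numeric"),
  interventions = c(name = "character", classification = "character",
                    target_age_lo = "numeric", target_age_hi = "numeric",
                    target_sexes = "character", effect_type = "character",
                    effect_size = "numeric", effect_se = "numeric",
                    uptake = "numeric", implementation_years = "numeric",
                    maintenance = "character",
                    maintenance_end_year = "numeric"),
  cost_components = c(intervention = "character", label = "character",
                      sector = "character", amount = "numeric",
                      year_first = "numeric", year_last = "numeric",
                      health_related = "logical", time_cost = "logical",
                      price_year = "numeric")
)

#' Validate a data bundle
#'
#' Asserts the structural invariants the modelling pipeline relies on:
#' activity-band prevalences summing to one, positive BMI sigma, rates and
#' disability weights in range, categorical RR vectors matching the band
#' count, a monotone growth reference, intervention fields in range, and
#' the epidemiological consistency conditions (steady-state disease
#' prevalence finite and below 0.5 at every age; all-cause mortality at
#' least the disease-specific mortality implied by the catalogue).
#'
#' @param bundle a `pmslt_bundle` list.
#' @return the bundle, invisibly, if valid; otherwise an error naming the
#'   violated condition.
#' @export
validate_bundle <- function(bundle) {
  need <- names(bundle_files)
  miss <- setdiff(need, names(bundle))
  if (length(miss))
    stop("bundle is missing element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pop <- bundle$population
  pa_cols <- grep("^pa_", names(pop), value = TRUE)
  if (length(pa_cols) < 2)
    stop("population must carry at least two pa_* prevalence columns",
         call. = FALSE)
  pa_sum <- rowSums(pop[pa_cols])
  if (any(abs(pa_sum - 1) > 1e-9))
    stop("population pa_* prevalences must sum to 1 (max deviation ",
         format(max(abs(pa_sum - 1))), ")", call. = FALSE)
  if (any(pop$bmi_sigma <= 0)) stop("bmi_sigma must be > 0", call. = FALSE)
  if (any(pop$count < 0)) stop("population counts must be >= 0", call. = FALSE)
  if (any(pop$yld_all_cause < 0 | pop$yld_all_cause >= 1))
    stop("yld_all_cause must lie in [0, 1)", call. = FALSE)
  if (any(pop$mean_height <= 0)) stop("mean_height must be > 0", call. = FALSE)

  dis <- bundle$diseases
  if (any(dis$disability_weight < 0 | dis$disability_weight > 1))
    stop("disability_weight must lie in [0, 1]", call. = FALSE)
  if (any(dis$annual_cost_per_case < 0))
    stop("annual_cost_per_case must be >= 0", call. = FALSE)
  if (nrow(dis) == 9 && sum(dis$pa_related) != 5)
    stop("the nine-disease catalogue must flag exactly five diseases as ",
         "physical-activity-related", call. = FALSE)
  dr <- bundle$disease_rates
  if (any(dr$incidence < 0 | dr$case_fatality < 0 | dr$remission < 0))
    stop("disease rates must be >= 0", call. = FALSE)

  rr <- bundle$rr
  if (any(rr$rr <= 0)) stop("relative risks must be > 0", call. = FALSE)
  bmi_rows <- rr$risk_factor == "bmi"
  if (any(rr$tmrel[bmi_rows] < 18 | rr$tmrel[bmi_rows] > 25))
    stop("tmrel must lie in [18, 25]", call. = FALSE)
  n_bands <- length(pa_cols)
  cat_counts <- table(rr$disease_id[rr$form == "categorical"])
  if (length(cat_counts) && any(cat_counts != n_bands))
    stop("categorical RR vectors must have one entry per activity band",
         call. = FALSE)

  gr <- bundle$growth_reference
  if (any(gr$M <= 0) || any(gr$S <= 0))
    stop("growth reference requires M > 0 and S > 0", call. = FALSE)
  # monotone BMI in z over [-4, 4] requires 1 + L*S*z > 0 at the extremes
  if (any(1 + gr$L * gr$S * 4 <= 0) || any(1 + gr$L * gr$S * -4 <= 0))
    stop("growth reference not monotone over z in [-4, 4]", call. = FALSE)

  iv <- bundle$interventions
  if (nrow(iv)) {
    if (any(iv$uptake < 0 | iv$uptake > 1))
      stop("intervention uptake must lie in [0, 1]", call. = FALSE)
    if (any(iv$implementation_years < 1))
      stop("implementation_years must be >= 1", call. = FALSE)
  }
  cc <- bundle$cost_components
  if (nrow(cc) && any(cc$amount < 0))
    stop("cost component amounts must be >= 0", call. = FALSE)

  ss <- steady_state_prevalence(bundle)
  if (any(!is.finite(ss$prevalence)) || any(ss$prevalence >= 0.5))
    stop("steady-state disease prevalence must be finite and < 0.5",
         call. = FALSE)
  implied <- implied_disease_mortality(bundle, ss)
  key <- paste(pop$age, pop$sex)
  tot <- implied$total[match(key, paste(implied$age, implied$sex))]
  if (any(pop$mortality_all_cause + 1e-12 < tot))
    stop("all-cause mortality must be >= implied disease-specific mortality",
         call. = FALSE)
  invisible(bundle)
}

#' Save a bundle as a directory of CSV files
#'
#' Writes one CSV per bundle table (see the bundle element names) plus
#' `settings.yml`. Numeric columns are written with 17 significant digits
#' so that [load_bundle()] round-trips all values exactly.
#'
#' @param bundle a `pmslt_bundle`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (el in names(bundle_files)) {
    df <- bundle[[el]]
    out <- df
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        v <- sprintf("%.17g", out[[j]])
        v[is.na(out[[j]])] <- NA
        out[[j]] <- v
      }
    }
    utils::write.csv(out, file.path(path, bundle_files[[el]]),
                     row.names = FALSE, quote = TRUE, na = "")
  }
  yaml::write_yaml(bundle$settings, file.path(path, "settings.yml"),
                   precision = 15)
  invisible(path)
}

#' Load a bundle saved by [save_bundle()]
#'
#' Columns are matched by name, so column order in the files is free.
#' Missing files or columns produce an error naming the file and column.
#'
#' @param path bundle directory.
#' @return a `pmslt_bundle`.
#' @export
load_bundle <- function(path) {
  if (!dir.exists(path)) stop("bundle directory not found: ", path,
                              call. = FALSE)
  bundle <- list()
  sf <- file.path(path, "settings.yml")
  settings <- if (file.exists(sf)) yaml::read_yaml(sf)
  for (el in names(bundle_files)) {
    f <- file.path(path, bundle_files[[el]])
    if (!file.exists(f))
      stop("bundle file missing: ", bundle_files[[el]], call. = FALSE)
    raw <- utils::read.csv(f, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    cls <- bundle_col_classes[[el]]
    if (el == "population") {
      pa_cols <- grep("^pa_", names(raw), value = TRUE)
      # canonical band order from the settings, placed after bmi_sigma
      if (!is.null(settings$pa_bands))
        pa_cols <- intersect(paste0("pa_", settings$pa_bands), pa_cols)
      cls <- append(cls,
                    stats::setNames(rep("numeric", length(pa_cols)),
                                    pa_cols),
                    after = match("bmi_sigma", names(cls)))
    }
    miss <- setdiff(names(cls), names(raw))
    if (length(miss))
      stop(sprintf("bundle file %s is missing column(s): %s",
                   bundle_files[[el]], paste(miss, collapse = ", ")),
           call. = FALSE)
    df <- raw[names(cls)]
    for (nm in names(cls)) {
      df[[nm]] <- switch(cls[[nm]],
        integer = as.integer(df[[nm]]),
        numeric = { x <- df[[nm]]; x[x == ""] <- NA; as.numeric(x) },
        logical = as.logical(df[[nm]]),
        character = { x <- df[[nm]]; x[x == ""] <- NA; x })
    }
    bundle[[el]] <- df
  }
  bundle$settings <- settings
  structure(bundle, class = "pmslt_bundle")
}
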