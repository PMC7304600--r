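# Intervention costing, ICER computation, dominance classification,
# league tables and portfolio summaries. All money is 2010 AUD.

#' Costing rules
#'
#' Wage on-costs (13\% public sector, 14\% private sector), 17.5\% leave
#' loading, a gender-free wage rate for time costs, and per-year price
#' index series (health price index for health-related components, GDP
#' index otherwise) used to express costs in reference-year values.
#' Index series are named vectors keyed by year; with `NULL` indices all
#' components are assumed to be stated in reference-year dollars already.
#'
#' @param oncost_public,oncost_private salary on-cost rates.
#' @param leave_loading leave loading rate.
#' @param wage_rate AUD per hour, gender-free.
#' @param health_price_index,gdp_index named numeric vectors
#'   (names = years), normalised so the reference year equals 1.
#' @param reference_year currency year, default 2010.
#' @return list of class `costing_rules`.
#' @export
costing_rules <- function(oncost_public = 0.13, oncost_private = 0.14,
                          leave_loading = 0.175, wage_rate = 40,
                          health_price_index = NULL, gdp_index = NULL,
                          reference_year = 2010) {
  stopifnot(oncost_public >= 0, oncost_private >= 0, leave_loading >= 0,
            wage_rate >= 0)
  if (!is.null(health_price_index) && any(health_price_index <= 0))
    stop("price indices must be positive", call. = FALSE)
  if (!is.null(gdp_index) && any(gdp_index <= 0))
    stop("price indices must be positive", call. = FALSE)
  structure(list(oncost_public = oncost_public,
                 oncost_private = oncost_private,
                 leave_loading = leave_loading, wage_rate = wage_rate,
                 health_price_index = health_price_index,
                 gdp_index = gdp_index, reference_year = reference_year),
            class = "costing_rules")
}

public_sectors <- c("federal_govt", "state_govt", "local_govt")

index_to_reference <- function(amount, price_year, index, reference_year) {
  if (is.null(index) || all(price_year == reference_year)) return(amount)
  yrs <- as.character(price_year)
  if (any(!yrs %in% names(index)))
    stop("price index has no entry for year(s): ",
         paste(setdiff(yrs, names(index)), collapse = ", "), call. = FALSE)
  ref <- index[[as.character(reference_year)]]
  if (is.null(ref))
    stop("price index has no entry for the reference year", call. = FALSE)
  amount * ref / index[yrs]
}

#' Cost an intervention
#'
#' Values each cost component per year: time-cost components (amounts in
#' person-hours/year) at the wage rate grossed up by the sector's salary
#' on-cost and the leave loading; monetary components indexed to
#' reference-year values by the health price index (health-related) or
#' the GDP index (otherwise). Returns the yearly stream, the total
#' discounted cost and the undiscounted first-three-year cost.
#'
#' @param components cost-component rows for one intervention (columns
#'   `sector`, `amount`, `year_first`, `year_last`, `health_related`,
#'   `time_cost`, optionally `price_year`).
#' @param rules a [costing_rules()] object.
#' @param discount_rate annual discount rate (default 0.03).
#' @return list: `by_year` (year, cost), `total_discounted`,
#'   `first3y_undiscounted`.
#' @export
#' @examples
#' comp <- data.frame(sector = "federal_govt", amount = 100,
#'                    year_first = 0, year_last = 0,
#'                    health_related = FALSE, time_cost = FALSE)
#' cost_intervention(comp, costing_rules())$total_discounted
cost_intervention <- function(components, rules = costing_rules(),
                              discount_rate = 0.03) {
  if (is.null(components) || nrow(components) == 0)
    return(list(by_year = data.frame(year = integer(), cost = numeric()),
                total_discounted = 0, first3y_undiscounted = 0))
  if (any(components$year_last < components$year_first))
    stop("cost component year ranges must be well ordered", call. = FALSE)
  py <- if ("price_year" %in% names(components)) components$price_year
        else rules$reference_year
  max_year <- max(components$year_last)
  yearly <- numeric(max_year + 1)
  for (k in seq_len(nrow(components))) {
    a <- components$amount[k]
    if (isTRUE(components$time_cost[k])) {
      oncost <- if (components$sector[k] %in% public_sectors)
        rules$oncost_public else rules$oncost_private
      a <- a * rules$wage_rate * (1 + oncost) * (1 + rules$leave_loading)
    } else {
      idx <- if (isTRUE(components$health_related[k]))
        rules$health_price_index else rules$gdp_index
      a <- index_to_reference(a, py[k], idx, rules$reference_year)
    }
    yrs <- components$year_first[k]:components$year_last[k]
    yearly[yrs + 1] <- yearly[yrs + 1] + a
  }
  years <- 0:max_year
  disc <- (1 + discount_rate)^(-years)
  list(by_year = data.frame(year = years, cost = yearly),
       total_discounted = sum(yearly * disc),
       first3y_undiscounted = sum(yearly[years <= 2]))
}

#' ICER and dominance classification
#'
#' Net cost divided by HALYs gained, classified against the
#' willingness-to-pay threshold. Sign conventions: health gains with net
#' savings are `dominant` (no interpretable ICER); health gains with
#' non-negative net cost give an ICER classified `cost_effective` below
#' `wtp`, else `not_cost_effective`; health losses with net cost are
#' `dominated`; health losses with net savings report the saving per HALY
#' lost and are flagged `not_cost_effective` for review. Zero health
#' effect: positive net cost is `not_cost_effective` (infinite ICER), net
#' savings are `cost_saving_health_neutral`.
#'
#' @param net_cost total intervention cost minus healthcare cost offsets.
#' @param halys_gained incremental HALYs.
#' @param wtp willingness-to-pay per HALY, default 50000.
#' @return list `icer` (NA where not interpretable) and
#'   `dominance_class`.
#' @export
#' @examples
#' compute_icer(1e6, 100)          # 10,000 per HALY, cost_effective
#' compute_icer(-502e6, 63492)     # dominant
compute_icer <- function(net_cost, halys_gained, wtp = 50000) {
  if (halys_gained > 0) {
    if (net_cost < 0)
      return(list(icer = NA_real_, dominance_class = "dominant"))
    icer <- net_cost / halys_gained
    cls <- if (icer < wtp) "cost_effective" else "not_cost_effective"
    return(list(icer = icer, dominance_class = cls))
  }
  if (halys_gained < 0) {
    if (net_cost > 0)
      return(list(icer = NA_real_, dominance_class = "dominated"))
    return(list(icer = net_cost / halys_gained,
                dominance_class = "not_cost_effective"))
  }
  if (net_cost > 0)
    return(list(icer = Inf, dominance_class = "not_cost_effective"))
  list(icer = NA_real_, dominance_class = "cost_saving_health_neutral")
}

#' Build a cost-effectiveness league table
#'
#' Dominant interventions (cost-saving and health-gaining) have no
#' interpretable ICER and rank first, ordered by total HALYs gained
#' descending; the remaining interventions follow, ordered by ICER
#' ascending. Residual ties break lexicographically by name.
#'
#' @param results data.frame with at least `name`, `halys_gained`,
#'   `icer`, `dominance_class`.
#' @return the same rows with a `rank` column, reordered.
#' @export
build_league_table <- function(results) {
  stopifnot(nrow(results) >= 1)
  dom <- results$dominance_class == "dominant"
  ord_dom <- order(-results$halys_gained[dom], results$name[dom])
  icer_nd <- results$icer[!dom]
  icer_nd[is.na(icer_nd)] <- Inf
  ord_nd <- order(icer_nd, results$name[!dom])
  out <- rbind(results[which(dom)[ord_dom], , drop = FALSE],
               results[which(!dom)[ord_nd], , drop = FALSE])
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# mid-50% range by rank-dropping: sort, drop floor(n/4) from each end,
# report the min and max of the remainder
mid50_range <- function(x) {
  x <- sort(x)
  k <- floor(length(x) / 4)
  r <- x[(k + 1):(length(x) - k)]
  c(low = min(r), high = max(r))
}

#' Portfolio summary across evaluated interventions
#'
#' Counts by dominance class, the summed first-three-year budget, means
#' of intervention costs and HALYs by dominance group and by
#' regulatory/program classification with their ratios, and mid-50\%
#' ranges (rank-dropping: drop floor(n/4) values from each end) for
#' HALYs, total intervention costs and net costs.
#'
#' @param results data.frame with `name`, `classification`,
#'   `halys_gained`, `intervention_cost_total`,
#'   `intervention_cost_first3y`, `cost_offsets`, `net_cost`, `icer`,
#'   `dominance_class`.
#' @param wtp willingness-to-pay threshold, default 50000.
#' @return a nested list of summaries.
#' @export
portfolio_summary <- function(results, wtp = 50000) {
  stopifnot(nrow(results) >= 1)
  dom <- results$dominance_class == "dominant"
  ce <- dom | results$dominance_class == "cost_effective" |
    results$dominance_class == "cost_saving_health_neutral"
  reg <- results$classification == "regulatory"
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  ratio <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_
           else a / b
  m_cost_dom <- mean_or_na(results$intervention_cost_total[dom])
  m_cost_nd <- mean_or_na(results$intervention_cost_total[!dom])
  m_haly_dom <- mean_or_na(results$halys_gained[dom])
  m_haly_nd <- mean_or_na(results$halys_gained[!dom])
  m_cost_reg <- mean_or_na(results$intervention_cost_total[reg])
  m_cost_prog <- mean_or_na(results$intervention_cost_total[!reg])
  m_haly_reg <- mean_or_na(results$halys_gained[reg])
  m_haly_prog <- mean_or_na(results$halys_gained[!reg])
  nd_icer <- results$icer[!dom & is.finite(results$icer)]
  list(
    n = nrow(results),
    n_dominant = sum(dom),
    n_cost_effective = sum(ce),
    first3y_total = sum(results$intervention_cost_first3y),
    icer_range_nondominant = if (length(nd_icer))
      range(nd_icer) else c(NA_real_, NA_real_),
    means = list(
      cost_dominant = m_cost_dom, cost_nondominant = m_cost_nd,
      halys_dominant = m_haly_dom, halys_nondominant = m_haly_nd,
      cost_regulatory = m_cost_reg, cost_program = m_cost_prog,
      halys_regulatory = m_haly_reg, halys_program = m_haly_prog),
    ratios = list(
      cost_nondominant_over_dominant = ratio(m_cost_nd, m_cost_dom),
      halys_dominant_over_nondominant = ratio(m_haly_dom, m_haly_nd),
      cost_program_over_regulatory = ratio(m_cost_prog, m_cost_reg),
      halys_program_over_regulatory = ratio(m_haly_prog, m_haly_reg)),
    mid50 = list(
      halys = mid50_range(results$halys_gained),
      intervention_cost = mid50_range(results$intervention_cost_total),
      net_cost = mid50_range(results$net_cost))
  )
}

#' Published league-table point estimates
#'
#' Point estimates transcribed from the published cost-effectiveness
#' league table of a 16-intervention obesity-prevention priority-setting
#' analysis for Australia (2010 AUD): total HALYs gained, total
#' intervention cost, first-three-year intervention cost, healthcare cost
#' offsets, net cost (all in AUD millions except HALYs), the printed
#' ICER for non-dominant rows and the evidence rating for BMI outcomes.
#' Used by the economics-only replay mode and the acceptance checks.
#'
#' @return data.frame, one row per intervention.
#' @export
league_table_fixture <- function() {
  read_results_fixture(system.file("extdata", "table3_fixture.csv",
                                   package = "pmslt", mustWork = TRUE))
}

#' Read a league-table results CSV
#'
#' Expects columns `name`, `classification`, `halys_gained`,
#' `intervention_cost_m`, `first3y_cost_m`, `cost_offsets_m`,
#' `net_cost_m`, `icer`, `evidence_bmi` (costs in AUD millions; blank
#' ICER = dominant). Returns the table in model units (AUD) with derived
#' `net_cost`, `icer` and `dominance_class` columns; the printed net cost
#' is kept (printed tables round, so it may differ slightly from cost
#' minus offsets).
#'
#' @param path CSV path.
#' @return data.frame of evaluation results.
#' @export
read_results_fixture <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "classification", "halys_gained",
            "intervention_cost_m", "first3y_cost_m", "cost_offsets_m",
            "net_cost_m", "icer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("results fixture is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(
    name = df$name, classification = df$classification,
    halys_gained = df$halys_gained,
    intervention_cost_total = df$intervention_cost_m * 1e6,
    intervention_cost_first3y = df$first3y_cost_m * 1e6,
    cost_offsets = df$cost_offsets_m * 1e6,
    net_cost = df$net_cost_m * 1e6,
    icer = df$icer, stringsAsFactors = FALSE)
  if ("evidence_bmi" %in% names(df)) out$evidence_bmi <- df$evidence_bmi
  cls <- character(nrow(out))
  for (k in seq_len(nrow(out)))
    cls[k] <- compute_icer(out$net_cost[k], out$halys_gained[k])$dominance_class
  out$dominance_class <- cls
  out
}
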