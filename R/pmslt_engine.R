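# The proportional multi-state life table engine. Each disease runs as a
# parallel sub-lifetable (susceptible/prevalent compartments with
# incidence, case fatality, remission); prevalence and disease mortality
# feed the main lifetable's all-cause mortality and morbidity, which
# yields person-years, HALYs and healthcare costs per cohort-year.
#
# Conventions (fixed, applied everywhere):
#   * annual cycles; rates become probabilities via q = 1 - exp(-rate)
#   * update order within a cycle: incidence, case fatality, remission,
#     then background mortality (background mortality is removed
#     proportionally from both compartments, so it cancels from the
#     conditional prevalence C/(S+C) and the sub-lifetables omit it)
#   * half-cycle correction L = (l_y + l_{y+1}) / 2
#   * discount factor (1 + r)^(-t) with t = 0 in the first model year
#   * cohorts truncate at age 100 (final partial person-years counted)

rate_to_prob <- function(rate) 1 - exp(-rate)

#' Run a single disease sub-lifetable
#'
#' Annual compartment updates for one cohort and one disease, in the fixed
#' order: new cases = S q_i, disease deaths = C q_f, remissions = C q_r,
#' then S <- S - new + rem, C <- C + new - deaths - rem. `incidence_scale`
#' carries (1 - PIF) per year. With `convert_rates = FALSE` the raw rates
#' are used as probabilities (small-rate mode, useful for hand checks);
#' the default converts via q = 1 - exp(-rate).
#'
#' @param incidence,case_fatality,remission per-year rate vectors (scalars
#'   recycle).
#' @param n_years number of annual cycles.
#' @param incidence_scale per-year incidence multiplier (1 - PIF);
#'   scalar or vector.
#' @param S0,C0 initial disease-free and prevalent proportions.
#' @param convert_rates convert rates to probabilities first? Default TRUE.
#' @return data.frame with one row per year (1..n_years): `S`, `C` after
#'   the year's update, `new_cases`, `d_mort` (disease deaths during the
#'   year, = C q_f of the start-of-year C).
#' @export
#' @examples
#' run_disease_process(0.01, 0.1, 0, n_years = 2, convert_rates = FALSE)
run_disease_process <- function(incidence, case_fatality, remission = 0,
                                n_years = max(length(incidence),
                                              length(case_fatality)),
                                incidence_scale = 1, S0 = 1, C0 = 0,
                                convert_rates = TRUE) {
  i <- rep_len(incidence, n_years)
  f <- rep_len(case_fatality, n_years)
  r <- rep_len(remission, n_years)
  sc <- rep_len(incidence_scale, n_years)
  qi <- if (convert_rates) rate_to_prob(i * sc) else i * sc
  qf <- if (convert_rates) rate_to_prob(f) else f
  qr <- if (convert_rates) rate_to_prob(r) else r
  S <- C <- new <- dth <- numeric(n_years)
  s <- S0; c0 <- C0
  for (y in seq_len(n_years)) {
    new[y] <- s * qi[y]
    dth[y] <- c0 * qf[y]
    rem <- c0 * qr[y]
    s <- s - new[y] + rem
    c0 <- c0 + new[y] - dth[y] - rem
    if (s < -1e-12 || c0 < -1e-12)
      stop("disease process produced a negative compartment; ",
           "rates too large for raw mode", call. = FALSE)
    S[y] <- s; C[y] <- c0
  }
  data.frame(year = seq_len(n_years), S = S, C = C, new_cases = new,
             d_mort = dth)
}

# Engine tables: flat lookup arrays over (age, sex), per-stratum-year
# rate cubes for the cohort loop, steady-state initial compartments and
# the PIF quadrature cache.
prepare_engine <- function(bundle) {
  pop <- bundle$population
  dis <- bundle$diseases
  dr <- bundle$disease_rates
  amin <- min(pop$age)
  ages <- amin:100
  A <- length(ages)
  sexes <- sort(unique(pop$sex))
  ns <- length(sexes)
  nd <- nrow(dis)
  n <- nrow(pop)

  flat_as <- function(age, sex) (match(sex, sexes) - 1L) * A +
    (age - amin + 1L)
  key <- flat_as(dr$age, dr$sex)
  ok <- !is.na(key) & dr$age >= amin
  inc <- cf <- rem <- matrix(0, A * ns, nd)
  dcol <- match(dr$disease_id, dis$disease_id)
  inc[cbind(key[ok], dcol[ok])] <- dr$incidence[ok]
  cf[cbind(key[ok], dcol[ok])] <- dr$case_fatality[ok]
  rem[cbind(key[ok], dcol[ok])] <- dr$remission[ok]

  pk <- flat_as(pop$age, pop$sex)
  mort <- yld <- bmi_mean <- rep(NA_real_, A * ns)
  mort[pk] <- pop$mortality_all_cause
  yld[pk] <- pop$yld_all_cause
  bmi_mean[pk] <- exp(pop$bmi_mu + pop$bmi_sigma^2 / 2)
  if (anyNA(mort))
    stop("population table must cover every age from ", amin,
         " to 100 for each sex", call. = FALSE)

  # steady-state compartments by running each disease from the youngest
  # age; prevalence is the normalised C/(S+C)
  Sst <- Cst <- array(NA_real_, c(A, ns, nd))
  for (sx in seq_len(ns)) {
    rows <- (sx - 1L) * A + seq_len(A)
    for (d in seq_len(nd)) {
      s <- 1; c0 <- 0
      for (ai in seq_len(A)) {
        Sst[ai, sx, d] <- s; Cst[ai, sx, d] <- c0
        qi <- rate_to_prob(inc[rows[ai], d])
        qf <- rate_to_prob(cf[rows[ai], d])
        qr <- rate_to_prob(rem[rows[ai], d])
        new <- s * qi; dth <- c0 * qf; rm_ <- c0 * qr
        s <- s - new + rm_; c0 <- c0 + new - dth - rm_
      }
    }
  }
  tot <- Sst + Cst
  prev <- Cst / tot
  prev[!is.finite(prev)] <- 0

  # residual (non-modelled) mortality = all-cause minus implied
  # disease-specific mortality, floored at zero
  implied <- rep(0, A * ns)
  for (d in seq_len(nd))
    implied <- implied + as.vector(prev[, , d]) * cf[, d]
  resid <- mort - implied
  if (any(resid[pk] < -1e-12))
    warning("implied disease mortality exceeds all-cause mortality for ",
            "some strata; residual mortality floored at 0")
  resid <- pmax(resid, 0)

  # growth reference medians for the child HRQoL term
  ref_bmi <- rep(NA_real_, A * ns)
  gr <- bundle$growth_reference
  if (!is.null(gr) && nrow(gr)) {
    gk <- flat_as(gr$age, gr$sex)
    ok <- !is.na(gk) & gr$age >= amin
    ref_bmi[gk[ok]] <- gr$M[ok]
  }

  # per-stratum-year cubes (dims [stratum, disease, year])
  Y <- 101L - amin
  age0 <- pop$age
  sexidx <- match(pop$sex, sexes)
  ial <- outer(age0, 0:(Y - 1), "+")
  active <- ial <= 100L
  idx <- as.vector((sexidx - 1L) * A + (pmin(ial, 100L) - amin + 1L))
  to_cube <- function(m) aperm(array(m[idx, ], c(n, Y, nd)), c(1, 3, 2))
  inc_cube <- to_cube(inc)
  cf_cube <- to_cube(cf)
  qf_cube <- rate_to_prob(cf_cube)
  qr_cube <- rate_to_prob(to_cube(rem))
  resid_sy <- matrix(resid[idx], n, Y)
  yld_sy <- matrix(yld[idx], n, Y)
  # child BMI excess base (mean BMI minus reference median at the
  # attained age); -Inf marks non-child stratum-years
  bd <- bmi_mean[idx] - ref_bmi[idx]
  bd[as.vector(ial) >= 18 | is.na(bd)] <- -Inf
  bd_sy <- matrix(bd, n, Y)

  S0m <- C0m <- matrix(0, n, nd)
  a0i <- age0 - amin + 1L
  for (d in seq_len(nd)) {
    sd <- Sst[cbind(a0i, sexidx, d)]
    cd <- Cst[cbind(a0i, sexidx, d)]
    S0m[, d] <- sd / (sd + cd)
    C0m[, d] <- cd / (sd + cd)
  }

  tmrels <- unique(bundle$rr$tmrel[bundle$rr$risk_factor == "bmi"])
  quad <- pif_quad_cache(pop, tmrels[!is.na(tmrels)])

  list(amin = amin, ages = ages, A = A, sexes = sexes, nd = nd, n = n,
       Y = Y, inc = inc, cf = cf, rem = rem, mort = mort, yld = yld,
       resid = resid, bmi_mean = bmi_mean, ref_bmi = ref_bmi,
       prev0 = prev, S0m = S0m, C0m = C0m, active = active,
       inc_cube = inc_cube, cf_cube = cf_cube, qf_cube = qf_cube,
       qr_cube = qr_cube, resid_sy = resid_sy, yld_sy = yld_sy,
       bd_sy = bd_sy, any_child = any(is.finite(bd)), quad = quad,
       dw = dis$disability_weight, cost = dis$annual_cost_per_case)
}

#' Steady-state disease prevalence implied by the catalogue
#'
#' Runs each disease process from the youngest modelled age with the
#' catalogue's incidence, case fatality and remission, and reports the
#' prevalence C/(S+C) at the start of each age. This is the prevalence a
#' cohort reaching that age holds at model start.
#'
#' @param bundle a `pmslt_bundle`.
#' @return data.frame `disease_id`, `age`, `sex`, `prevalence`.
#' @export
steady_state_prevalence <- function(bundle) {
  eng <- prepare_engine(bundle)
  grid <- expand.grid(age = eng$ages, sex = eng$sexes,
                      disease_id = bundle$diseases$disease_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$prevalence <- as.vector(eng$prev0)
  grid[, c("disease_id", "age", "sex", "prevalence")]
}

# Total disease-specific mortality rate implied by steady-state prevalence.
implied_disease_mortality <- function(bundle, ss = NULL) {
  eng <- prepare_engine(bundle)
  tot <- rep(0, eng$A * length(eng$sexes))
  for (d in seq_len(eng$nd))
    tot <- tot + as.vector(eng$prev0[, , d]) * eng$cf[, d]
  data.frame(age = rep(eng$ages, length(eng$sexes)),
             sex = rep(eng$sexes, each = eng$A), total = tot)
}

#' Run the proportional multi-state life table
#'
#' Simulates every population stratum as a closed cohort from its baseline
#' age to age 100. Disease sub-lifetables are scaled by (1 - PIF) per
#' year; all-cause mortality each year is the residual (non-modelled)
#' mortality plus the prevalence-weighted case fatality of the modelled
#' diseases; morbidity is the baseline all-cause YLD rate adjusted by the
#' prevalence differences times disability weights, plus the child BMI
#' HRQoL decrement. Person-years use the half-cycle correction; HALYs and
#' healthcare costs (the modelled diseases only) are discounted to the
#' first model year.
#'
#' @param bundle a validated `pmslt_bundle`.
#' @param pif optional `pif[stratum, disease, year]` array
#'   ([pifs_for_intervention()]); `NULL` means baseline.
#' @param deltas optional `risk_factor_delta` (for the child HRQoL term).
#' @param discount_rate annual discount rate (default from bundle
#'   settings, else 0.03).
#' @param child_hrql_coeff utility decrement per BMI unit above the
#'   age--sex reference in ages 2--17 (default from settings, else 0.005).
#' @param baseline a previous baseline result to difference against
#'   (computed on the fly when omitted and `pif` is given).
#' @return object of class `pmslt_outcome`: `total_halys`, `total_cost`,
#'   `cost_by_disease`, `by_year` (year, halys, cost), `by_cohort`,
#'   baseline prevalence array `P` (baseline runs only), survivor matrix
#'   `l`, the engine tables (for reuse), and the `scenario` label.
#' @export
run_lifetable <- function(bundle, pif = NULL, deltas = NULL,
                          discount_rate = NULL, child_hrql_coeff = NULL,
                          baseline = NULL) {
  st <- bundle$settings
  discount_rate <- discount_rate %||% (st$discount_rate %||% 0.03)
  child_hrql_coeff <- child_hrql_coeff %||% (st$child_hrql_coeff %||% 0.005)
  eng <- if (!is.null(baseline)) baseline$engine else prepare_engine(bundle)
  if (is.null(baseline) && !is.null(pif))
    baseline <- run_lifetable(bundle, pif = NULL, deltas = NULL,
                              discount_rate = discount_rate,
                              child_hrql_coeff = child_hrql_coeff)
  pop <- bundle$population
  n <- eng$n; nd <- eng$nd; Y <- eng$Y

  count <- pop$count
  disc <- (1 + discount_rate)^(-(0:(Y - 1)))
  store_P <- is.null(pif)
  core <- .lifetable_core(
    eng$S0m, eng$C0m, eng$inc_cube, eng$cf_cube, eng$qf_cube, eng$qr_cube,
    eng$resid_sy, eng$yld_sy, eng$bd_sy, eng$active, eng$dw, eng$cost,
    count, disc,
    pif, baseline$P,
    if (!is.null(deltas)) deltas$bmi_shift else NULL,
    if (eng$any_child) child_hrql_coeff else 0, store_P)
  haly_sy <- core$haly_sy; cost_sy <- core$cost_sy
  cost_by_disease <- core$cost_by_disease
  lmat <- core$lmat
  P <- if (store_P) core$P else NULL

  by_year <- data.frame(year = 0:(Y - 1), halys = colSums(haly_sy),
                        cost = colSums(cost_sy))
  by_cohort <- data.frame(age = pop$age, sex = pop$sex,
                          halys = rowSums(haly_sy), cost = rowSums(cost_sy))
  structure(list(
    total_halys = sum(haly_sy), total_cost = sum(cost_sy),
    cost_by_disease = stats::setNames(cost_by_disease,
                                      bundle$diseases$disease_id),
    by_year = by_year, by_cohort = by_cohort, P = P, l = lmat,
    engine = eng, discount_rate = discount_rate,
    child_hrql_coeff = child_hrql_coeff,
    scenario = if (is.null(pif)) "baseline" else "intervention"
  ), class = "pmslt_outcome")
}

#' @export
print.pmslt_outcome <- function(x, ...) {
  cat(sprintf("<pmslt_outcome: %s>\n  total HALYs: %.1f\n  total cost: %.0f\n",
              x$scenario, x$total_halys, x$total_cost))
  invisible(x)
}

#' Evaluate one intervention against the no-intervention comparator
#'
#' Builds the risk-factor deltas, the PIF table and the scenario life
#' table, and differences against baseline: HALYs gained = scenario -
#' baseline HALYs; cost offsets = baseline - scenario healthcare costs
#' (positive = savings).
#'
#' @param bundle a validated `pmslt_bundle`.
#' @param spec an intervention name (looked up in `bundle$interventions`)
#'   or a one-row specification data.frame.
#' @param discount_rate,child_hrql_coeff model settings, defaulting to the
#'   bundle settings.
#' @param baseline optional precomputed baseline `pmslt_outcome`.
#' @param effect_size,uptake optional overrides of the specification (used
#'   by the uncertainty machinery).
#' @param rr_scale optional named vector (by disease) of multiplicative
#'   factors applied on the log-RR scale: each affected RR becomes
#'   `exp(f * log(rr))`. Used by the uncertainty machinery to propagate
#'   log-normal RR draws.
#' @return list: `halys_gained`, `cost_offsets`, `by_year` (incremental
#'   streams), `scenario`, `baseline`.
#' @export
evaluate_intervention <- function(bundle, spec, discount_rate = NULL,
                                  child_hrql_coeff = NULL, baseline = NULL,
                                  effect_size = NULL, uptake = NULL,
                                  rr_scale = NULL) {
  if (is.character(spec)) {
    i <- match(spec, bundle$interventions$name)
    if (is.na(i)) stop("unknown intervention: ", spec, call. = FALSE)
    spec <- bundle$interventions[i, ]
  }
  if (!is.null(effect_size)) spec$effect_size <- effect_size
  if (!is.null(uptake)) spec$uptake <- uptake
  b <- bundle
  if (!is.null(rr_scale)) {
    i <- match(b$rr$disease_id, names(rr_scale))
    f <- ifelse(is.na(i), 1, rr_scale[i])
    adj <- b$rr$form == "loglinear_per_unit" |
      (b$rr$form == "categorical" & b$rr$rr != 1)
    b$rr$rr <- ifelse(adj, exp(log(b$rr$rr) * f), b$rr$rr)
  }
  st <- bundle$settings
  eb <- if (!is.null(st$energy_balance)) do.call(energy_balance_params,
                                                 st$energy_balance)
        else energy_balance_params()
  deltas <- build_risk_deltas(
    spec, bundle$population, bundle$growth_reference, eb,
    pa_affects_bmi = st$flags$pa_affects_bmi %||% TRUE,
    net_mets = st$flags$net_mets %||% FALSE)
  if (is.null(baseline))
    baseline <- run_lifetable(bundle, discount_rate = discount_rate,
                              child_hrql_coeff = child_hrql_coeff)
  pif <- pifs_for_intervention(deltas, b, quad = baseline$engine$quad)
  scen <- run_lifetable(bundle, pif = pif, deltas = deltas,
                        discount_rate = discount_rate,
                        child_hrql_coeff = child_hrql_coeff,
                        baseline = baseline)
  by_year <- data.frame(year = baseline$by_year$year,
                        haly_gain = scen$by_year$halys - baseline$by_year$halys,
                        cost_offset = baseline$by_year$cost -
                          scen$by_year$cost)
  list(halys_gained = scen$total_halys - baseline$total_halys,
       cost_offsets = baseline$total_cost - scen$total_cost,
       by_year = by_year, scenario = scen, baseline = baseline)
}
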