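# Parameter-uncertainty propagation: Monte Carlo with percentile
# uncertainty intervals, univariate sensitivity analyses, and
# threshold analyses by bisection on the ICER.

valid_families <- c("lognormal", "gamma", "beta", "normal_truncated",
                    "degenerate")

#' Build a parameter-distribution table
#'
#' One row per uncertain parameter: `parameter` is a path string
#' (`"effect_size"`, `"uptake"`, `"cost_scale"`, `"rr:<disease_id>"`,
#' `"disease_cost:<disease_id>"`), `family` one of lognormal (par1 =
#' meanlog, par2 = sdlog), gamma (shape, rate), beta (shape1, shape2),
#' normal_truncated (mean, sd, lower = par3, upper = par4) or degenerate
#' (par1 = value).
#'
#' @param parameter,family,par1,par2,par3,par4 columns, recycled.
#' @return data.frame of class `parameter_distributions`.
#' @export
parameter_distributions <- function(parameter, family, par1, par2 = NA_real_,
                                    par3 = NA_real_, par4 = NA_real_) {
  df <- data.frame(parameter = parameter, family = family, par1 = par1,
                   par2 = par2, par3 = par3, par4 = par4,
                   stringsAsFactors = FALSE)
  validate_distributions(df)
  df
}

validate_distributions <- function(dists) {
  bad <- setdiff(dists$family, valid_families)
  if (length(bad))
    stop("invalid distribution family: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in seq_len(nrow(dists))) {
    fam <- dists$family[k]
    p1 <- dists$par1[k]; p2 <- dists$par2[k]
    if (fam == "lognormal" && (is.na(p2) || p2 < 0))
      stop("lognormal sdlog must be >= 0", call. = FALSE)
    if (fam == "gamma" && (p1 <= 0 || is.na(p2) || p2 <= 0))
      stop("gamma shape and rate must be > 0", call. = FALSE)
    if (fam == "beta" && (p1 <= 0 || is.na(p2) || p2 <= 0))
      stop("beta shapes must be > 0", call. = FALSE)
    if (fam == "normal_truncated" && (is.na(p2) || p2 < 0))
      stop("normal_truncated sd must be >= 0", call. = FALSE)
  }
  invisible(dists)
}

sample_parameter <- function(family, par1, par2, par3 = NA, par4 = NA) {
  switch(family,
    degenerate = par1,
    lognormal = stats::rlnorm(1, par1, par2),
    gamma = stats::rgamma(1, shape = par1, rate = par2),
    beta = stats::rbeta(1, par1, par2),
    normal_truncated = {
      lo <- if (is.na(par3)) -Inf else par3
      hi <- if (is.na(par4)) Inf else par4
      if (par2 == 0) return(min(max(par1, lo), hi))
      u <- stats::runif(1, stats::pnorm(lo, par1, par2),
                        stats::pnorm(hi, par1, par2))
      stats::qnorm(u, par1, par2)
    },
    stop("invalid distribution family: ", family, call. = FALSE))
}

#' Default parameter distributions for an intervention
#'
#' Standard health-economics choices: a truncated normal on the effect
#' size (truncated at zero on the far side so beneficial effects stay
#' beneficial), a beta on uptake (concentration 100; degenerate at 0/1),
#' log-normals on each disease's BMI relative risk (meanlog = log RR,
#' sdlog = the RR's log-scale standard error), and a gamma with mean 1
#' and 10\% coefficient of variation scaling total intervention cost.
#'
#' @param bundle a `pmslt_bundle`.
#' @param spec an intervention row or name.
#' @return a `parameter_distributions` data.frame.
#' @export
default_distributions <- function(bundle, spec) {
  if (is.character(spec))
    spec <- bundle$interventions[match(spec, bundle$interventions$name), ]
  rows <- list()
  e <- spec$effect_size; se <- spec$effect_se %||% abs(e) * 0.15
  rows[[1]] <- data.frame(parameter = "effect_size",
                          family = "normal_truncated", par1 = e, par2 = se,
                          par3 = if (e < 0) NA_real_ else 0,
                          par4 = if (e < 0) 0 else NA_real_)
  u <- spec$uptake
  rows[[2]] <- if (u <= 0 || u >= 1) {
    data.frame(parameter = "uptake", family = "degenerate", par1 = u,
               par2 = NA_real_, par3 = NA_real_, par4 = NA_real_)
  } else {
    data.frame(parameter = "uptake", family = "beta", par1 = u * 100,
               par2 = (1 - u) * 100, par3 = NA_real_, par4 = NA_real_)
  }
  rr_bmi <- bundle$rr[bundle$rr$risk_factor == "bmi", ]
  rows[[3]] <- data.frame(parameter = paste0("rr:", rr_bmi$disease_id),
                          family = "lognormal", par1 = log(rr_bmi$rr),
                          par2 = rr_bmi$log_se, par3 = NA_real_,
                          par4 = NA_real_)
  rows[[4]] <- data.frame(parameter = "cost_scale", family = "gamma",
                          par1 = 100, par2 = 100, par3 = NA_real_,
                          par4 = NA_real_)
  out <- do.call(rbind, rows)
  validate_distributions(out)
  out
}

#' Monte Carlo uncertainty analysis for one intervention
#'
#' Each iteration samples every parameter distribution once and evaluates
#' the full pipeline with that common draw (baseline and scenario share
#' the draw, so incremental outputs difference out shared parameters),
#' collecting HALYs gained, cost offsets, intervention cost, net cost and
#' ICER. Uncertainty intervals are percentile-based. Fully reproducible
#' given `seed`.
#'
#' @param bundle a validated `pmslt_bundle`.
#' @param spec intervention name or row.
#' @param dists a `parameter_distributions` table; default
#'   [default_distributions()].
#' @param n iterations (the study default is 2000).
#' @param seed integer seed.
#' @param wtp willingness-to-pay per HALY.
#' @param rules [costing_rules()] for the intervention costing.
#' @param discount_rate,child_hrql_coeff model settings (bundle defaults).
#' @param baseline optional precomputed baseline outcome.
#' @return object of class `mc_result`: `point` (deterministic outputs),
#'   `draws` (one row per iteration), `summary` (mean and 95\% UI per
#'   output), `n_iterations`, `seed`.
#' @export
run_monte_carlo <- function(bundle, spec, dists = NULL, n = 2000, seed = 1L,
                            wtp = NULL, rules = costing_rules(),
                            discount_rate = NULL, child_hrql_coeff = NULL,
                            baseline = NULL) {
  stopifnot(n >= 1)
  if (is.character(spec))
    spec <- bundle$interventions[match(spec, bundle$interventions$name), ]
  if (is.null(dists)) dists <- default_distributions(bundle, spec)
  validate_distributions(dists)
  wtp <- wtp %||% (bundle$settings$wtp %||% 50000)
  discount_rate <- discount_rate %||%
    (bundle$settings$discount_rate %||% 0.03)
  if (is.null(baseline))
    baseline <- run_lifetable(bundle, discount_rate = discount_rate,
                              child_hrql_coeff = child_hrql_coeff)
  comp <- bundle$cost_components[
    bundle$cost_components$intervention == spec$name, , drop = FALSE]
  cost0 <- cost_intervention(comp, rules, discount_rate)

  spec <- as.list(spec)  # cheap field access in the iteration loop
  point_ev <- evaluate_intervention(bundle, spec,
                                    discount_rate = discount_rate,
                                    child_hrql_coeff = child_hrql_coeff,
                                    baseline = baseline)
  point <- mc_outputs(point_ev, cost0$total_discounted, 1, NULL, wtp)

  draws <- local_seed(seed, {
    out <- matrix(NA_real_, n, 5,
                  dimnames = list(NULL, c("halys_gained", "cost_offsets",
                                          "intervention_cost", "net_cost",
                                          "icer")))
    for (it in seq_len(n)) {
      dr <- vapply(seq_len(nrow(dists)), function(k)
        sample_parameter(dists$family[k], dists$par1[k], dists$par2[k],
                         dists$par3[k], dists$par4[k]), numeric(1))
      names(dr) <- dists$parameter
      rr_i <- grep("^rr:", names(dr))
      rr_scale <- NULL
      if (length(rr_i)) {
        dn <- sub("^rr:", "", names(dr)[rr_i])
        base_rr <- bundle$rr$rr[match(dn, bundle$rr$disease_id)]
        rr_scale <- stats::setNames(log(dr[rr_i]) / log(base_rr), dn)
        rr_scale[!is.finite(rr_scale)] <- 1
      }
      ev <- evaluate_intervention(
        bundle, spec, discount_rate = discount_rate,
        child_hrql_coeff = child_hrql_coeff, baseline = baseline,
        effect_size = unname(dr["effect_size"]) %na% spec$effect_size,
        uptake = unname(dr["uptake"]) %na% spec$uptake,
        rr_scale = rr_scale)
      cscale <- unname(dr["cost_scale"]) %na% 1
      dcost_i <- grep("^disease_cost:", names(dr))
      offsets <- ev$cost_offsets
      if (length(dcost_i)) {
        dn <- sub("^disease_cost:", "", names(dr)[dcost_i])
        off_d <- baseline$cost_by_disease - ev$scenario$cost_by_disease
        g <- stats::setNames(rep(1, length(off_d)), names(off_d))
        g[dn] <- dr[dcost_i] / bundle$diseases$annual_cost_per_case[
          match(dn, bundle$diseases$disease_id)]
        offsets <- sum(off_d * g)
      }
      icost <- cost0$total_discounted * cscale
      net <- icost - offsets
      out[it, ] <- c(ev$halys_gained, offsets, icost, net,
                     compute_icer(net, ev$halys_gained, wtp)$icer)
    }
    out
  })
  draws <- as.data.frame(draws)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  summ <- lapply(draws, function(x)
    c(mean = mean(x, na.rm = TRUE), lo = qs(x)[1], hi = qs(x)[2]))
  structure(list(point = point, draws = draws, summary = summ,
                 n_iterations = n, seed = as.integer(seed)),
            class = "mc_result")
}

`%na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

mc_outputs <- function(ev, icost, cscale, offsets_override, wtp) {
  offsets <- offsets_override %||% ev$cost_offsets
  net <- icost * cscale - offsets
  ic <- compute_icer(net, ev$halys_gained, wtp)
  list(halys_gained = ev$halys_gained, cost_offsets = offsets,
       intervention_cost = icost * cscale, net_cost = net,
       icer = ic$icer, dominance_class = ic$dominance_class)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result: %d iterations, seed %d>\n", x$n_iterations,
              x$seed))
  for (nm in names(x$summary))
    cat(sprintf("  %-18s mean %12.4g  95%% UI [%12.4g, %12.4g]\n", nm,
                x$summary[[nm]]["mean"], x$summary[[nm]]["lo"],
                x$summary[[nm]]["hi"]))
  invisible(x)
}

sensitivity_params <- c("discount_rate", "effect_size", "uptake",
                        "child_hrql_coeff", "cost_scale")

eval_with_param <- function(bundle, spec, param, value, wtp, rules,
                            baseline, model_cache = NULL) {
  discount_rate <- bundle$settings$discount_rate %||% 0.03
  child <- bundle$settings$child_hrql_coeff %||% 0.005
  comp <- bundle$cost_components[
    bundle$cost_components$intervention == spec$name, , drop = FALSE]
  cscale <- 1
  if (param == "cost_scale") {
    cscale <- value
    ev <- model_cache %||% evaluate_intervention(bundle, spec,
                                                 baseline = baseline)
    cost <- cost_intervention(comp, rules, discount_rate)
  } else if (param == "discount_rate") {
    ev <- evaluate_intervention(bundle, spec, discount_rate = value)
    cost <- cost_intervention(comp, rules, value)
  } else if (param == "effect_size") {
    ev <- evaluate_intervention(bundle, spec, baseline = baseline,
                                effect_size = value)
    cost <- cost_intervention(comp, rules, discount_rate)
  } else if (param == "uptake") {
    if (value < 0 || value > 1)
      stop("uptake values must lie in [0, 1]", call. = FALSE)
    ev <- evaluate_intervention(bundle, spec, baseline = baseline,
                                uptake = value)
    cost <- cost_intervention(comp, rules, discount_rate)
  } else if (param == "child_hrql_coeff") {
    ev <- evaluate_intervention(bundle, spec, child_hrql_coeff = value)
    cost <- cost_intervention(comp, rules, discount_rate)
  } else {
    stop("unknown sensitivity parameter: ", param, call. = FALSE)
  }
  c(list(param = param, value = value, model = ev),
    mc_outputs(ev, cost$total_discounted, cscale, NULL, wtp))
}

#' Univariate sensitivity analysis
#'
#' One deterministic pipeline run per parameter value, everything else at
#' base case. Supported parameters: `discount_rate`, `effect_size`,
#' `uptake`, `child_hrql_coeff`, `cost_scale` (a multiplier on the
#' intervention cost).
#'
#' @param bundle a `pmslt_bundle`.
#' @param spec intervention name or row.
#' @param param parameter name.
#' @param values numeric vector of parameter values (must be in the
#'   parameter's valid range).
#' @param wtp,rules see [run_monte_carlo()].
#' @return data.frame with one row per value: outputs and dominance
#'   class.
#' @export
univariate_sensitivity <- function(bundle, spec, param, values,
                                   wtp = NULL, rules = costing_rules()) {
  if (is.character(spec))
    spec <- bundle$interventions[match(spec, bundle$interventions$name), ]
  wtp <- wtp %||% (bundle$settings$wtp %||% 50000)
  if (param == "discount_rate" && any(values < 0))
    stop("discount_rate values must be >= 0", call. = FALSE)
  if (length(values) == 0)
    return(data.frame(param = character(), value = numeric(),
                      halys_gained = numeric(), cost_offsets = numeric(),
                      intervention_cost = numeric(), net_cost = numeric(),
                      icer = numeric(), dominance_class = character()))
  baseline <- if (param %in% c("effect_size", "uptake", "cost_scale"))
    run_lifetable(bundle) else NULL
  cache <- if (param == "cost_scale")
    evaluate_intervention(bundle, spec, baseline = baseline) else NULL
  rows <- lapply(values, function(v) {
    r <- eval_with_param(bundle, spec, param, v, wtp, rules, baseline,
                         cache)
    data.frame(param = param, value = v, halys_gained = r$halys_gained,
               cost_offsets = r$cost_offsets,
               intervention_cost = r$intervention_cost,
               net_cost = r$net_cost, icer = r$icer,
               dominance_class = r$dominance_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold analysis: parameter value at which the ICER hits the
#' willingness-to-pay threshold
#'
#' Bisection on the raw cost-effectiveness ratio net_cost/HALYs gained
#' (negative while the intervention is dominant) over `bracket`.
#' Endpoints are evaluated first; if the threshold is not bracketed the
#' result carries a `"no threshold"` diagnostic instead of a value.
#'
#' @param bundle a `pmslt_bundle`.
#' @param spec intervention name or row.
#' @param param sensitivity parameter (see [univariate_sensitivity()]).
#' @param bracket numeric length-2 search interval.
#' @param wtp threshold, default 50000.
#' @param tol relative tolerance on the ICER at the returned value
#'   (default 1e-6): stop when |ICER - wtp| <= tol * wtp.
#' @param max_iter bisection cap.
#' @param rules costing rules.
#' @return list: `threshold` (NA when not bracketed), `icer_at_threshold`,
#'   `iterations`, `diagnostic`.
#' @export
threshold_analysis <- function(bundle, spec, param, bracket, wtp = 50000,
                               tol = 1e-6, max_iter = 200,
                               rules = costing_rules()) {
  if (is.character(spec))
    spec <- bundle$interventions[match(spec, bundle$interventions$name), ]
  baseline <- run_lifetable(bundle)
  cache <- if (param == "cost_scale")
    evaluate_intervention(bundle, spec, baseline = baseline) else NULL
  ratio_at <- function(v) {
    r <- eval_with_param(bundle, spec, param, v, wtp, rules, baseline,
                         cache)
    if (r$halys_gained == 0) return(Inf)
    r$net_cost / r$halys_gained
  }
  f_lo <- ratio_at(bracket[1]) - wtp
  f_hi <- ratio_at(bracket[2]) - wtp
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    diag <- if (!is.na(f_lo) && !is.na(f_hi) && f_lo < 0 && f_hi < 0)
      "no threshold in range: cost-effective (or dominant) across bracket"
    else "no threshold in range"
    return(list(threshold = NA_real_, icer_at_threshold = NA_real_,
                iterations = 0L, diagnostic = diag))
  }
  lo <- bracket[1]; hi <- bracket[2]
  it <- 0L; mid <- NA_real_; fm <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- ratio_at(mid) - wtp
    if (abs(fm) <= tol * wtp) break
    if (fm * f_lo <= 0) hi <- mid else { lo <- mid; f_lo <- fm }
    if ((hi - lo) < .Machine$double.eps * max(1, abs(hi))) break
  }
  list(threshold = mid, icer_at_threshold = fm + wtp, iterations = it,
       diagnostic = if (abs(fm) <= tol * wtp) "converged"
                    else "bracket exhausted")
}
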