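# End-to-end orchestration: evaluate every intervention in a bundle
# (full mode), or replay printed league-table/considerations fixtures
# through the economics and ranking machinery only (tables-only mode).

#' Study-level configuration
#'
#' @param discount_rate annual discount rate, default 0.03.
#' @param wtp willingness to pay per HALY, default 50000.
#' @param n_iterations Monte Carlo iterations per intervention in full
#'   mode; 1 = deterministic only. The study default for probabilistic
#'   results is 2000.
#' @param seed integer seed for the Monte Carlo streams.
#' @param rules [costing_rules()].
#' @return a named list.
#' @export
study_config <- function(discount_rate = 0.03, wtp = 50000,
                         n_iterations = 1, seed = 1L,
                         rules = costing_rules()) {
  stopifnot(discount_rate >= 0, wtp > 0, n_iterations >= 1)
  list(discount_rate = discount_rate, wtp = wtp,
       n_iterations = n_iterations, seed = as.integer(seed), rules = rules)
}

#' Run a full study
#'
#' In `"full"` mode every intervention in the bundle is evaluated against
#' the shared baseline: risk-factor deltas, PIFs, scenario life table,
#' intervention costing, ICER and dominance class, then the league table
#' and portfolio summary (plus per-intervention Monte Carlo when
#' `n_iterations > 1`). In `"tables_only"` mode printed evaluation
#' results and considerations profiles are replayed through the
#' economics and ranking machinery without invoking the life table
#' engine.
#'
#' All outputs are computed before anything is written, so a failing
#' stage leaves no partial output files.
#'
#' @param bundle a `pmslt_bundle` or a path to a saved bundle directory
#'   (full mode).
#' @param config a [study_config()].
#' @param mode `"full"` or `"tables_only"`.
#' @param results a results data.frame or CSV path (tables-only mode;
#'   default: the packaged published league-table fixture).
#' @param profiles a considerations data.frame or CSV path (optional in
#'   full mode; default in tables-only mode: the packaged fixture).
#' @param output_dir optional directory; when given, writes
#'   `league_table.csv`, `portfolio_summary.json` (if jsonlite is
#'   installed, else .yml), `considerations.csv` and per-intervention
#'   incremental streams.
#' @param verbose emit progress messages?
#' @return list of class `pmslt_study`: `results`, `league_table`,
#'   `portfolio`, `considerations`, `mc`, `mode`, `config`.
#' @export
run_study <- function(bundle = NULL, config = study_config(),
                      mode = c("full", "tables_only"), results = NULL,
                      profiles = NULL, output_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  mc <- list()
  streams <- list()

  if (mode == "full") {
    if (is.character(bundle)) bundle <- load_bundle(bundle)
    if (is.null(bundle))
      stop("full mode requires a bundle (object or path)", call. = FALSE)
    validate_bundle(bundle)
    say("baseline life table ...")
    baseline <- run_lifetable(bundle, discount_rate = config$discount_rate)
    iv <- bundle$interventions
    rows <- vector("list", nrow(iv))
    for (k in seq_len(nrow(iv))) {
      nm <- iv$name[k]
      say("evaluating %s ...", nm)
      res <- tryCatch({
        ev <- evaluate_intervention(bundle, iv[k, ],
                                    discount_rate = config$discount_rate,
                                    baseline = baseline)
        comp <- bundle$cost_components[
          bundle$cost_components$intervention == nm, , drop = FALSE]
        cost <- cost_intervention(comp, config$rules, config$discount_rate)
        net <- cost$total_discounted - ev$cost_offsets
        ic <- compute_icer(net, ev$halys_gained, config$wtp)
        streams[[nm]] <- ev$by_year
        if (config$n_iterations > 1) {
          mc[[nm]] <- run_monte_carlo(
            bundle, iv[k, ], n = config$n_iterations,
            seed = config$seed + k, wtp = config$wtp,
            rules = config$rules, discount_rate = config$discount_rate,
            baseline = baseline)
        }
        data.frame(name = nm, classification = iv$classification[k],
                   halys_gained = ev$halys_gained,
                   intervention_cost_total = cost$total_discounted,
                   intervention_cost_first3y = cost$first3y_undiscounted,
                   cost_offsets = ev$cost_offsets, net_cost = net,
                   icer = ic$icer, dominance_class = ic$dominance_class,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        stop(sprintf("stage 'evaluate' failed for intervention '%s': %s",
                     nm, conditionMessage(e)), call. = FALSE)
      })
      rows[[k]] <- res
    }
    results <- do.call(rbind, rows)
  } else {
    if (is.null(results)) results <- league_table_fixture()
    if (is.character(results)) results <- read_results_fixture(results)
    if (is.null(profiles)) profiles <- considerations_fixture()
  }
  if (is.character(profiles)) profiles <- read_profiles_fixture(profiles)

  league <- build_league_table(results)
  portfolio <- portfolio_summary(results, config$wtp)
  considerations <- if (!is.null(profiles)) rank_considerations(profiles)

  out <- structure(list(results = results, league_table = league,
                        portfolio = portfolio,
                        considerations = considerations, mc = mc,
                        streams = streams, mode = mode, config = config),
                   class = "pmslt_study")
  if (!is.null(output_dir)) write_study_outputs(out, output_dir)
  out
}

write_study_outputs <- function(study, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  num_fmt <- function(df) {
    for (j in seq_along(df)) if (is.double(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
    df
  }
  utils::write.csv(num_fmt(study$league_table),
                   file.path(output_dir, "league_table.csv"),
                   row.names = FALSE)
  if (!is.null(study$considerations))
    utils::write.csv(study$considerations,
                     file.path(output_dir, "considerations.csv"),
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(study$portfolio,
                         file.path(output_dir, "portfolio_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(study$portfolio,
                     file.path(output_dir, "portfolio_summary.yml"))
  }
  for (nm in names(study$streams))
    utils::write.csv(num_fmt(study$streams[[nm]]),
                     file.path(output_dir, paste0("stream_", nm, ".csv")),
                     row.names = FALSE)
  invisible(output_dir)
}

#' @export
print.pmslt_study <- function(x, ...) {
  cat(sprintf("<pmslt_study: %s mode, %d interventions>\n", x$mode,
              nrow(x$results)))
  cat(sprintf("  dominant: %d of %d; cost-effective: %d\n",
              x$portfolio$n_dominant, x$portfolio$n,
              x$portfolio$n_cost_effective))
  lt <- x$league_table
  cat("  league table (rank, name, HALYs, net cost $M):\n")
  for (k in seq_len(min(nrow(lt), 20)))
    cat(sprintf("   %2d %-55s %10.0f %9.1f\n", lt$rank[k],
                substr(lt$name[k], 1, 55), lt$halys_gained[k],
                lt$net_cost[k] / 1e6))
  invisible(x)
}
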