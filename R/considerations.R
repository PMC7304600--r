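# Qualitative implementation-considerations framework: six factors
# (strength of evidence for BMI outcomes; strength of evidence for
# nutrition/physical-activity outcomes; equity; acceptability to the
# public, to government and to industry; feasibility; sustainability),
# each rated on an ordinal scale, and the league-table ordering built
# from them.

consideration_fields <- c("evidence_bmi", "evidence_pa_diet", "equity",
                          "accept_public", "accept_government",
                          "accept_industry", "feasibility",
                          "sustainability")

consideration_levels <- list(
  evidence_bmi = c("n/a", "low", "medium", "high"),
  evidence_pa_diet = c("n/a", "low", "medium", "high"),
  equity = c("negative", "neutral", "positive"),
  accept_public = c("low", "medium", "high"),
  accept_government = c("low", "medium", "high"),
  accept_industry = c("low", "medium", "high"),
  feasibility = c("low", "medium", "high"),
  sustainability = c("low", "medium", "high")
)

check_profiles <- function(profiles) {
  miss <- setdiff(c("name", consideration_fields), names(profiles))
  if (length(miss))
    stop("profiles are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in consideration_fields) {
    bad <- !profiles[[f]] %in% consideration_levels[[f]]
    if (any(bad))
      stop(sprintf("invalid %s rating: %s", f,
                   paste(unique(profiles[[f]][bad]), collapse = ", ")),
           call. = FALSE)
  }
  invisible(profiles)
}

#' Rank interventions on the implementation considerations
#'
#' Lexicographic ordering: strength of evidence for BMI outcomes
#' (high > medium > low > n/a), then strength of evidence for
#' nutrition/physical-activity outcomes (same order), then equity
#' (positive > neutral > negative), then the number of 'high' or
#' 'positive' ratings across all eight fields (descending); residual ties
#' break alphabetically by name.
#'
#' @param profiles data.frame with a `name` column and the eight rating
#'   columns (`evidence_bmi`, `evidence_pa_diet`, `equity`,
#'   `accept_public`, `accept_government`, `accept_industry`,
#'   `feasibility`, `sustainability`), lower-case ratings.
#' @return the profiles reordered with a `rank` column and the
#'   `n_high_positive` tally.
#' @export
rank_considerations <- function(profiles) {
  stopifnot(nrow(profiles) >= 1)
  check_profiles(profiles)
  score <- function(f) match(profiles[[f]], consideration_levels[[f]])
  n_hp <- rowSums(vapply(consideration_fields, function(f)
    profiles[[f]] %in% c("high", "positive"), logical(nrow(profiles))))
  ord <- order(-score("evidence_bmi"), -score("evidence_pa_diet"),
               -score("equity"), -n_hp, profiles$name)
  out <- profiles[ord, , drop = FALSE]
  out$n_high_positive <- n_hp[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count profiles with a field in given levels
#'
#' @param profiles profiles data.frame (see [rank_considerations()]).
#' @param field one of the eight rating fields.
#' @param levels character vector of levels to count.
#' @return integer count.
#' @export
#' @examples
#' p <- considerations_fixture()
#' tally_profiles(p, "equity", c("neutral", "positive"))
tally_profiles <- function(profiles, field, levels) {
  if (!field %in% consideration_fields)
    stop("unknown considerations field: ", field, call. = FALSE)
  bad <- setdiff(levels, consideration_levels[[field]])
  if (length(bad))
    stop("unknown level(s) for ", field, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  sum(profiles[[field]] %in% levels)
}

#' Published implementation-considerations ratings
#'
#' The considerations profiles transcribed from the published
#' implementation-considerations league table of the 16-intervention
#' obesity-prevention priority-setting analysis, together with the
#' printed ICER string and cost-effectiveness rank for context.
#'
#' @return data.frame, one row per intervention.
#' @export
considerations_fixture <- function() {
  read_profiles_fixture(system.file("extdata", "table4_fixture.csv",
                                    package = "pmslt", mustWork = TRUE))
}

#' Read a considerations-profiles CSV
#'
#' @param path CSV with columns `name`, the eight rating fields and
#'   optional context columns.
#' @return validated data.frame.
#' @export
read_profiles_fixture <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_profiles(df)
  df
}
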