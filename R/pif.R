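# Potential impact fractions. BMI uses the distribution-shift method
# against a log-normal exposure distribution with a log-linear RR above
# TMREL; physical activity uses the relative-risk-shift method over
# categorical activity bands. Joint effects combine multiplicatively.

# Quadrature cache for the vectorised distribution-shift PIF: the shared
# node grid (with a node at every TMREL), trapezoid weights, and the
# weighted baseline density matrix (one row per population stratum).
pif_quad_cache <- function(population, tmrels, n_nodes = 2001,
                           support = c(10, 60)) {
  x <- seq(support[1], support[2], length.out = n_nodes)
  x <- sort(unique(c(x, tmrels[tmrels > support[1] & tmrels < support[2]])))
  dx <- diff(x)
  w <- c(dx, 0) / 2 + c(0, dx) / 2
  n <- nrow(population)
  F0 <- matrix(stats::dlnorm(rep(x, each = n), population$bmi_mu,
                             population$bmi_sigma), n, length(x))
  F0w <- F0 * rep(w, each = n)
  tF0w <- t(F0w)
  cumF0wT <- apply(tF0w, 2, cumsum)
  list(x = x, w = w, F0w = F0w, tF0w = tF0w, cumF0wT = cumF0wT,
       m0 = rowSums(F0w), n_nodes = n_nodes, support = support)
}

pif_grid <- function(support, n_nodes, tmrel = NULL) {
  x <- seq(support[1], support[2], length.out = n_nodes)
  if (!is.null(tmrel) && tmrel > support[1] && tmrel < support[2])
    x <- sort(unique(c(x, tmrel)))
  x
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Potential impact fraction by the distribution-shift method (BMI)
#'
#' PIF = 1 - E1[RR(X)] / E0[RR(X)], where E0 integrates over the baseline
#' log-normal BMI density, E1 over the same density translated by
#' `bmi_shift` on the natural scale (sigma preserved), and
#' RR(x) = rr^max(0, x - tmrel). Composite-trapezoid integration on at
#' least 2001 nodes over `support`, with a node placed exactly at the
#' TMREL kink. Negative PIFs (harmful shifts) are returned unchanged.
#'
#' @param bmi_mu,bmi_sigma log-scale parameters of the baseline BMI
#'   distribution.
#' @param bmi_shift signed shift of the BMI distribution (kg/m^2).
#' @param rr_point relative risk per BMI unit above `tmrel` (> 0).
#' @param tmrel theoretical minimum risk exposure level (kg/m^2).
#' @param n_nodes number of integration nodes (>= 2001 recommended).
#' @param support integration support, default `c(10, 60)` kg/m^2; shifted
#'   distributions are clamped to it and an error is raised if material
#'   probability mass leaves the grid.
#' @return scalar PIF (<= 1).
#' @export
#' @examples
#' pif_distribution_shift(log(25), 0.15, -1, rr_point = 1.1, tmrel = 0)
pif_distribution_shift <- function(bmi_mu, bmi_sigma, bmi_shift, rr_point,
                                   tmrel, n_nodes = 2001,
                                   support = c(10, 60)) {
  x <- pif_grid(support, n_nodes, tmrel)
  f0 <- stats::dlnorm(x, bmi_mu, bmi_sigma)
  f1 <- stats::dlnorm(x - bmi_shift, bmi_mu, bmi_sigma)
  m0 <- trapz(x, f0); m1 <- trapz(x, f1)
  if (m0 < 1 - 1e-3 || m1 < 1 - 1e-3)
    stop("BMI distribution mass falls outside the integration grid ",
         "(shift too large for the support)", call. = FALSE)
  rrv <- rr_point^pmax(0, x - tmrel)
  # expectations normalised by the (near-unit) numerical masses
  1 - (trapz(x, rrv * f1) / m1) / (trapz(x, rrv * f0) / m0)
}

#' Potential impact fraction by the relative-risk-shift method (activity)
#'
#' PIF = (sum p0 RR - sum p1 RR) / (sum p0 RR) for baseline and shifted
#' category prevalence vectors `p0`, `p1` and a categorical RR vector with
#' reference category RR = 1.
#'
#' @param p0,p1 prevalence vectors over the ordered activity bands, each
#'   summing to 1.
#' @param rr_vector positive RRs, one per band.
#' @return scalar PIF (negative when the shift is harmful).
#' @export
#' @examples
#' pif_rr_shift(c(0.2, 0.8), c(0.1, 0.9), c(1.5, 1.0))
pif_rr_shift <- function(p0, p1, rr_vector) {
  if (length(p0) != length(p1) || length(p0) != length(rr_vector))
    stop("p0, p1 and rr_vector must have equal length", call. = FALSE)
  if (abs(sum(p0) - 1) > 1e-9 || abs(sum(p1) - 1) > 1e-9)
    stop("prevalence vectors must sum to 1", call. = FALSE)
  if (any(rr_vector <= 0)) stop("RRs must be > 0", call. = FALSE)
  e0 <- sum(p0 * rr_vector)
  (e0 - sum(p1 * rr_vector)) / e0
}

#' Combine two potential impact fractions multiplicatively
#'
#' `1 - (1 - pif_a)(1 - pif_b)`: the joint effect of two risk factors on
#' the same disease under multiplicative RR adjustment. Commutative and
#' associative, with 0 as the identity.
#'
#' @param pif_a,pif_b PIFs (<= 1).
#' @return combined PIF.
#' @export
combine_pifs <- function(pif_a, pif_b) {
  1 - (1 - pif_a) * (1 - pif_b)
}

#' Potential impact fractions for an intervention
#'
#' Routes the BMI shifts of a [build_risk_deltas()] result through the
#' distribution-shift PIF for every BMI-related disease and the
#' activity-band shifts through the RR-shift PIF for every
#' activity-related disease, combining multiplicatively where a disease is
#' related to both. Zero-shift stratum-years give PIF 0. Results are
#' cached over the distinct shift values of each stratum, so sustained
#' effects cost one integration per stratum and disease.
#'
#' @param deltas a `risk_factor_delta` from [build_risk_deltas()].
#' @param bundle a validated `pmslt_bundle` (uses `population`, `diseases`,
#'   `rr`).
#' @param n_nodes,support integration controls, see
#'   [pif_distribution_shift()].
#' @param quad optional precomputed quadrature cache (internal reuse by
#'   the Monte Carlo machinery).
#' @return 3-d array `pif[stratum, disease, year]` with disease names on
#'   the second dimension.
#' @export
pifs_for_intervention <- function(deltas, bundle, n_nodes = 2001,
                                  support = c(10, 60), quad = NULL) {
  pop <- bundle$population
  dis <- bundle$diseases
  n <- nrow(pop); nd <- nrow(dis); ny <- length(deltas$years)
  pif <- array(0, dim = c(n, nd, ny),
               dimnames = list(NULL, dis$disease_id, NULL))

  rr_bmi <- bundle$rr[bundle$rr$risk_factor == "bmi", ]
  rrp <- rr_bmi$rr[match(dis$disease_id, rr_bmi$disease_id)]
  tmrel <- rr_bmi$tmrel[match(dis$disease_id, rr_bmi$disease_id)]
  bands <- grep("^pa_", names(pop), value = TRUE)
  band_names <- sub("^pa_", "", bands)
  rr_pa <- bundle$rr[bundle$rr$risk_factor == "pa", ]
  pa_dis <- which(dis$pa_related)

  # BMI path, vectorised: trapezoid quadrature as matrix products over a
  # shared grid (nodes at every TMREL), one density row per distinct
  # (stratum, shift) pair, densities for the baseline strata cached
  if (is.null(quad))
    quad <- pif_quad_cache(pop, stats::na.omit(unique(tmrel)), n_nodes,
                           support)
  x <- quad$x
  rrv <- matrix(1, length(x), nd)
  for (d in seq_len(nd))
    if (!is.na(rrp[d])) rrv[, d] <- rrp[d]^pmax(0, x - tmrel[d])
  E0 <- (quad$F0w %*% rrv) / quad$m0

  ps <- psh <- numeric(0)
  pyrs <- list()
  groups <- NULL
  if (!is.null(deltas$base_eff) && !is.null(deltas$scale_by_year)) {
    # deltas factorise as base_eff[s] * scale[y]: one density pass per
    # stratum and distinct maintenance scale, block-assigned per scale
    nz <- which(deltas$base_eff != 0)
    groups <- list()
    for (u in unique(deltas$scale_by_year[deltas$scale_by_year != 0])) {
      yrs <- which(deltas$scale_by_year == u)
      groups[[length(groups) + 1]] <-
        list(rows = length(ps) + seq_along(nz), strata = nz, yrs = yrs)
      ps <- c(ps, nz)
      psh <- c(psh, deltas$base_eff[nz] * u)
    }
  } else {
    for (s in seq_len(n)) {
      shifts <- deltas$bmi_shift[s, ]
      for (sh in unique(shifts[shifts != 0])) {
        ps <- c(ps, s); psh <- c(psh, sh)
        pyrs[[length(ps)]] <- which(shifts == sh)
      }
    }
  }
  if (length(ps)) {
    np <- length(ps)
    if (any(abs(psh) > diff(support) / 4) || any(quad$m0[ps] < 1 - 1e-3))
      stop("BMI distribution mass falls outside the integration grid ",
           "(shift too large for the support)", call. = FALSE)
    rrv_full <- matrix(1, length(x), nd)
    for (d in seq_len(nd))
      if (!is.na(rrp[d])) rrv_full[, d] <- rrp[d]^(x - tmrel[d])
    M1full <- quad$F0w[ps, , drop = FALSE] %*% rrv_full
    E1 <- .pif_e1_core(x, quad$tF0w, quad$cumF0wT, quad$m0,
                       as.integer(ps - 1L), psh, rrv_full, M1full,
                       ifelse(is.na(rrp), NA_real_, rrp),
                       ifelse(is.na(tmrel), 0, tmrel))
    pifp <- 1 - E1 / E0[ps, , drop = FALSE]
    pifp[, is.na(rrp)] <- 0
    if (!is.null(groups)) {
      for (g in groups)
        pif[g$strata, , g$yrs] <-
          array(pifp[g$rows, ], c(length(g$strata), nd, length(g$yrs)))
    } else {
      for (k in seq_len(np))
        pif[ps[k], , pyrs[[k]]] <- pifp[k, ]
    }
  }

  # activity path for the activity-related diseases, vectorised over the
  # target strata (the band shift fraction factorises like the BMI path)
  if (length(pa_dis) && any(deltas$pa_frac != 0)) {
    rr_list <- lapply(pa_dis, function(d) {
      rrd <- rr_pa[rr_pa$disease_id == dis$disease_id[d], ]
      rrd$rr[match(band_names, rrd$category)]
    })
    P0all <- as.matrix(pop[bands])
    K <- ncol(P0all)
    fr_mat <- deltas$pa_frac
    for (fr in unique(fr_mat[fr_mat != 0])) {
      hit <- fr_mat == fr
      strata <- which(rowSums(hit) > 0)
      yrs <- which(colSums(hit[strata, , drop = FALSE]) > 0)
      if (!all(hit[strata, yrs])) {
        # non-rectangular coincidence of fraction values: assign per cell
        for (s in strata) for (y in which(hit[s, ])) {
          p1s <- shift_pa_prevalence(P0all[s, ], fr)
          for (k in seq_along(pa_dis)) {
            d <- pa_dis[k]
            ppa <- pif_rr_shift(P0all[s, ], p1s, rr_list[[k]])
            pif[s, d, y] <- combine_pifs(pif[s, d, y], ppa)
          }
        }
        next
      }
      P0 <- P0all[strata, , drop = FALSE]
      moved <- P0 * fr
      P1 <- P0 - moved
      P1[, 2:K] <- P1[, 2:K] + moved[, 1:(K - 1), drop = FALSE]
      P1[, K] <- P1[, K] + moved[, K]
      for (k in seq_along(pa_dis)) {
        d <- pa_dis[k]
        e0 <- as.vector(P0 %*% rr_list[[k]])
        p_pa <- (e0 - as.vector(P1 %*% rr_list[[k]])) / e0
        cur <- pif[strata, d, yrs]
        pif[strata, d, yrs] <- 1 - (1 - cur) * (1 - p_pa)
      }
    }
  }
  pif
}

#' Convert a PIF array to a long data.frame
#'
#' @param pif array from [pifs_for_intervention()].
#' @param population the population table the array was built against.
#' @return data.frame with columns `disease`, `age`, `sex`, `year`, `pif`.
#' @export
pif_table_to_df <- function(pif, population) {
  dn <- dim(pif)
  df <- expand.grid(stratum = seq_len(dn[1]),
                    disease = dimnames(pif)[[2]],
                    year = seq_len(dn[3]) - 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$age <- population$age[df$stratum]
  df$sex <- population$sex[df$stratum]
  df$pif <- as.vector(pif)
  df[, c("disease", "age", "sex", "year", "pif")]
}
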