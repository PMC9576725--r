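#' Viability signal per cell
#'
#' The well-level viability fluorescence divided by the well's cell count, a
#' proxy for the per-cell metabolic (resistance) state of the surviving
#' cells. Vectorized; missing values propagate. A zero count leaves the
#' ratio undefined: it is returned as \code{NA} with a warning rather than
#' as \code{Inf}.
#'
#' @param viability Numeric vector, fluorescence (arbitrary units).
#' @param count Numeric vector, cells per well.
#' @return Numeric vector of per-cell viability (a.u. per cell).
#' @examples
#' viabilityPerCell(1000, 500)
#' @export
viabilityPerCell <- function(viability, count) {
  n <- max(length(viability), length(count))
  viability <- rep_len(viability, n)
  count <- rep_len(count, n)
  zero <- !is.na(count) & count == 0
  if (any(zero)) {
    warning(sprintf("viability per cell undefined for %d well(s) with zero count; returned NA",
                    sum(zero)), call. = FALSE)
  }
  out <- viability / count
  out[zero] <- NA_real_
  out
}

#' Percent growth inhibition
#'
#' \deqn{\%GI = \frac{count(treatment, 96h) - count(0h)}
#'                   {count(control, 96h) - count(0h)} \times 100}
#' Treatment identical to control gives 100; no net growth under treatment
#' gives 0; net kill below seeding is negative. The measure is invariant
#' under a common rescaling of all three counts.
#'
#' @param count0h Cell count at time zero.
#' @param countTreat96h Cell count after 96 h under treatment.
#' @param countCtrl96h Cell count after 96 h in the control.
#' @return Percent growth inhibition (vectorized).
#' @examples
#' percentGrowthInhibition(400, 800, 1600)
#' @export
percentGrowthInhibition <- function(count0h, countTreat96h, countCtrl96h) {
  denom <- countCtrl96h - count0h
  if (any(!is.na(denom) & denom == 0)) {
    stop("percent growth inhibition undefined: control count equals the 0 h count",
         call. = FALSE)
  }
  (countTreat96h - count0h) / denom * 100
}

#' Additive expectation for a combination treatment
#'
#' The expected combined change under no interaction: the sum of the two
#' single-treatment changes (cisplatin alone and siRNA alone). Both deltas
#' must be on the same scale (e.g. percent-of-control change); mixing scales
#' is not detectable and is the caller's contract.
#'
#' @param deltaCisplatinAlone,deltaSirnaAlone Single-treatment changes.
#' @return Their sum.
#' @export
additiveExpectation <- function(deltaCisplatinAlone, deltaSirnaAlone) {
  deltaCisplatinAlone + deltaSirnaAlone
}

#' Flag synergy against the additive expectation
#'
#' TRUE iff the observed combined decrease strictly exceeds the additive
#' expectation by more than \code{tolerance} (i.e. \code{observed <
#' expected - tolerance}). An observed change exactly at the expectation is
#' not synergy.
#'
#' @param observedCombinedChange Observed change under the combination.
#' @param additiveExpected Additive expectation (same scale).
#' @param tolerance Nonnegative slack, default 0.
#' @return Logical (vectorized).
#' @examples
#' synergyFlag(-60, additiveExpectation(-30, -20))
#' @export
synergyFlag <- function(observedCombinedChange, additiveExpected,
                        tolerance = 0) {
  stopifnot(all(tolerance >= 0))
  observedCombinedChange < additiveExpected - tolerance
}

#' Self-renewal synergy assessment from a four-condition assay
#'
#' Consumes regrowth cell counts of surviving cells reseeded after
#' treatment, across seeding densities, under the four conditions
#' \code{siNC-DMF}, \code{siNC-cisplatin}, \code{siGPCR-DMF} and
#' \code{siGPCR-cisplatin}. Counts are first expressed as a percentage of
#' the \code{siNC-DMF} condition within each seeding density; changes are
#' percent-of-control minus 100. The additive expectation is the sum of the
#' cisplatin-alone and siRNA-alone changes; the combination is flagged
#' synergistic when its observed change falls below that expectation by more
#' than \code{tolerance} (default: the replicate standard error of the
#' combined condition).
#'
#' @param df data.frame with columns \code{condition},
#'   \code{seeding_density}, \code{final_count} (one row per replicate).
#' @param tolerance Synergy slack on the percent scale; \code{NULL} (default)
#'   uses the standard error of the combined condition's percent values
#'   within each density (0 when there is a single replicate).
#' @return data.frame per seeding density: per-condition percent of control,
#'   single-treatment changes, observed combined change, additive
#'   expectation and \code{synergy} flag; plus a cross-density summary row
#'   (\code{seeding_density = NA}) averaging the per-density values.
#' @importFrom stats sd
#' @export
selfRenewalSynergy <- function(df, tolerance = NULL) {
  conds <- c("siNC-DMF", "siNC-cisplatin", "siGPCR-DMF", "siGPCR-cisplatin")
  miss <- setdiff(conds, unique(df$condition))
  if (length(miss)) {
    stop("self-renewal table is missing condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- lapply(sort(unique(df$seeding_density)), function(d) {
    sub <- df[df$seeding_density == d, ]
    ctrl <- mean(sub$final_count[sub$condition == "siNC-DMF"])
    pct <- vapply(conds, function(cc)
      mean(sub$final_count[sub$condition == cc]) / ctrl * 100, numeric(1))
    combPct <- sub$final_count[sub$condition == "siGPCR-cisplatin"] / ctrl * 100
    tol <- if (is.null(tolerance)) {
      if (length(combPct) >= 2) sd(combPct) / sqrt(length(combPct)) else 0
    } else tolerance
    dCis <- pct["siNC-cisplatin"] - 100
    dSi <- pct["siGPCR-DMF"] - 100
    obs <- pct["siGPCR-cisplatin"] - 100
    expd <- additiveExpectation(dCis, dSi)
    data.frame(seeding_density = d,
               pct_siNC_DMF = pct["siNC-DMF"],
               pct_siNC_cisplatin = pct["siNC-cisplatin"],
               pct_siGPCR_DMF = pct["siGPCR-DMF"],
               pct_siGPCR_cisplatin = pct["siGPCR-cisplatin"],
               delta_cisplatin = dCis, delta_sirna = dSi,
               observed_combined = obs, additive_expected = expd,
               tolerance = tol,
               synergy = synergyFlag(obs, expd, tol),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  summary <- res[1, ]
  summary$seeding_density <- NA
  for (cn in setdiff(names(res), c("seeding_density", "synergy"))) {
    summary[[cn]] <- mean(res[[cn]])
  }
  summary$synergy <- synergyFlag(summary$observed_combined,
                                 summary$additive_expected, summary$tolerance)
  rbind(res, summary)
}

#' Contrast siRNA effects on fresh vs cisplatin-pretreated cells
#'
#' Difference of mean effects (percent-of-siNC scale) between
#' cisplatin-pretreated and fresh cells for one gene, with a two-sided
#' two-sample Student t-test. A negative difference means the knockdown
#' inhibits pretreated cells more strongly. With fewer than two replicates
#' in either context the p-value is missing.
#'
#' @param fresh Numeric replicate values on fresh cells.
#' @param pretreated Numeric replicate values on pretreated cells.
#' @param varEqual Pooled variance (default TRUE).
#' @return list with \code{difference} (pretreated - fresh), \code{p_value},
#'   \code{n_fresh}, \code{n_pretreated}.
#' @importFrom stats t.test
#' @export
serialTreatmentContrast <- function(fresh, pretreated, varEqual = TRUE) {
  fresh <- fresh[!is.na(fresh)]
  pretreated <- pretreated[!is.na(pretreated)]
  diff <- mean(pretreated) - mean(fresh)
  p <- if (length(fresh) >= 2 && length(pretreated) >= 2) {
    t.test(pretreated, fresh, var.equal = varEqual)$p.value
  } else NA_real_
  list(difference = diff, p_value = p, n_fresh = length(fresh),
       n_pretreated = length(pretreated))
}
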