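#' z'-factor from control-well statistics
#'
#' The screening-window statistic computed from the means and standard
#' deviations of the positive (siPLK1) and negative (siNC) control wells of
#' one plate and readout. Two variants are provided:
#' \describe{
#'   \item{\code{standard}}{\eqn{1 - 3(sd_{pos} + sd_{neg}) / |avg_{pos} -
#'     avg_{neg}|}, the canonical Zhang screening-window coefficient
#'     (default).}
#'   \item{\code{as-printed}}{\eqn{1 - 3(sd_{pos} - sd_{neg}) / |avg_{pos} -
#'     avg_{neg}|}, with the SDs subtracted. Kept reproducible behind this
#'     flag; note it returns 1 for equally noisy controls, which contradicts
#'     the canonical definition, so \code{standard} is the default.}
#' }
#' Ranges over \eqn{(-\infty, 1]}; values above 0.5 indicate an excellent
#' assay window, values above 0 a borderline one.
#'
#' @param avgPos,sdPos Mean and sample SD of the positive-control wells.
#' @param avgNeg,sdNeg Mean and sample SD of the negative-control wells.
#' @param variant \code{"standard"} or \code{"as-printed"}.
#' @return The z'-factor, a real number \eqn{\le 1}.
#' @examples
#' computeZPrime(avgPos = 2, sdPos = 1, avgNeg = 11, sdNeg = 1)
#' @export
computeZPrime <- function(avgPos, sdPos, avgNeg, sdNeg,
                          variant = c("standard", "as-printed")) {
  variant <- match.arg(variant)
  stopifnot(sdPos >= 0, sdNeg >= 0)
  sep <- abs(avgPos - avgNeg)
  if (isTRUE(all.equal(sep, 0)) || sep == 0) {
    stop("z'-factor undefined: positive and negative control means coincide",
         call. = FALSE)
  }
  spread <- if (variant == "standard") sdPos + sdNeg else sdPos - sdNeg
  1 - 3 * spread / sep
}

#' Classify assay quality from a z'-factor
#'
#' Strict thresholds: z' > \code{excellent} is \code{EXCELLENT},
#' \code{borderline} < z' <= \code{excellent} is \code{BORDERLINE}, anything
#' at or below \code{borderline} is \code{FAIL}.
#'
#' @param zPrime Numeric vector of z'-factors (finite).
#' @param excellent,borderline Thresholds (defaults 0.5 and 0).
#' @return Character vector: \code{EXCELLENT}, \code{BORDERLINE} or
#'   \code{FAIL}.
#' @export
classifyAssayQuality <- function(zPrime, excellent = 0.5, borderline = 0) {
  if (any(!is.finite(zPrime))) {
    stop("z'-factor must be finite for quality classification", call. = FALSE)
  }
  ifelse(zPrime > excellent, "EXCELLENT",
         ifelse(zPrime > borderline, "BORDERLINE", "FAIL"))
}

# Control statistics per plate instance (plate x batch x arm) and readout,
# computed on raw values. Errors if a control class has < 2 wells.
controlStats <- function(x) {
  w <- wells(x)
  keys <- unique(w[, c("plate", "batch", "co_treatment")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- w[w$plate == keys$plate[i] & w$batch == keys$batch[i] &
               w$co_treatment == keys$co_treatment[i], ]
    for (readout in c("COUNT", "VIABILITY")) {
      colname <- if (readout == "COUNT") "count" else "viability"
      pos <- sub[[colname]][sub$perturbation == "PLK1"]
      neg <- sub[[colname]][sub$perturbation == "NC"]
      pos <- pos[!is.na(pos)]
      neg <- neg[!is.na(neg)]
      if (length(pos) < 2 || length(neg) < 2) {
        stop(sprintf(
          "plate %s batch %s arm %s: need >= 2 siPLK1 and >= 2 siNC wells (have %d/%d)",
          keys$plate[i], keys$batch[i], keys$co_treatment[i],
          length(pos), length(neg)), call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        plate = keys$plate[i], batch = keys$batch[i],
        co_treatment = keys$co_treatment[i], readout = readout,
        avg_pos = mean(pos), sd_pos = stats::sd(pos),
        avg_neg = mean(neg), sd_neg = stats::sd(neg),
        n_pos = length(pos), n_neg = length(neg),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-plate z'-factor quality-control report
#'
#' Computes, for every plate instance (plate x batch x co-treatment arm) and
#' each readout (cell count, viability), the z'-factor from the raw (not
#' normalized) siPLK1 and siNC control wells of that instance, and classifies
#' assay quality. Control statistics use the sample (n-1) standard deviation.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param variant z'-factor variant, see \code{\link{computeZPrime}}.
#' @param excellent,borderline Quality thresholds.
#' @return data.frame with columns \code{plate}, \code{batch},
#'   \code{co_treatment}, \code{readout}, \code{z_prime}, \code{quality}.
#' @examples
#' qcReport(generateScreen(screenPreset("tiny")))
#' @export
setGeneric("qcReport", function(x, variant = c("standard", "as-printed"),
                                excellent = 0.5, borderline = 0)
  standardGeneric("qcReport"))

#' @rdname qcReport
#' @export
setMethod("qcReport", "ScreenExperiment",
          function(x, variant = c("standard", "as-printed"),
                   excellent = 0.5, borderline = 0) {
  variant <- match.arg(variant)
  cs <- controlStats(x)
  cs$z_prime <- mapply(computeZPrime, cs$avg_pos, cs$sd_pos, cs$avg_neg,
                       cs$sd_neg, MoreArgs = list(variant = variant))
  cs$quality <- classifyAssayQuality(cs$z_prime, excellent, borderline)
  cs[, c("plate", "batch", "co_treatment", "readout", "z_prime", "quality")]
})
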