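#' Per-plate log2 normalization against negative controls
#'
#' Converts raw readout values of one plate instance and arm to log2 ratios
#' over the center of the plate's siNC (non-targeting control) wells:
#' \code{log2(raw / center(siNC))}. Negative values indicate fewer cells (or
#' less signal) than the negative controls. The center is the median of the
#' siNC wells by default (robust to a single bad control well); the mean is
#' available.
#'
#' Missing values propagate as missing; if every siNC value is missing the
#' whole output is missing, without an error. Zero or negative raw values are
#' an error because they have no log2 image.
#'
#' @param values Numeric vector of raw readout values for the plate's wells.
#' @param ncValues Numeric vector of raw siNC values from the same plate
#'   instance and arm.
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return Numeric vector of log2 ratios, same length as \code{values}.
#' @examples
#' normalizePlate(c(100, 25, 400), ncValues = c(100, 100))
#' @export
normalizePlate <- function(values, ncValues, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(ncValues) == 0) {
    stop("no siNC wells available for normalization", call. = FALSE)
  }
  if (any(!is.na(values) & values <= 0) || any(!is.na(ncValues) & ncValues <= 0)) {
    stop("raw readout values must be strictly positive for log2 normalization",
         call. = FALSE)
  }
  ctr <- ncCenter(ncValues, center)
  if (is.na(ctr) && !all(is.na(ncValues))) {
    stop("no usable siNC values for normalization", call. = FALSE)
  }
  log2(values / ctr)
}

# Normalize both readouts of every well, per plate instance (plate x batch x
# co-treatment arm), against the siNC wells of the same instance. Empty
# wells stay missing. Returns the well table plus norm_count/norm_viability.
#' Normalize a whole screen against per-plate siNC controls
#'
#' Applies \code{\link{normalizePlate}} to both readouts of every plate
#' instance of the screen. Each well is normalized against the siNC wells of
#' its own plate, batch and co-treatment arm, so plate- and batch-level
#' shifts cancel and the combined arm isolates the siRNA effect on top of
#' cisplatin.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param center siNC center, \code{"median"} (default) or \code{"mean"}.
#' @return The well table with added columns \code{norm_count} and
#'   \code{norm_viability} (log2 ratios to the plate siNC center).
#' @export
normalizeScreen <- function(x, center = c("median", "mean")) {
  center <- match.arg(center)
  w <- wells(x)
  key <- paste(w$plate, w$batch, w$co_treatment, sep = "\r")
  w$norm_count <- NA_real_
  w$norm_viability <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    nc <- idx[w$perturbation[idx] == "NC"]
    w$norm_count[idx] <- normalizePlate(w$count[idx], w$count[nc], center)
    w$norm_viability[idx] <- normalizePlate(w$viability[idx],
                                            w$viability[nc], center)
  }
  w
}

#' Replicate aggregation and significance for one gene
#'
#' Summarizes a gene's per-batch normalized values in one arm into a mean
#' log2 fold change and a two-sided independent two-sample Student t-test
#' p-value against the same-arm siNC normalized well values (pooled variance
#' by default; Welch behind \code{varEqual = FALSE}; a one-sample test
#' against zero behind \code{against = "zero"}).
#'
#' With fewer than two replicate values the effect is still reported but the
#' p-value is missing.
#'
#' @param geneValues Numeric vector, the gene's per-batch normalized values.
#' @param ncValues Numeric vector of normalized siNC well values (ignored for
#'   \code{against = "zero"}).
#' @param varEqual Pooled-variance Student test if TRUE (default).
#' @param against \code{"nc"} (default) or \code{"zero"}.
#' @return list with \code{log2fc}, \code{p}, \code{n_reps}.
#' @importFrom stats t.test
#' @export
aggregateGene <- function(geneValues, ncValues, varEqual = TRUE,
                          against = c("nc", "zero")) {
  against <- match.arg(against)
  geneValues <- geneValues[!is.na(geneValues)]
  ncValues <- ncValues[!is.na(ncValues)]
  fc <- if (length(geneValues)) mean(geneValues) else NA_real_
  p <- NA_real_
  if (length(geneValues) >= 2) {
    p <- tryCatch({
      if (against == "zero") {
        t.test(geneValues, mu = 0)$p.value
      } else if (length(ncValues) >= 2) {
        t.test(geneValues, ncValues, var.equal = varEqual)$p.value
      } else NA_real_
    }, error = function(e) NA_real_)
  }
  list(log2fc = fc, p = p, n_reps = length(geneValues))
}

#' Per-gene, per-arm replicate-aggregated effects
#'
#' Normalizes the screen (\code{\link{normalizeScreen}}) and aggregates each
#' gene's replicate values across batches within each co-treatment arm, for
#' both readouts. The t-test reference set is the normalized siNC well
#' values of the gene's own plate across batches in the same arm.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param center siNC center for normalization.
#' @param varEqual,against Passed to \code{\link{aggregateGene}}.
#' @return data.frame with one row per gene x arm: \code{gene}, \code{arm}
#'   (SINGLE for vehicle, COMBINED for cisplatin), \code{log2fc_count},
#'   \code{p_count}, \code{log2fc_viability}, \code{p_viability},
#'   \code{n_reps}.
#' @examples
#' eff <- geneEffects(generateScreen(screenPreset("tiny")))
#' head(eff)
#' @export
geneEffects <- function(x, center = c("median", "mean"), varEqual = TRUE,
                        against = c("nc", "zero")) {
  center <- match.arg(center)
  against <- match.arg(against)
  nw <- normalizeScreen(x, center)
  genes <- setdiff(unique(nw$perturbation), PERTURBATION_RESERVED)
  armOf <- c(VEHICLE = "SINGLE", CISPLATIN = "COMBINED")
  out <- vector("list", length(genes) * 2L)
  k <- 0L
  for (arm in ARMS) {
    sub <- nw[nw$co_treatment == arm, ]
    ncByPlate <- split(sub[sub$perturbation == "NC",
                           c("norm_count", "norm_viability")],
                       sub$plate[sub$perturbation == "NC"])
    gidx <- split(seq_len(nrow(sub)), sub$perturbation)
    for (g in genes) {
      k <- k + 1L
      rows <- sub[gidx[[g]], ]
      nc <- ncByPlate[[rows$plate[1]]]
      aggC <- aggregateGene(rows$norm_count, nc$norm_count, varEqual, against)
      aggV <- aggregateGene(rows$norm_viability, nc$norm_viability, varEqual,
                            against)
      out[[k]] <- data.frame(
        gene = g, arm = unname(armOf[arm]), log2fc_count = aggC$log2fc,
        p_count = aggC$p, log2fc_viability = aggV$log2fc,
        p_viability = aggV$p, n_reps = aggC$n_reps,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Call screen hits into categories
#'
#' Applies the replicate-level hit rules to a screen. A gene is significant
#' in an arm when its count-readout p-value is below \code{pThreshold} and
#' its count log2 fold change is at or below \code{-foldThreshold} (hits are
#' inhibitory only; growth-promoting genes are reported but never
#' categorized as hits). Categories:
#' \describe{
#'   \item{COMMON}{significant in both the single and the
#'     cisplatin-combined arm.}
#'   \item{CISPLATIN_SENSITIZED}{significant in the combined arm (only), and
#'     the combined-vs-single contrast on per-batch normalized count values
#'     (two-sample Student t-test) has p below \code{pThreshold} with the
#'     combined mean more inhibitory than the single mean.}
#'   \item{SINGLE_ONLY / COMBINED_ONLY}{significant in exactly that arm,
#'     without the sensitization contrast.}
#'   \item{NONE}{otherwise.}
#' }
#' The sensitization contrast p-value and flag are reported for every gene.
#' P-values are raw (no multiple-testing correction): the screen's selection
#' rule is a fixed raw threshold, and this is deliberately reproduced.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param pThreshold Raw p-value threshold (default 0.01).
#' @param foldThreshold Inhibition threshold in log2 units (default 1,
#'   i.e. a twofold count decrease).
#' @param center,varEqual Passed to normalization/aggregation.
#' @return data.frame with one row per gene: per-arm effects and p-values
#'   (count readout), \code{sensitization_p}, \code{sensitized},
#'   \code{category}.
#' @examples
#' cfg <- screenPreset("tiny",
#'   plantedEffects = list(GENE1 = c(-1.5, -1.6)), nBatches = 3)
#' hits <- callHits(generateScreen(cfg))
#' table(hits$category)
#' @export
setGeneric("callHits", function(x, pThreshold = 0.01, foldThreshold = 1,
                                center = c("median", "mean"), varEqual = TRUE)
  standardGeneric("callHits"))

#' @rdname callHits
#' @export
setMethod("callHits", "ScreenExperiment",
          function(x, pThreshold = 0.01, foldThreshold = 1,
                   center = c("median", "mean"), varEqual = TRUE) {
  center <- match.arg(center)
  nw <- normalizeScreen(x, center)
  genes <- setdiff(unique(nw$perturbation), PERTURBATION_RESERVED)
  eff <- geneEffects(x, center, varEqual)
  effS <- eff[eff$arm == "SINGLE", ]
  effC <- eff[eff$arm == "COMBINED", ]
  rownames(effS) <- effS$gene
  rownames(effC) <- effC$gene

  byGeneArm <- split(nw$norm_count,
                     list(nw$perturbation, nw$co_treatment), drop = FALSE)
  out <- data.frame(
    gene = genes,
    log2fc_count_single = effS[genes, "log2fc_count"],
    p_count_single = effS[genes, "p_count"],
    log2fc_count_combined = effC[genes, "log2fc_count"],
    p_count_combined = effC[genes, "p_count"],
    log2fc_viability_single = effS[genes, "log2fc_viability"],
    log2fc_viability_combined = effC[genes, "log2fc_viability"],
    stringsAsFactors = FALSE)

  sigArm <- function(p, fc) !is.na(p) & !is.na(fc) &
    p < pThreshold & fc <= -foldThreshold
  out$single_significant <- sigArm(out$p_count_single, out$log2fc_count_single)
  out$combined_significant <- sigArm(out$p_count_combined,
                                     out$log2fc_count_combined)

  sens <- vapply(genes, function(g) {
    s <- byGeneArm[[paste(g, "VEHICLE", sep = ".")]]
    cb <- byGeneArm[[paste(g, "CISPLATIN", sep = ".")]]
    s <- s[!is.na(s)]; cb <- cb[!is.na(cb)]
    if (length(s) < 2 || length(cb) < 2) return(c(NA_real_, NA_real_))
    c(t.test(cb, s, var.equal = varEqual)$p.value, mean(cb) - mean(s))
  }, numeric(2))
  out$sensitization_p <- sens[1, ]
  out$sensitized <- !is.na(out$sensitization_p) &
    out$sensitization_p < pThreshold & sens[2, ] < 0

  out$category <- ifelse(
    out$single_significant & out$combined_significant, "COMMON",
    ifelse(out$combined_significant & out$sensitized, "CISPLATIN_SENSITIZED",
    ifelse(out$combined_significant, "COMBINED_ONLY",
    ifelse(out$single_significant, "SINGLE_ONLY", "NONE"))))
  rownames(out) <- NULL
  out
})
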