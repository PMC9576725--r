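#' Simulation settings for a dual-readout RNAi screen
#'
#' Defines the plate-format screen emulated by \code{\link{generateScreen}}:
#' 384-well plates (16 rows x 24 columns) carrying non-targeting negative
#' controls (siNC), strong positive controls (siPLK1), library gene wells and
#' trailing empty wells; three independent screening repeats (batches); and
#' two co-treatment arms (vehicle and cisplatin). Well counts follow a
#' lognormal model around a plate baseline on the log2 scale, which matches
#' the log2-ratio analysis model and keeps noiseless runs exactly invertible.
#'
#' @slot nGenes integer, number of library genes (one well per gene per
#'   plate-instance).
#' @slot nBatches integer, screening repeats (default 3).
#' @slot nNc,nPlk1 integer, control wells per plate (default 16 each).
#' @slot controlEffectPlk1 log2 count effect of the siPLK1 control
#'   (default -3, a strong kill).
#' @slot plantedEffects named list, gene -> c(single, combined) log2 count
#'   effects; genes absent from the list are null.
#' @slot countNoiseCv,viabilityNoiseCv coefficients of variation of the two
#'   readouts (natural scale; 0 allowed for noiseless oracles).
#' @slot batchShiftSd SD of the per plate-instance log2 shift emulating
#'   batch/plate handling effects.
#' @slot cisplatinShift global log2 count effect of the cisplatin arm applied
#'   to every well including controls (default -1).
#' @slot resistanceGain slope linking count decrease to per-cell viability
#'   increase (log2 per log2), emulating surviving-cell resistance.
#' @slot percellBase viability signal per cell, arbitrary units.
#' @slot baselineCount expected untreated cells per well at assay time
#'   (default 1600, i.e. 400 seeded cells over four days).
#' @slot countModel "lognormal" (default) or "nb" (negative binomial with the
#'   same CV).
#' @slot seed integer RNG seed; all generator randomness flows from it.
#' @export
setClass("ScreenSimConfig", representation(
  nGenes = "integer", nBatches = "integer", nNc = "integer", nPlk1 = "integer",
  controlEffectPlk1 = "numeric", plantedEffects = "list",
  countNoiseCv = "numeric", viabilityNoiseCv = "numeric",
  batchShiftSd = "numeric", cisplatinShift = "numeric",
  resistanceGain = "numeric", percellBase = "numeric",
  baselineCount = "numeric", countModel = "character", seed = "integer"))

setValidity("ScreenSimConfig", function(object) {
  msgs <- character()
  if (object@nGenes < 1) msgs <- c(msgs, "nGenes must be >= 1")
  if (object@nNc < 2 || object@nPlk1 < 2) {
    msgs <- c(msgs, "nNc and nPlk1 must be >= 2")
  }
  if (object@countNoiseCv < 0 || object@viabilityNoiseCv < 0) {
    msgs <- c(msgs, "noise CVs must be >= 0")
  }
  if (object@baselineCount <= 0) msgs <- c(msgs, "baselineCount must be > 0")
  if (!object@countModel %in% c("lognormal", "nb")) {
    msgs <- c(msgs, "countModel must be 'lognormal' or 'nb'")
  }
  bad <- vapply(object@plantedEffects, function(e) length(e) != 2, logical(1))
  if (any(bad)) msgs <- c(msgs, "plantedEffects entries must be c(single, combined)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScreenSimConfig-class
#' @param nGenes,nBatches,nNc,nPlk1,controlEffectPlk1,plantedEffects,countNoiseCv,viabilityNoiseCv,batchShiftSd,cisplatinShift,resistanceGain,percellBase,baselineCount,countModel,seed
#'   see the class slots.
#' @return A \code{ScreenSimConfig}.
#' @export
screenSimConfig <- function(nGenes = 390L, nBatches = 3L, nNc = 16L,
                            nPlk1 = 16L, controlEffectPlk1 = -3,
                            plantedEffects = list(), countNoiseCv = 0.10,
                            viabilityNoiseCv = 0.15, batchShiftSd = 0.1,
                            cisplatinShift = -1, resistanceGain = 0.5,
                            percellBase = 2, baselineCount = 1600,
                            countModel = "lognormal", seed = 1L) {
  methods::new("ScreenSimConfig", nGenes = as.integer(nGenes),
               nBatches = as.integer(nBatches), nNc = as.integer(nNc),
               nPlk1 = as.integer(nPlk1),
               controlEffectPlk1 = controlEffectPlk1,
               plantedEffects = plantedEffects, countNoiseCv = countNoiseCv,
               viabilityNoiseCv = viabilityNoiseCv,
               batchShiftSd = batchShiftSd, cisplatinShift = cisplatinShift,
               resistanceGain = resistanceGain, percellBase = percellBase,
               baselineCount = baselineCount, countModel = countModel,
               seed = as.integer(seed))
}

#' Preset screen configurations
#'
#' \code{"tiny"} (12 genes, one plate) runs in well under a second and is
#' meant for examples and smoke tests; \code{"paper-shaped"} matches the
#' scale of a 390-gene GPCR library screened in triplicate in both arms.
#'
#' @param preset "tiny" or "paper-shaped".
#' @param ... overrides passed to \code{\link{screenSimConfig}}.
#' @return A \linkS4class{ScreenSimConfig}.
#' @export
screenPreset <- function(preset = c("tiny", "paper-shaped"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 "tiny" = list(nGenes = 12L, nBatches = 2L, nNc = 4L,
                               nPlk1 = 4L),
                 "paper-shaped" = list(nGenes = 390L))
  args <- utils::modifyList(base, list(...))
  do.call(screenSimConfig, args)
}

# One plate layout: wells in column-major order; controls first, then genes,
# remainder EMPTY. Layout is fixed given (nNc, nPlk1, genes).
.plateLayout <- function(genes, nNc, nPlk1) {
  rows <- rep(LETTERS[1:16], times = 24)
  cols <- rep(1:24, each = 16)
  labels <- c(rep("NC", nNc), rep("PLK1", nPlk1), genes)
  if (length(labels) > 384) stop("more than 384 wells requested on one plate")
  labels <- c(labels, rep("EMPTY", 384 - length(labels)))
  data.frame(row = rows, col = cols, perturbation = labels,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dual-readout screen
#'
#' Simulates the full screen defined by a \linkS4class{ScreenSimConfig}:
#' every batch and both co-treatment arms. Counts are
#' \code{round(baseline * 2^(effect + armShift + plateShift + noise))};
#' viability is \code{count * percellBase * 2^(resistanceGain * max(0,
#' -effect) + noise)}, so wells whose perturbation kills cells show an
#' elevated per-cell viability signal, emulating the resistance phenotype of
#' surviving cells. Empty wells carry missing readouts. Deterministic for a
#' fixed seed.
#'
#' @param config A \linkS4class{ScreenSimConfig}.
#' @param seed Optional override of \code{config@seed}.
#' @return A \linkS4class{ScreenExperiment}.
#' @examples
#' se <- generateScreen(screenPreset("tiny"))
#' qcReport(se)
#' @importFrom stats rnorm rnbinom
#' @export
generateScreen <- function(config, seed = config@seed) {
  methods::validObject(config)
  genes <- paste0("GENE", seq_len(config@nGenes))
  genesPerPlate <- 384L - config@nNc - config@nPlk1
  nPlates <- ceiling(config@nGenes / genesPerPlate)
  plateGenes <- split(genes, ceiling(seq_along(genes) / genesPerPlate))

  sdCount <- cvToLog2Sd(config@countNoiseCv)
  sdViab <- cvToLog2Sd(config@viabilityNoiseCv)

  effectOf <- function(pert, arm) {
    slot <- if (arm == "CISPLATIN") 2L else 1L
    vapply(pert, function(p) {
      if (p == "PLK1") return(config@controlEffectPlk1)
      if (p %in% c("NC", "EMPTY")) return(0)
      e <- config@plantedEffects[[p]]
      if (is.null(e)) 0 else e[slot]
    }, numeric(1), USE.NAMES = FALSE)
  }

  withSeed(seed, {
    out <- vector("list", nPlates * config@nBatches * 2L)
    k <- 0L
    for (b in seq_len(config@nBatches)) {
      for (p in seq_len(nPlates)) {
        layout <- .plateLayout(plateGenes[[p]], config@nNc, config@nPlk1)
        for (arm in ARMS) {
          k <- k + 1L
          nW <- nrow(layout)
          plateShift <- rnorm(1, 0, config@batchShiftSd)
          armShift <- if (arm == "CISPLATIN") config@cisplatinShift else 0
          eff <- effectOf(layout$perturbation, arm)
          mu <- config@baselineCount *
            2^(eff + armShift + plateShift + rnorm(nW, 0, sdCount))
          count <- if (config@countModel == "lognormal") {
            round(mu)
          } else {
            size <- if (config@countNoiseCv > 0) 1 / config@countNoiseCv^2 else Inf
            rnbinom(nW, mu = config@baselineCount * 2^(eff + armShift + plateShift),
                    size = size)
          }
          viability <- count * config@percellBase *
            2^(config@resistanceGain * pmax(0, -eff) + rnorm(nW, 0, sdViab))
          empty <- layout$perturbation == "EMPTY"
          count[empty] <- NA
          viability[empty] <- NA
          out[[k]] <- data.frame(
            plate = sprintf("P%02d", p), batch = b, row = layout$row,
            col = layout$col, perturbation = layout$perturbation,
            co_treatment = arm, viability = viability, count = count,
            stringsAsFactors = FALSE)
        }
      }
    }
    ScreenExperiment(do.call(rbind, out))
  })
}

#' Simulation settings for a survival cohort
#'
#' Defines the cohort emulated by \code{\link{generateCohort}}: per-sample
#' gender and stage, a gene-by-sample log2(TPM+1) expression matrix in which
#' one focal gene follows a two-component (low/high) location-shift mixture,
#' somatic mutation sets, and exponential survival with a proportional-hazards
#' effect of high expression that can be confined to carriers of a mutation
#' gene set (an expression-by-mutation interaction).
#'
#' @slot nSamples integer.
#' @slot genes character, gene symbols in the expression matrix; the first is
#'   the focal gene carrying the planted expression-hazard effect.
#' @slot baselineHazard exponential event rate per day (default 1/730,
#'   a two-year median survival).
#' @slot hrHighExpression hazard ratio of the latent high-expression group.
#' @slot interactionGeneset character; mutation gene symbols defining carriers.
#' @slot hrInteraction extra hazard ratio for high expression among carriers.
#' @slot carrierFraction fraction of samples carrying >= 1 geneset mutation.
#' @slot censoringRate exponential censoring rate per day (default 1/1095,
#'   roughly three-year administrative follow-up).
#' @slot genderProbs,stageProbs named category probabilities (sum to 1).
#' @slot highFraction latent high-expression fraction (default 0.5).
#' @slot exprBase,exprShift,exprSd two-component expression model on the
#'   log2(TPM+1) scale: low component N(exprBase, exprSd), high component
#'   shifted up by exprShift.
#' @slot backgroundMutGenes,backgroundMutRate background mutations applied
#'   independently of the interaction geneset.
#' @slot recurrenceHazardFactor extra hazard of the recurrence process
#'   relative to death, so DFS events precede or coincide with OS events.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSimConfig", representation(
  nSamples = "integer", genes = "character", baselineHazard = "numeric",
  hrHighExpression = "numeric", interactionGeneset = "character",
  hrInteraction = "numeric", carrierFraction = "numeric",
  censoringRate = "numeric", genderProbs = "numeric", stageProbs = "numeric",
  highFraction = "numeric", exprBase = "numeric", exprShift = "numeric",
  exprSd = "numeric", backgroundMutGenes = "character",
  backgroundMutRate = "numeric", recurrenceHazardFactor = "numeric",
  seed = "integer"))

setValidity("CohortSimConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 1) msgs <- c(msgs, "nSamples must be >= 1")
  if (object@baselineHazard <= 0 || object@censoringRate <= 0) {
    msgs <- c(msgs, "rates must be > 0")
  }
  if (abs(sum(object@genderProbs) - 1) > 1e-8 ||
      abs(sum(object@stageProbs) - 1) > 1e-8) {
    msgs <- c(msgs, "category probabilities must sum to 1")
  }
  if (!identical(sort(names(object@genderProbs)), sort(GENDERS))) {
    msgs <- c(msgs, "genderProbs must be named FEMALE/MALE")
  }
  if (!identical(sort(names(object@stageProbs)), sort(STAGES))) {
    msgs <- c(msgs, "stageProbs must be named I/II/III/IV")
  }
  if (object@carrierFraction < 0 || object@carrierFraction > 1) {
    msgs <- c(msgs, "carrierFraction must be in [0,1]")
  }
  if (object@hrHighExpression <= 0 || object@hrInteraction <= 0) {
    msgs <- c(msgs, "hazard ratios must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname CohortSimConfig-class
#' @param nSamples,genes,baselineHazard,hrHighExpression,interactionGeneset,hrInteraction,carrierFraction,censoringRate,genderProbs,stageProbs,highFraction,exprBase,exprShift,exprSd,backgroundMutGenes,backgroundMutRate,recurrenceHazardFactor,seed
#'   see the class slots.
#' @return A \code{CohortSimConfig}.
#' @export
cohortSimConfig <- function(nSamples = 300L, genes = paste0("G", 1:5),
                            baselineHazard = 1 / 730, hrHighExpression = 1,
                            interactionGeneset = character(0),
                            hrInteraction = 1, carrierFraction = 0.25,
                            censoringRate = 1 / 1095,
                            genderProbs = c(FEMALE = 0.54, MALE = 0.46),
                            stageProbs = c(I = 0.53, II = 0.25, III = 0.17,
                                           IV = 0.05),
                            highFraction = 0.5, exprBase = 2, exprShift = 2,
                            exprSd = 1,
                            backgroundMutGenes = paste0("MUT", 1:8),
                            backgroundMutRate = 0.1,
                            recurrenceHazardFactor = 0.5, seed = 1L) {
  methods::new("CohortSimConfig", nSamples = as.integer(nSamples),
               genes = genes, baselineHazard = baselineHazard,
               hrHighExpression = hrHighExpression,
               interactionGeneset = interactionGeneset,
               hrInteraction = hrInteraction,
               carrierFraction = carrierFraction,
               censoringRate = censoringRate, genderProbs = genderProbs,
               stageProbs = stageProbs, highFraction = highFraction,
               exprBase = exprBase, exprShift = exprShift, exprSd = exprSd,
               backgroundMutGenes = backgroundMutGenes,
               backgroundMutRate = backgroundMutRate,
               recurrenceHazardFactor = recurrenceHazardFactor,
               seed = as.integer(seed))
}

#' Generate a synthetic survival cohort
#'
#' Draws gender, stage, expression, mutation sets and exponential survival
#' and censoring times per the \linkS4class{CohortSimConfig}. The per-sample
#' death hazard is \code{baselineHazard * hrHighExpression^high *
#' hrInteraction^(high & carrier)} where \code{high} is the latent
#' high-expression component of the focal gene. Recurrence is an independent
#' exponential process with rate \code{hazard * recurrenceHazardFactor}; the
#' DFS event time is the earlier of recurrence and death, so DFS events never
#' follow the OS event. Both endpoints share one censoring draw. Times are
#' rounded up to whole days. Deterministic for a fixed seed.
#'
#' @param config A \linkS4class{CohortSimConfig}.
#' @param seed Optional override of \code{config@seed}.
#' @return A \linkS4class{SurvivalCohort}.
#' @examples
#' coh <- generateCohort(cohortSimConfig(nSamples = 40))
#' head(clinicalData(coh))
#' @importFrom stats rexp rnorm runif rbinom
#' @export
generateCohort <- function(config, seed = config@seed) {
  methods::validObject(config)
  n <- config@nSamples
  withSeed(seed, {
    ids <- sprintf("S%04d", seq_len(n))
    gender <- sample(names(config@genderProbs), n, replace = TRUE,
                     prob = config@genderProbs)
    stage <- sample(names(config@stageProbs), n, replace = TRUE,
                    prob = config@stageProbs)
    high <- rbinom(n, 1, config@highFraction) == 1
    carrier <- rbinom(n, 1, config@carrierFraction) == 1
    if (length(config@interactionGeneset) == 0) carrier[] <- FALSE

    expr <- matrix(rnorm(length(config@genes) * n, config@exprBase,
                         config@exprSd),
                   nrow = length(config@genes), ncol = n,
                   dimnames = list(config@genes, ids))
    expr[1, ] <- expr[1, ] + config@exprShift * high
    expr[expr < 0] <- 0

    mutations <- lapply(seq_len(n), function(i) {
      mut <- config@backgroundMutGenes[
        runif(length(config@backgroundMutGenes)) < config@backgroundMutRate]
      if (carrier[i]) {
        gs <- config@interactionGeneset
        pick <- gs[runif(length(gs)) < 0.5]
        if (!length(pick)) pick <- sample(gs, 1)
        mut <- union(mut, pick)
      }
      sort(mut)
    })
    names(mutations) <- ids

    hazard <- config@baselineHazard *
      config@hrHighExpression^high *
      config@hrInteraction^(high & carrier)
    death <- rexp(n, hazard)
    recur <- rexp(n, hazard * config@recurrenceHazardFactor)
    cens <- rexp(n, config@censoringRate)

    osTime <- ceiling(pmin(death, cens))
    osEvent <- death <= cens
    dfsRaw <- pmin(death, recur)
    dfsTime <- ceiling(pmin(dfsRaw, cens))
    dfsEvent <- dfsRaw <= cens

    clinical <- data.frame(sample_id = ids, os_time = osTime,
                           os_event = osEvent, dfs_time = dfsTime,
                           dfs_event = dfsEvent, gender = gender,
                           stage = stage, stringsAsFactors = FALSE)
    SurvivalCohort(clinical, expr, mutations)
  })
}
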