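#' ScreenExperiment: plate-format dual-readout screen data
#'
#' Container for a multiplexed RNAi screen in 384-well plate format with two
#' readouts per well: a fluorescence viability signal (arbitrary units) and an
#' image-derived cell count. Wells are kept in long format (one row per well)
#' because batches and co-treatment arms interleave across physical plates.
#'
#' The well table has columns \code{plate} (plate identifier), \code{batch}
#' (screening repeat, integer), \code{row} (letter A-P), \code{col} (integer
#' 1-24), \code{perturbation} (gene symbol or one of the reserved labels
#' \code{NC}, \code{PLK1}, \code{EMPTY}), \code{co_treatment} (\code{VEHICLE}
#' or \code{CISPLATIN}), \code{viability} and \code{count}. Missing readouts
#' are \code{NA}, never zero.
#'
#' @slot wells data.frame of wells in long format (see Details).
#'
#' @examples
#' cfg <- screenSimConfig(nGenes = 12, countNoiseCv = 0.1)
#' se <- generateScreen(cfg)
#' se
#' head(wells(se))
#' @export
setClass("ScreenExperiment", representation(wells = "data.frame"))

.validScreenExperiment <- function(object) {
  w <- object@wells
  req <- c("plate", "batch", "row", "col", "perturbation", "co_treatment",
           "viability", "count")
  miss <- setdiff(req, names(w))
  if (length(miss)) {
    return(sprintf("missing well column(s): %s", paste(miss, collapse = ", ")))
  }
  msgs <- character()
  badRow <- !w$row %in% LETTERS[1:16]
  if (any(badRow)) {
    msgs <- c(msgs, sprintf("row outside A-P at well row(s) %s",
                            paste(utils::head(which(badRow), 5), collapse = ", ")))
  }
  badCol <- is.na(w$col) | w$col < 1 | w$col > 24 | w$col != as.integer(w$col)
  if (any(badCol)) {
    msgs <- c(msgs, sprintf("column outside 1-24 at well row(s) %s",
                            paste(utils::head(which(badCol), 5), collapse = ", ")))
  }
  badArm <- !w$co_treatment %in% ARMS
  if (any(badArm)) {
    msgs <- c(msgs, "co_treatment must be VEHICLE or CISPLATIN")
  }
  cnt <- w$count[!is.na(w$count)]
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    msgs <- c(msgs, "count must be a nonnegative integer")
  }
  via <- w$viability[!is.na(w$viability)]
  if (any(via < 0)) msgs <- c(msgs, "viability must be nonnegative")
  if (length(msgs)) msgs else TRUE
}
setValidity("ScreenExperiment", .validScreenExperiment)

#' Construct a ScreenExperiment from a well table
#'
#' @param wells data.frame with columns \code{plate}, \code{batch}, \code{row},
#'   \code{col}, \code{perturbation}, \code{co_treatment}, \code{viability},
#'   \code{count}.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
ScreenExperiment <- function(wells) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  wells$batch <- as.integer(wells$batch)
  if ("col" %in% names(wells)) wells$col <- as.integer(wells$col)
  # reserved labels are case-insensitive on input, canonical uppercase inside
  up <- toupper(wells$perturbation)
  res <- up %in% PERTURBATION_RESERVED
  wells$perturbation[res] <- up[res]
  wells$co_treatment <- toupper(wells$co_treatment)
  rownames(wells) <- NULL
  methods::new("ScreenExperiment", wells = wells)
}

#' @describeIn ScreenExperiment-class Access the long-format well table.
#' @param x A \code{ScreenExperiment}.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @export
setMethod("wells", "ScreenExperiment", function(x) x@wells)

#' @export
setMethod("show", "ScreenExperiment", function(object) {
  w <- object@wells
  cat("ScreenExperiment with", nrow(w), "wells\n")
  cat("  plates:", length(unique(w$plate)),
      " batches:", length(unique(w$batch)),
      " arms:", paste(sort(unique(w$co_treatment)), collapse = "/"), "\n")
  nGenes <- length(setdiff(unique(w$perturbation), PERTURBATION_RESERVED))
  cat("  perturbations:", nGenes, "genes +",
      sum(w$perturbation == "NC"), "siNC /",
      sum(w$perturbation == "PLK1"), "siPLK1 /",
      sum(w$perturbation == "EMPTY"), "empty wells\n")
})

#' SurvivalCohort: clinical, expression and mutation data for one cohort
#'
#' Holds per-sample survival endpoints (overall survival, OS, and disease-free
#' survival, DFS), gender and tumor stage, a gene-by-sample expression matrix
#' on the log2(TPM+1) scale, and per-sample somatic mutation sets.
#'
#' @slot clinical data.frame with columns \code{sample_id}, \code{os_time},
#'   \code{os_event}, \code{dfs_time}, \code{dfs_event}, \code{gender}
#'   (FEMALE/MALE), \code{stage} (I-IV). Times are in days, strictly positive;
#'   events are logical.
#' @slot expression numeric matrix, genes as rows, samples as columns.
#' @slot mutations named list; one character vector of mutated gene symbols
#'   per sample (empty vector = no recorded mutation).
#'
#' @examples
#' coh <- generateCohort(cohortSimConfig(nSamples = 50))
#' coh
#' @export
setClass("SurvivalCohort",
         representation(clinical = "data.frame", expression = "matrix",
                        mutations = "list"))

.validSurvivalCohort <- function(object) {
  cl <- object@clinical
  req <- c("sample_id", "os_time", "os_event", "dfs_time", "dfs_event",
           "gender", "stage")
  miss <- setdiff(req, names(cl))
  if (length(miss)) {
    return(sprintf("missing clinical column(s): %s",
                   paste(miss, collapse = ", ")))
  }
  msgs <- character()
  if (anyDuplicated(cl$sample_id)) msgs <- c(msgs, "duplicated sample_id")
  tms <- c(cl$os_time, cl$dfs_time)
  if (any(!is.na(tms) & tms <= 0)) {
    msgs <- c(msgs, "survival times must be strictly positive")
  }
  if (!all(cl$gender %in% GENDERS)) {
    msgs <- c(msgs, "gender must be FEMALE or MALE")
  }
  if (!all(cl$stage %in% STAGES)) msgs <- c(msgs, "stage must be I/II/III/IV")
  if (!identical(colnames(object@expression), cl$sample_id)) {
    msgs <- c(msgs, "expression columns must match clinical sample_id order")
  }
  if (!identical(names(object@mutations), cl$sample_id)) {
    msgs <- c(msgs, "mutation list names must match clinical sample_id order")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SurvivalCohort", .validSurvivalCohort)

#' Construct a SurvivalCohort
#'
#' @param clinical,expression,mutations see \linkS4class{SurvivalCohort}.
#' @return A \linkS4class{SurvivalCohort}.
#' @export
SurvivalCohort <- function(clinical, expression, mutations) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  clinical$gender <- toupper(clinical$gender)
  clinical$stage <- toupper(clinical$stage)
  clinical$os_event <- as.logical(clinical$os_event)
  clinical$dfs_event <- as.logical(clinical$dfs_event)
  rownames(clinical) <- NULL
  expression <- as.matrix(expression)
  methods::new("SurvivalCohort", clinical = clinical,
               expression = expression, mutations = mutations)
}

#' @describeIn SurvivalCohort-class Number of samples.
#' @param x A \code{SurvivalCohort}.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "SurvivalCohort", function(x) nrow(x@clinical))

#' @describeIn SurvivalCohort-class Sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "SurvivalCohort", function(x) x@clinical$sample_id)

#' @describeIn SurvivalCohort-class Clinical table.
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @export
setMethod("clinicalData", "SurvivalCohort", function(x) x@clinical)

#' @describeIn SurvivalCohort-class Expression matrix (genes x samples).
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @export
setMethod("exprMatrix", "SurvivalCohort", function(x) x@expression)

#' @describeIn SurvivalCohort-class Per-sample mutation sets (named list).
#' @export
setGeneric("mutationSets", function(x) standardGeneric("mutationSets"))
#' @export
setMethod("mutationSets", "SurvivalCohort", function(x) x@mutations)

#' Subset a cohort by sample identifier
#'
#' @param x A \linkS4class{SurvivalCohort}.
#' @param ids Character vector of sample identifiers to keep (order kept from
#'   the cohort, not from \code{ids}).
#' @return A \linkS4class{SurvivalCohort} restricted to \code{ids}.
#' @export
subsetCohort <- function(x, ids) {
  keep <- x@clinical$sample_id %in% ids
  SurvivalCohort(x@clinical[keep, , drop = FALSE],
                 x@expression[, keep, drop = FALSE],
                 x@mutations[keep])
}

#' @export
setMethod("show", "SurvivalCohort", function(object) {
  cl <- object@clinical
  cat("SurvivalCohort with", nrow(cl), "samples,",
      nrow(object@expression), "genes\n")
  cat("  OS events:", sum(cl$os_event), " DFS events:", sum(cl$dfs_event), "\n")
  cat("  gender:", paste(sprintf("%s=%d", names(table(cl$gender)),
                                 table(cl$gender)), collapse = " "),
      " stage:", paste(sprintf("%s=%d", names(table(cl$stage)),
                               table(cl$stage)), collapse = " "), "\n")
  nMut <- sum(lengths(object@mutations) > 0)
  cat("  samples with >=1 mutation:", nMut, "\n")
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' Step-function survival estimate. \code{time} holds the distinct event
#' times in ascending order; \code{surv} the estimate S(t) just after each;
#' \code{nRisk} and \code{nEvent} the at-risk and event counts at each time.
#'
#' @slot time numeric, ascending distinct times with at least one event.
#' @slot surv numeric in [0,1], non-increasing.
#' @slot nRisk integer, at-risk counts (censored-at-t subjects still at risk).
#' @slot nEvent integer, events at each time.
#' @slot nCensored integer(1), total censored subjects.
#' @slot n integer(1), total subjects.
#' @export
setClass("KMCurve",
         representation(time = "numeric", surv = "numeric", nRisk = "integer",
                        nEvent = "integer", nCensored = "integer",
                        n = "integer"))

setValidity("KMCurve", function(object) {
  msgs <- character()
  if (is.unsorted(object@time, strictly = TRUE) && length(object@time) > 1) {
    msgs <- c(msgs, "event times must be strictly increasing")
  }
  if (any(diff(object@surv) > 1e-12)) msgs <- c(msgs, "S(t) must be non-increasing")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12)) {
    msgs <- c(msgs, "S(t) must lie in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "KMCurve", function(object) {
  cat("KMCurve:", object@n, "subjects,", sum(object@nEvent), "events,",
      object@nCensored, "censored\n")
  if (length(object@time)) {
    df <- data.frame(time = object@time, n.risk = object@nRisk,
                     n.event = object@nEvent, survival = round(object@surv, 4))
    print(utils::head(df, 10), row.names = FALSE)
    if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more event times\n")
  }
})
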