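#' Run the full screen-to-survival pipeline
#'
#' Orchestrates the stages qc -> call-hits -> metrics -> survival-scan on
#' plate-format screen data (read from a file or simulated) and, optionally,
#' a survival cohort. Every inter-stage artifact is a plain CSV in
#' \code{outdir} (inspectable and diff-able), and a JSON run manifest with
#' the configuration snapshot, input digests, seed, package version and
#' per-stage output paths is written last. Re-running with an identical
#' configuration and seed reproduces identical stage outputs.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{outdir}{output directory (created if needed). Required.}
#'     \item{seed}{integer seed for simulated inputs (default 1).}
#'     \item{screen}{either \code{list(path = "wells.csv")} or a list of
#'       \code{\link{screenPreset}} arguments, e.g.
#'       \code{list(preset = "tiny")} (default).}
#'     \item{cohort}{\code{NULL} to skip the survival stage,
#'       \code{list(clinical=, expression=, mutations=)} file paths, or a
#'       list of \code{\link{cohortSimConfig}} arguments with
#'       \code{simulate = TRUE}.}
#'     \item{gene}{gene to scan in the survival stage (default: first gene
#'       of the cohort expression matrix).}
#'     \item{geneset}{optional mutation gene set for a stratified scan.}
#'     \item{p, fold, zVariant, excellent, borderline, ncCenter}{analysis
#'       thresholds, defaulting to 0.01, 1, "standard", 0.5, 0, "median".}
#'   }
#' @param quiet Suppress progress messages on stderr.
#' @return The manifest, invisibly (a list).
#' @examples
#' out <- file.path(tempdir(), "runall-example")
#' m <- runAll(list(outdir = out, seed = 7,
#'                  screen = list(preset = "tiny"),
#'                  cohort = list(simulate = TRUE, nSamples = 60)))
#' names(m$stages)
#' @export
runAll <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stop("config$outdir is required", call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  p <- config$p %||% 0.01
  fold <- config$fold %||% 1
  zVariant <- config$zVariant %||% "standard"
  ncCtr <- config$ncCenter %||% "median"
  say <- function(...) if (!quiet) message("[screenSurv] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outputs <- list()
  inputs <- character()

  screenCfg <- config$screen %||% list(preset = "tiny")
  se <- stage("qc", {
    if (!is.null(screenCfg$path)) {
      inputs <- c(inputs, screenCfg$path)
      say("reading plate table ", screenCfg$path)
      readPlateTable(screenCfg$path)
    } else {
      args <- screenCfg
      args$seed <- args$seed %||% seed
      say("simulating screen (preset ", args$preset %||% "tiny", ")")
      generateScreen(do.call(screenPreset, args))
    }
  })

  qc <- stage("qc", qcReport(se, variant = zVariant,
                             excellent = config$excellent %||% 0.5,
                             borderline = config$borderline %||% 0))
  outputs$qc <- file.path(config$outdir, "qc.csv")
  writeResultsTable(qc, outputs$qc)
  say("qc: ", nrow(qc), " plate/readout results")

  eff <- stage("call-hits", geneEffects(se, center = ncCtr))
  hits <- stage("call-hits", callHits(se, pThreshold = p,
                                      foldThreshold = fold, center = ncCtr))
  outputs$effects <- file.path(config$outdir, "gene_effects.csv")
  writeResultsTable(eff, outputs$effects)
  outputs$hits <- file.path(config$outdir, "hit_calls.csv")
  writeResultsTable(hits, outputs$hits)
  say("call-hits: ", sum(hits$category != "NONE"), " hits / ",
      nrow(hits), " genes")

  met <- stage("metrics", {
    w <- wells(se)
    ok <- w$perturbation != "EMPTY"
    data.frame(w[ok, c("plate", "batch", "row", "col", "perturbation",
                       "co_treatment")],
               viability_per_cell = suppressWarnings(
                 viabilityPerCell(w$viability[ok], w$count[ok])),
               stringsAsFactors = FALSE)
  })
  outputs$metrics <- file.path(config$outdir, "viability_per_cell.csv")
  writeResultsTable(met, outputs$metrics)

  if (!is.null(config$cohort)) {
    cc <- config$cohort
    coh <- stage("survival-scan", {
      if (!is.null(cc$clinical)) {
        inputs <- c(inputs, cc$clinical, cc$expression, cc$mutations)
        readCohortTables(cc$clinical, cc$expression, cc$mutations)
      } else {
        args <- cc
        args$simulate <- NULL
        args$seed <- args$seed %||% seed
        generateCohort(do.call(cohortSimConfig, args))
      }
    })
    gene <- config$gene %||% rownames(exprMatrix(coh))[1]
    res <- stage("survival-scan", {
      if (!is.null(config$geneset)) {
        mutationStratifiedScan(coh, gene, config$geneset)
      } else {
        scan48(coh, gene)
      }
    })
    outputs$survival <- file.path(config$outdir, "prognosis.csv")
    writeResultsTable(res$cells,
                      file.path(config$outdir, "scan_cells.csv"))
    writeResultsTable(res$call, outputs$survival)
    say("survival-scan: ", gene, " -> ", res$call$call,
        " (best p = ", signif(res$call$best_p, 3), ")")
  }

  manifest <- list(
    package = "screenSurv",
    version = as.character(utils::packageVersion("screenSurv")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config[setdiff(names(config), "outdir")],
    input_digests = as.list(tools::md5sum(inputs)),
    stages = lapply(outputs, function(pth)
      list(path = pth, md5 = unname(tools::md5sum(pth))))
  )
  manifestPath <- file.path(config$outdir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  } else {
    saveRDS(manifest, sub("\\.json$", ".rds", manifestPath))
  }
  say("manifest written to ", manifestPath)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
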