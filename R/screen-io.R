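#' Read a plate-format screen table
#'
#' Reads a long-format well table (CSV or TSV by extension) with header
#' columns \code{plate}, \code{batch}, \code{row}, \code{col},
#' \code{perturbation}, \code{co_treatment}, \code{viability}, \code{count}.
#' Reserved perturbation labels (\code{NC}, \code{PLK1}, \code{EMPTY}) are
#' case-insensitive on input and canonicalized to uppercase. Empty wells are
#' retained and flagged via their label; missing readouts are empty cells and
#' become \code{NA}. Every plate instance is checked for the presence of both
#' control classes; a missing class raises a warning at load.
#'
#' @param path Path to a delimited file (.csv comma, .tsv/.txt tab).
#' @return A \linkS4class{ScreenExperiment}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeScreenTable(generateScreen(screenPreset("tiny")), f)
#' se <- readPlateTable(f)
#' @export
readPlateTable <- function(path) {
  df <- .readDelim(path)
  req <- c("plate", "batch", "row", "col", "perturbation", "co_treatment",
           "viability", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("plate table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # line numbers: header is line 1
  line <- seq_len(nrow(df)) + 1L
  df$row <- toupper(as.character(df$row))
  badRow <- !df$row %in% LETTERS[1:16]
  badCol <- is.na(df$col) | df$col < 1 | df$col > 24
  if (any(badRow | badCol)) {
    i <- which(badRow | badCol)[1]
    stop(sprintf("well coordinate out of 384-well bounds at line %d (row %s, col %s)",
                 line[i], df$row[i], df$col[i]), call. = FALSE)
  }
  for (rc in c("viability", "count")) {
    bad <- !is.na(df[[rc]]) & df[[rc]] < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("negative %s at line %d", rc, line[i]), call. = FALSE)
    }
  }
  se <- ScreenExperiment(df)
  .checkControlsPresent(se)
  se
}

.checkControlsPresent <- function(se) {
  w <- wells(se)
  key <- interaction(w$plate, w$batch, w$co_treatment, drop = TRUE)
  for (k in levels(key)) {
    sub <- w$perturbation[key == k]
    for (ctl in c("NC", "PLK1")) {
      if (!any(sub == ctl)) {
        warning(sprintf("plate instance %s has no %s control wells",
                        gsub("\\.", "/", k), ctl), call. = FALSE)
      }
    }
  }
  invisible(se)
}

#' Write a screen to a plate table file
#'
#' Inverse of \code{\link{readPlateTable}}; round-trips losslessly, with
#' missing readouts written as empty cells.
#'
#' @param x A \linkS4class{ScreenExperiment}.
#' @param path Output path (.csv or .tsv).
#' @return The path, invisibly.
#' @export
writeScreenTable <- function(x, path) {
  .writeDelim(wells(x), path)
}

#' Read cohort tables (clinical, expression, mutations)
#'
#' Assembles a \linkS4class{SurvivalCohort} from three delimited files.
#' The clinical table carries raw follow-up fields as deposited by cancer
#' registries: \code{sample_id}, \code{vital_status} (Alive/Dead),
#' \code{days_to_death}, \code{days_to_last_follow_up},
#' \code{days_to_new_tumor_event}, \code{gender}, \code{stage}. Endpoints are
#' derived here: OS time is days to death for deceased samples, otherwise
#' days to last follow-up (censored); the DFS event time is the first of new
#' tumor event or death, censored at last follow-up when neither occurred.
#'
#' The expression matrix has genes as rows; its first column holds gene
#' symbols and the remaining columns are samples. The mutation table is long
#' format with columns \code{sample_id} and \code{gene}; samples with no rows
#' get an empty mutation set.
#'
#' Samples present in the clinical table but absent from the expression
#' matrix are dropped with a warning. Zero overlap is an error, as is a
#' duplicated clinical \code{sample_id}.
#'
#' @param clinical,expression,mutations Paths to the three files.
#' @return A \linkS4class{SurvivalCohort}.
#' @export
readCohortTables <- function(clinical, expression, mutations) {
  cl <- .readDelim(clinical)
  req <- c("sample_id", "vital_status", "days_to_death",
           "days_to_last_follow_up", "days_to_new_tumor_event", "gender",
           "stage")
  miss <- setdiff(req, names(cl))
  if (length(miss)) {
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cl$sample_id)) {
    stop("duplicated sample_id in clinical table: ",
         cl$sample_id[duplicated(cl$sample_id)][1], call. = FALSE)
  }

  ex <- .readDelim(expression)
  geneCol <- names(ex)[1]
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- as.character(ex[[geneCol]])

  overlap <- intersect(cl$sample_id, colnames(mat))
  if (length(overlap) == 0) {
    stop("no overlapping samples between clinical and expression tables",
         call. = FALSE)
  }
  dropped <- setdiff(cl$sample_id, colnames(mat))
  if (length(dropped)) {
    warning(sprintf("%d clinical sample(s) absent from expression matrix dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  cl <- cl[cl$sample_id %in% overlap, , drop = FALSE]
  mat <- mat[, cl$sample_id, drop = FALSE]

  mut <- .readDelim(mutations)
  if (!all(c("sample_id", "gene") %in% names(mut))) {
    stop("mutation table must have columns sample_id and gene", call. = FALSE)
  }
  mutSets <- lapply(cl$sample_id, function(s) {
    sort(unique(as.character(mut$gene[mut$sample_id == s])))
  })
  names(mutSets) <- cl$sample_id

  dead <- toupper(cl$vital_status) == "DEAD"
  osTime <- ifelse(dead, cl$days_to_death, cl$days_to_last_follow_up)
  dfsEventTime <- pmin(cl$days_to_new_tumor_event,
                       ifelse(dead, cl$days_to_death, Inf), na.rm = TRUE)
  dfsEvent <- is.finite(dfsEventTime)
  dfsTime <- ifelse(dfsEvent, dfsEventTime, cl$days_to_last_follow_up)

  clinical <- data.frame(sample_id = cl$sample_id, os_time = osTime,
                         os_event = dead, dfs_time = dfsTime,
                         dfs_event = dfsEvent, gender = toupper(cl$gender),
                         stage = toupper(cl$stage), stringsAsFactors = FALSE)
  SurvivalCohort(clinical, mat, mutSets)
}

#' Write cohort tables
#'
#' Inverse of \code{\link{readCohortTables}}: writes the clinical table in
#' raw follow-up form, the gene-by-sample expression matrix and the
#' long-format mutation table, such that reading the three files back yields
#' an identical cohort.
#'
#' @param x A \linkS4class{SurvivalCohort}.
#' @param clinical,expression,mutations Output paths.
#' @return Invisibly, the three paths.
#' @export
writeCohortTables <- function(x, clinical, expression, mutations) {
  cl <- clinicalData(x)
  raw <- data.frame(
    sample_id = cl$sample_id,
    vital_status = ifelse(cl$os_event, "Dead", "Alive"),
    days_to_death = ifelse(cl$os_event, cl$os_time, NA),
    days_to_last_follow_up = ifelse(cl$os_event, NA, cl$os_time),
    days_to_new_tumor_event = ifelse(cl$dfs_event & !(cl$os_event &
                                       cl$dfs_time == cl$os_time),
                                     cl$dfs_time, NA),
    gender = cl$gender, stage = cl$stage, stringsAsFactors = FALSE)
  .writeDelim(raw, clinical)

  mat <- exprMatrix(x)
  exdf <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
  .writeDelim(exdf, expression)

  ms <- mutationSets(x)
  long <- data.frame(
    sample_id = rep(names(ms), lengths(ms)),
    gene = unlist(ms, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0) long <- data.frame(sample_id = character(0),
                                          gene = character(0))
  .writeDelim(long, mutations)
  invisible(c(clinical, expression, mutations))
}

#' Write a result table to a delimited file
#'
#' Generic writer for the package's result tables (QC reports, gene effects,
#' hit calls, scan cells). Missing values are written as empty cells so the
#' table round-trips through \code{\link{readResultsTable}}.
#'
#' @param table A data.frame.
#' @param path Output path (.csv or .tsv).
#' @return The path, invisibly.
#' @export
writeResultsTable <- function(table, path) {
  .writeDelim(as.data.frame(table), path)
}

#' Read a result table written by \code{\link{writeResultsTable}}
#'
#' @param path Path to the file.
#' @return A data.frame with empty cells restored as \code{NA}.
#' @export
readResultsTable <- function(path) {
  .readDelim(path)
}
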