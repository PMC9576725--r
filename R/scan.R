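#' 48-condition prognostic survival scan for one gene
#'
#' Evaluates the association of a gene's expression with survival across all
#' 48 combinations of endpoint (OS, DFS), expression split (median,
#' quartile), gender filter (FEMALE, MALE, BOTH) and tumor stage filter (I,
#' II, III, IV): 2 x 2 x 3 x 4 = 48 cells. In each cell the cohort is
#' filtered, the expression split is computed within the filtered samples,
#' and a two-group log-rank test compares the HIGH vs LOW groups. The best
#' (smallest) p-value across cells with both groups non-empty drives the
#' prognosis call:
#' \describe{
#'   \item{UNFAVORABLE}{best p < 0.05 and the HIGH group has worse survival
#'     in the best cell.}
#'   \item{FAVORABLE}{best p < 0.05 and the HIGH group has better survival.}
#'   \item{NONE}{best p >= 0.05 (or no valid cell).}
#' }
#' Tiers follow the reporting thresholds: \code{P01} (p < 0.01), \code{P05}
#' (p < 0.05), \code{NS}. Ties in the best p are broken by the fixed cell
#' ordering (endpoint, split, gender, stage) for determinism.
#'
#' Note that selecting the best of 48 correlated tests without correction
#' inflates the false-positive rate of the call; the package measures this
#' inflation by simulation (see the methods vignette) but deliberately does
#' not correct it, reproducing the published selection rule.
#'
#' @param cohort A \linkS4class{SurvivalCohort}.
#' @param gene Gene symbol present in the expression matrix.
#' @return list with \code{cells} (48-row data.frame: \code{endpoint},
#'   \code{split}, \code{gender_filter}, \code{stage_filter}, \code{n_high},
#'   \code{n_low}, \code{p_value}, \code{direction}) and \code{call}
#'   (one-row data.frame: \code{gene}, \code{best_p}, best-cell columns,
#'   \code{call}, \code{tier}).
#' @examples
#' coh <- generateCohort(cohortSimConfig(nSamples = 120, hrHighExpression = 3))
#' res <- scan48(coh, "G1")
#' res$call
#' @export
scan48 <- function(cohort, gene) {
  if (!gene %in% rownames(exprMatrix(cohort))) {
    stop("gene not present in the cohort expression matrix: ", gene,
         call. = FALSE)
  }
  cl <- clinicalData(cohort)
  expr <- exprMatrix(cohort)[gene, ]
  grid <- expand.grid(stage_filter = STAGES,
                      gender_filter = c("FEMALE", "MALE", "BOTH"),
                      split = c("MEDIAN", "QUARTILE"),
                      endpoint = c("OS", "DFS"),
                      stringsAsFactors = FALSE)
  # fixed deterministic ordering: endpoint, split, gender, stage
  grid <- grid[, c("endpoint", "split", "gender_filter", "stage_filter")]

  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    keep <- cl$stage == g$stage_filter &
      (g$gender_filter == "BOTH" | cl$gender == g$gender_filter)
    res <- data.frame(g, n_high = 0L, n_low = 0L, p_value = NA_real_,
                      direction = NA_real_, stringsAsFactors = FALSE)
    n <- sum(keep)
    minN <- if (g$split == "MEDIAN") 2L else 4L
    if (n < minN) return(res)
    vals <- expr[keep]
    labels <- splitByExpression(vals, tolower(g$split))
    use <- labels != "EXCLUDED"
    tm <- if (g$endpoint == "OS") cl$os_time[keep] else cl$dfs_time[keep]
    ev <- if (g$endpoint == "OS") cl$os_event[keep] else cl$dfs_event[keep]
    res$n_high <- sum(labels == "HIGH")
    res$n_low <- sum(labels == "LOW")
    if (res$n_high == 0 || res$n_low == 0 || sum(ev[use]) == 0) return(res)
    lr <- logrankTest(tm[use], ev[use],
                      factor(labels[use], levels = c("HIGH", "LOW")))
    res$p_value <- lr$p_value
    res$direction <- lr$direction
    res
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  list(cells = cells, call = .prognosisCall(cells, gene))
}

.prognosisCall <- function(cells, gene) {
  valid <- which(!is.na(cells$p_value))
  if (!length(valid)) {
    return(data.frame(gene = gene, best_p = NA_real_, endpoint = NA,
                      split = NA, gender_filter = NA, stage_filter = NA,
                      direction = NA_real_, call = "NONE", tier = "NS",
                      stringsAsFactors = FALSE))
  }
  best <- valid[which.min(cells$p_value[valid])]  # first minimum: fixed order
  bp <- cells$p_value[best]
  dir <- cells$direction[best]
  call <- if (bp >= 0.05 || is.na(dir) || dir == 0) {
    "NONE"
  } else if (dir < 0) "UNFAVORABLE" else "FAVORABLE"
  tier <- if (bp < 0.01) "P01" else if (bp < 0.05) "P05" else "NS"
  data.frame(gene = gene, best_p = bp, endpoint = cells$endpoint[best],
             split = cells$split[best],
             gender_filter = cells$gender_filter[best],
             stage_filter = cells$stage_filter[best], direction = dir,
             call = call, tier = tier, stringsAsFactors = FALSE)
}

#' Mutation-set-stratified prognostic scan
#'
#' Restricts the cohort to samples whose somatic mutation set intersects a
#' given gene set (carriers of one or more of the listed mutations), then
#' runs the 48-condition scan on the subset. An empty subset is an error.
#'
#' @param cohort A \linkS4class{SurvivalCohort}.
#' @param gene Expression gene to scan.
#' @param mutationGeneset Non-empty character vector of mutation gene
#'   symbols.
#' @return As \code{\link{scan48}}, plus \code{n_subset}.
#' @export
mutationStratifiedScan <- function(cohort, gene, mutationGeneset) {
  if (!length(mutationGeneset)) {
    stop("mutation gene set must be non-empty", call. = FALSE)
  }
  ms <- mutationSets(cohort)
  carrier <- vapply(ms, function(m) length(intersect(m, mutationGeneset)) > 0,
                    logical(1))
  if (!any(carrier)) {
    stop("no sample carries a mutation in the given gene set (subset size 0)",
         call. = FALSE)
  }
  sub <- subsetCohort(cohort, sampleIds(cohort)[carrier])
  res <- scan48(sub, gene)
  res$n_subset <- nSamples(sub)
  res
}

#' Binary oncoprint matrix with frequencies and co-occurrence
#'
#' Builds the sample-by-gene binary mutation matrix (1 = the sample's
#' mutation set contains the gene), per-gene carrier counts and frequencies,
#' and the gene-by-gene co-occurrence count matrix (number of samples
#' mutated in both genes). Rendering is out of scope; the matrices are
#' suitable for tabulation or external plotting.
#'
#' @param cohort A \linkS4class{SurvivalCohort}.
#' @param genes Genes to include; default: all genes mutated in any sample.
#' @return list with \code{matrix} (samples x genes, 0/1),
#'   \code{frequencies} (data.frame gene / n_mutated / frequency) and
#'   \code{cooccurrence} (genes x genes counts; diagonal = carrier counts).
#' @export
oncoprintMatrix <- function(cohort, genes = NULL) {
  ms <- mutationSets(cohort)
  if (is.null(genes)) genes <- sort(unique(unlist(ms)))
  mat <- matrix(0L, nrow = length(ms), ncol = length(genes),
                dimnames = list(names(ms), genes))
  for (i in seq_along(ms)) {
    mat[i, genes %in% ms[[i]]] <- 1L
  }
  counts <- colSums(mat)
  freq <- data.frame(gene = genes, n_mutated = as.integer(counts),
                     frequency = counts / max(1L, nrow(mat)),
                     stringsAsFactors = FALSE, row.names = NULL)
  cooc <- crossprod(mat)
  list(matrix = mat, frequencies = freq, cooccurrence = cooc)
}
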