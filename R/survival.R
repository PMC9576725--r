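#' Convert FPKM to log2(TPM + 1)
#'
#' Per sample, \eqn{TPM_i = FPKM_i / \sum_j FPKM_j \times 10^6}, then
#' \eqn{log2(TPM_i + 1)}. The per-sample TPM vector sums to \eqn{10^6}
#' exactly (up to floating tolerance) and the conversion is invariant to a
#' common rescaling of the FPKM values.
#'
#' @param fpkm Numeric vector (one sample over genes) or matrix (genes x
#'   samples; each column converted independently). All values must be
#'   nonnegative and not all zero per sample.
#' @return log2(TPM + 1) values, same shape as the input.
#' @examples
#' fpkmToLog2Tpm(c(1, 1, 2))
#' @export
fpkmToLog2Tpm <- function(fpkm) {
  if (is.matrix(fpkm)) {
    return(apply(fpkm, 2, fpkmToLog2Tpm))
  }
  if (any(is.na(fpkm)) || any(fpkm < 0)) {
    stop("FPKM values must be nonnegative and non-missing", call. = FALSE)
  }
  tot <- sum(fpkm)
  if (tot == 0) stop("all-zero FPKM sample cannot be converted", call. = FALSE)
  tpm <- fpkm / tot * 1e6
  log2(tpm + 1)
}

#' Kaplan-Meier product-limit estimate
#'
#' Implements the product-limit estimator from first principles. At each
#' distinct event time t with d events among n at risk, the survival
#' estimate multiplies by (1 - d/n). Subjects censored at t remain at risk
#' for the events at t (events precede censorings at tied times).
#'
#' @param times Positive follow-up times.
#' @param events Logical (or 0/1): TRUE = event, FALSE = censored.
#' @return A \linkS4class{KMCurve}.
#' @examples
#' kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' @export
kmEstimate <- function(times, events) {
  events <- as.logical(events)
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(is.na(times)) || any(is.na(events)) || any(times <= 0)) {
    stop("times must be positive and non-missing", call. = FALSE)
  }
  eventTimes <- sort(unique(times[events]))
  nRisk <- vapply(eventTimes, function(t) sum(times >= t), integer(1))
  nEvent <- vapply(eventTimes, function(t) sum(times == t & events),
                   integer(1))
  surv <- cumprod(1 - nEvent / nRisk)
  methods::new("KMCurve", time = as.numeric(eventTimes), surv = surv,
               nRisk = nRisk, nEvent = nEvent,
               nCensored = sum(!events), n = length(times))
}

#' Survival probability at given times
#'
#' Step-function evaluation of a \linkS4class{KMCurve}: S(t) is the estimate
#' just after the last event time at or before t (1 before the first event).
#'
#' @param curve A \linkS4class{KMCurve}.
#' @param t Numeric vector of times.
#' @return Numeric vector of survival probabilities.
#' @export
survProb <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve@time <= tt)
    if (i == 0) 1 else curve@surv[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank test implemented from first principles: at
#' each distinct event time the observed events in group 1 are compared with
#' the hypergeometric expectation given the margins, the variance summed
#' across event times, and the statistic \eqn{(O_1-E_1)^2/V} referred to a
#' chi-square distribution with 1 df. An exact permutation p-value (over
#' group-label reassignments, holding group sizes fixed) is available for
#' small samples: all \code{choose(n, n1)} assignments are enumerated when
#' there are at most \code{maxExact} of them, otherwise sampled.
#'
#' @param times Positive follow-up times.
#' @param events Logical event indicators.
#' @param groups Two-level grouping (factor, character or logical). Both
#'   groups must be non-empty.
#' @param exact If TRUE also compute a permutation p-value.
#' @param maxExact Maximum number of label assignments to enumerate
#'   exhaustively (default 200000); beyond it, \code{nPerm} random
#'   assignments are sampled.
#' @param nPerm Random permutations when enumeration is infeasible.
#' @return list with \code{statistic}, \code{p_value} (asymptotic),
#'   \code{observed}, \code{expected} (per group), \code{direction} (+1 if
#'   group 1, the first level, has fewer events than expected, i.e. better
#'   survival; -1 if worse; 0 if equal) and, when \code{exact},
#'   \code{p_exact}.
#' @importFrom stats pchisq
#' @examples
#' logrankTest(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 0, 1),
#'             rep(c("A", "B"), each = 3))
#' @export
logrankTest <- function(times, events, groups, exact = FALSE,
                        maxExact = 2e5, nPerm = 20000) {
  events <- as.logical(events)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) {
    stop("log-rank test requires exactly two non-empty groups; got ",
         nlevels(groups), call. = FALSE)
  }
  if (any(table(groups) == 0)) {
    stop("log-rank test requires both groups non-empty", call. = FALSE)
  }
  g1 <- groups == levels(groups)[1]

  stat <- .logrankStat(times, events, g1)
  p <- pchisq(stat$chisq, df = 1, lower.tail = FALSE)
  res <- list(statistic = stat$chisq, p_value = p,
              observed = stat$observed, expected = stat$expected,
              direction = sign(stat$expected[1] - stat$observed[1]))
  names(res$observed) <- names(res$expected) <- levels(groups)

  if (exact) {
    n <- length(times)
    n1 <- sum(g1)
    total <- choose(n, n1)
    obs <- stat$chisq
    if (total <= maxExact) {
      idx <- utils::combn(n, n1)
      stats <- apply(idx, 2, function(ii) {
        gg <- logical(n); gg[ii] <- TRUE
        .logrankStat(times, events, gg)$chisq
      })
      # permutation p includes the identity assignment by construction
      res$p_exact <- mean(stats >= obs - 1e-12)
    } else {
      stats <- replicate(nPerm, {
        gg <- logical(n); gg[sample.int(n, n1)] <- TRUE
        .logrankStat(times, events, gg)$chisq
      })
      res$p_exact <- (1 + sum(stats >= obs - 1e-12)) / (nPerm + 1)
    }
  }
  res
}

# O-E and hypergeometric variance accumulated over distinct event times.
.logrankStat <- function(times, events, g1) {
  eventTimes <- sort(unique(times[events]))
  O1 <- 0; E1 <- 0; V <- 0; Ototal <- 0
  for (t in eventTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    Ototal <- Ototal + d
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chisq = chisq, observed = c(O1, Ototal - O1),
       expected = c(E1, Ototal - E1))
}

#' Split samples by expression level
#'
#' \code{median}: HIGH when strictly above the median, LOW otherwise (ties
#' go LOW). \code{quartile}: HIGH when strictly above the 75th percentile,
#' LOW when strictly below the 25th, the middle half EXCLUDED. Percentiles
#' use linear interpolation (default quantile type).
#'
#' @param values Numeric expression values.
#' @param method \code{"median"} or \code{"quartile"}.
#' @return Character vector of labels \code{HIGH}, \code{LOW},
#'   \code{EXCLUDED}.
#' @examples
#' splitByExpression(1:8, "quartile")
#' @importFrom stats median quantile
#' @export
splitByExpression <- function(values, method = c("median", "quartile")) {
  method <- match.arg(method)
  n <- sum(!is.na(values))
  if (method == "median") {
    if (n < 2) stop("median split needs >= 2 values", call. = FALSE)
    ifelse(values > median(values, na.rm = TRUE), "HIGH", "LOW")
  } else {
    if (n < 4) stop("quartile split needs >= 4 values", call. = FALSE)
    q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    ifelse(values > q[2], "HIGH", ifelse(values < q[1], "LOW", "EXCLUDED"))
  }
}
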