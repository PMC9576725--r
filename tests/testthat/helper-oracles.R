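# Independent oracles used across tests.

# Exact permutation log-rank p-value, with the statistic taken from
# survival::survdiff (independent of the package's own implementation).
# Enumerates every group-label assignment with the observed group sizes.
permLogrankOracle <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  g1 <- groups == levels(groups)[1]
  n <- length(times)
  n1 <- sum(g1)
  chisqOf <- function(g) {
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }
  obs <- chisqOf(g1)
  idx <- utils::combn(n, n1)
  stats <- apply(idx, 2, function(ii) {
    gg <- logical(n); gg[ii] <- TRUE
    chisqOf(gg)
  })
  mean(stats >= obs - 1e-12)
}

# Textbook pooled-variance two-sample t-test p-value.
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# A small plate table written to a temp file; returns the path.
writePlateFixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal hand-built screen: one plate, `nBatches` batches, both arms,
# with explicit control wells and a few gene wells. Counts are exact powers
# of two around 1600 so normalization is exact.
handScreen <- function(nBatches = 2) {
  rows <- list()
  for (b in seq_len(nBatches)) {
    for (arm in c("VEHICLE", "CISPLATIN")) {
      base <- if (arm == "CISPLATIN") 800 else 1600
      mk <- function(row, col, pert, count) {
        data.frame(plate = "P01", batch = b, row = row, col = col,
                   perturbation = pert, co_treatment = arm,
                   viability = count * 2, count = count,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(
        mk("A", 1, "NC", base), mk("B", 1, "NC", base),
        mk("C", 1, "NC", base),
        mk("A", 2, "PLK1", base / 8), mk("B", 2, "PLK1", base / 8),
        mk("A", 3, "GENE1", base / 4), mk("B", 3, "GENE2", base)))
    }
  }
  ScreenExperiment(do.call(rbind, rows))
}
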