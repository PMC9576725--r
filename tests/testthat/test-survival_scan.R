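test_that("FPKM to log2(TPM+1) matches hand arithmetic", {
  out <- fpkmToLog2Tpm(c(1, 1, 2))
  expect_equal(2^out - 1, c(250000, 250000, 500000))
  # single-gene sample takes the whole million
  expect_equal(fpkmToLog2Tpm(5), log2(1e6 + 1))
  # scale invariance
  expect_equal(fpkmToLog2Tpm(c(3, 7, 90)), fpkmToLog2Tpm(2 * c(3, 7, 90)))
  expect_error(fpkmToLog2Tpm(c(0, 0)), "all-zero")
  expect_error(fpkmToLog2Tpm(c(-1, 2)), "nonnegative")
})

test_that("per-sample TPM sums to one million", {
  set.seed(33)
  mat <- matrix(rexp(200, 1 / 10), nrow = 40)
  out <- fpkmToLog2Tpm(mat)
  sums <- colSums(2^out - 1)
  expect_equal(sums, rep(1e6, 5), tolerance = 1e-6)
})

test_that("product-limit estimate matches hand calculation", {
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km@surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km@nRisk, 3:1)

  # all censored: S identically 1
  none <- kmEstimate(c(5, 8, 12), c(FALSE, FALSE, FALSE))
  expect_length(none@time, 0)
  expect_equal(survProb(none, c(1, 100)), c(1, 1))
  expect_equal(none@nCensored, 3L)

  # a single subject with an event drops S to zero at its time
  one <- kmEstimate(5, TRUE)
  expect_equal(survProb(one, c(4.9, 5)), c(1, 0))

  expect_error(kmEstimate(numeric(0), logical(0)), "empty")
  expect_error(kmEstimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("censoring ties keep subjects at risk for simultaneous events", {
  # event and censoring at t = 2: the censored subject counts in the risk set
  km <- kmEstimate(c(1, 2, 2, 3), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(km@nRisk, c(4L, 3L, 1L))
  expect_equal(km@surv, c(3 / 4, 3 / 4 * 2 / 3, 0))
})

test_that("KM without censoring equals one minus the ECDF", {
  set.seed(17)
  t <- round(rexp(40, 1 / 100)) + 1
  km <- kmEstimate(t, rep(TRUE, 40))
  ec <- ecdf(t)
  expect_equal(survProb(km, sort(unique(t))), 1 - ec(sort(unique(t))),
               tolerance = 1e-12)
})

test_that("KM agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(29)
  for (i in 1:5) {
    t <- ceiling(rexp(60, 1 / 200))
    e <- runif(60) < 0.6
    if (!any(e)) next
    km <- kmEstimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref <- summary(sf, times = km@time)
    expect_equal(km@surv, ref$surv, tolerance = 1e-9)
    expect_equal(km@nRisk, ref$n.risk)
  }
})

test_that("log-rank test agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(37)
  for (i in 1:5) {
    n <- 50
    g <- rep(c("A", "B"), each = n / 2)
    t <- ceiling(rexp(n, ifelse(g == "A", 1 / 100, 1 / 180)))
    e <- runif(n) < 0.7
    if (sum(e) < 2) next
    mine <- logrankTest(t, e, g)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(unname(mine$observed), unname(ref$obs))
    expect_equal(unname(mine$expected), unname(ref$exp), tolerance = 1e-9)
  }
})

test_that("log-rank is invariant to swapping group labels", {
  set.seed(39)
  t <- ceiling(rexp(30, 1 / 100)); e <- runif(30) < 0.7
  g <- rep(c("A", "B"), 15)
  a <- logrankTest(t, e, g)
  b <- logrankTest(t, e, ifelse(g == "A", "B", "A"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$direction, -b$direction)
  expect_error(logrankTest(t, e, rep("A", 30)), "two non-empty groups")
})

test_that("asymptotic log-rank p is close to the exact permutation oracle", {
  skip_if_not_installed("survival")
  # n = 10, balanced groups, moderate separation
  t <- c(14, 7, 16, 5, 4, 17, 13, 9, 15, 10)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1) == 1
  g <- rep(c("A", "B"), each = 5)
  oracle <- permLogrankOracle(t, e, g)
  mine <- logrankTest(t, e, g, exact = TRUE)
  expect_equal(mine$p_exact, oracle, tolerance = 1e-12)
  expect_lt(abs(mine$p_value - oracle), 0.02)
})

test_that("expression splits follow the median and quartile rules", {
  expect_equal(splitByExpression(1:4, "median"),
               c("LOW", "LOW", "HIGH", "HIGH"))
  q <- splitByExpression(1:8, "quartile")
  expect_equal(sum(q == "HIGH"), 2)
  expect_equal(sum(q == "LOW"), 2)
  expect_equal(sum(q == "EXCLUDED"), 4)
  # ties at the median go LOW, degenerately all LOW for constant input
  expect_equal(splitByExpression(rep(3, 5), "median"), rep("LOW", 5))
  expect_error(splitByExpression(1, "median"), ">= 2")
  expect_error(splitByExpression(1:3, "quartile"), ">= 4")
})

test_that("the scan enumerates exactly 48 conditions", {
  coh <- generateCohort(cohortSimConfig(nSamples = 120, seed = 8))
  res <- scan48(coh, "G1")
  expect_equal(nrow(res$cells), 48)
  expect_equal(nrow(unique(res$cells[, 1:4])), 48)
  expect_setequal(unique(res$cells$endpoint), c("OS", "DFS"))
  expect_setequal(unique(res$cells$stage_filter), c("I", "II", "III", "IV"))
  p <- res$cells$p_value
  expect_true(all(is.na(p) | (p >= 0 & p <= 1)))
  expect_error(scan48(coh, "NOSUCHGENE"), "not present")
})

test_that("a single-stage cohort leaves 36 cells missing but returns", {
  coh <- generateCohort(cohortSimConfig(
    nSamples = 80, seed = 12,
    stageProbs = c(I = 1, II = 0, III = 0, IV = 0)))
  res <- scan48(coh, "G1")
  expect_equal(nrow(res$cells), 48)
  expect_equal(sum(is.na(res$cells$p_value[res$cells$stage_filter != "I"])),
               36)
  expect_true(is.data.frame(res$call))
})

test_that("a planted hazardous gene is called unfavorable", {
  coh <- generateCohort(cohortSimConfig(nSamples = 300, seed = 14,
                                        hrHighExpression = 3))
  res <- scan48(coh, "G1")
  expect_equal(res$call$call, "UNFAVORABLE")
  expect_lt(res$call$best_p, 0.05)
  # a protective gene is called favorable under the mirrored design
  coh2 <- generateCohort(cohortSimConfig(nSamples = 300, seed = 14,
                                         hrHighExpression = 1 / 3))
  res2 <- scan48(coh2, "G1")
  expect_equal(res2$call$call, "FAVORABLE")
})

test_that("duplicating the cohort preserves directions and sharpens p", {
  coh <- generateCohort(cohortSimConfig(nSamples = 100, seed = 18,
                                        hrHighExpression = 2))
  cl <- clinicalData(coh)
  cl2 <- rbind(cl, transform(cl, sample_id = paste0(sample_id, "b")))
  ex <- exprMatrix(coh)
  ex2 <- cbind(ex, ex)
  colnames(ex2) <- cl2$sample_id
  ms2 <- c(mutationSets(coh), mutationSets(coh))
  names(ms2) <- cl2$sample_id
  dup <- SurvivalCohort(cl2, ex2, ms2)

  a <- scan48(coh, "G1")$cells
  b <- scan48(dup, "G1")$cells
  # compare cells whose group composition exactly doubled (quartile
  # interpolation can reassign a boundary sample, which changes the groups)
  same <- !is.na(a$p_value) & !is.na(b$p_value) &
    b$n_high == 2 * a$n_high & b$n_low == 2 * a$n_low
  expect_gt(sum(same), 10)
  expect_true(all(b$direction[same] == a$direction[same] |
                    a$direction[same] == 0))
  expect_true(all(b$p_value[same] <= a$p_value[same] + 1e-9))
})

test_that("mutation-set stratification subsets carriers correctly", {
  coh <- generateCohort(cohortSimConfig(
    nSamples = 150, seed = 22, interactionGeneset = c("GNAQ", "GNAS"),
    carrierFraction = 0.3))
  expect_error(mutationStratifiedScan(coh, "G1", character(0)), "non-empty")
  expect_error(mutationStratifiedScan(coh, "G1", "UNSEEN_GENE"),
               "subset size 0")

  allMut <- sort(unique(unlist(mutationSets(coh))))
  res <- mutationStratifiedScan(coh, "G1", allMut)
  expect_equal(res$n_subset, sum(lengths(mutationSets(coh)) > 0))

  gs <- c("GNAQ", "GNAS")
  res2 <- mutationStratifiedScan(coh, "G1", gs)
  carriers <- vapply(mutationSets(coh),
                     function(m) length(intersect(m, gs)) > 0, logical(1))
  expect_equal(res2$n_subset, sum(carriers))
})

test_that("oncoprint matrix encodes mutation sets and their accounting", {
  cl <- data.frame(sample_id = c("S1", "S2", "S3"),
                   os_time = c(10, 20, 30), os_event = c(TRUE, FALSE, TRUE),
                   dfs_time = c(8, 20, 25), dfs_event = c(TRUE, FALSE, TRUE),
                   gender = c("FEMALE", "MALE", "FEMALE"),
                   stage = c("I", "II", "I"))
  ex <- matrix(1:6, nrow = 2, dimnames = list(c("G1", "G2"), cl$sample_id))
  ms <- list(S1 = c("KRAS", "TP53"), S2 = "KRAS", S3 = character(0))
  coh <- SurvivalCohort(cl, ex, ms)
  op <- oncoprintMatrix(coh)
  expect_equal(op$matrix["S1", ], c(KRAS = 1L, TP53 = 1L))
  expect_equal(op$matrix["S3", ], c(KRAS = 0L, TP53 = 0L))
  expect_equal(colSums(op$matrix), c(KRAS = 2, TP53 = 1))
  expect_equal(op$frequencies$n_mutated, c(2L, 1L))
  expect_equal(op$cooccurrence["KRAS", "TP53"], 1)
  expect_equal(diag(op$cooccurrence), c(KRAS = 2, TP53 = 1))

  # no mutations anywhere: zero matrix over the requested genes
  msEmpty <- list(S1 = character(0), S2 = character(0), S3 = character(0))
  cohE <- SurvivalCohort(cl, ex, msEmpty)
  opE <- oncoprintMatrix(cohE, genes = c("KRAS", "TP53"))
  expect_true(all(opE$matrix == 0))
})
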