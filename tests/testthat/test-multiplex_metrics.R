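test_that("viability per cell is the exact quotient with signalled zeros", {
  expect_equal(viabilityPerCell(1000, 500), 2)
  expect_identical(viabilityPerCell(NA, 500), NA_real_)
  expect_identical(viabilityPerCell(1000, NA), NA_real_)
  expect_warning(out <- viabilityPerCell(c(1000, 800), c(0, 400)),
                 "zero count")
  expect_identical(out, c(NA, 2))
})

test_that("mean per-cell viability equals the pooled ratio for equal counts", {
  via <- c(1000, 1200, 900)
  cnt <- rep(400, 3)
  expect_equal(mean(viabilityPerCell(via, cnt)), sum(via) / sum(cnt),
               tolerance = 1e-12)
})

test_that("per-cell viability rises as counts fall in treated wells", {
  # the generator's resistance term: killed wells keep a higher per-cell
  # signal, so normalized count and per-cell viability anticorrelate
  effects <- setNames(lapply(seq(-3, 0, length.out = 12),
                             function(e) c(e, e)),
                      paste0("GENE", 1:12))
  cfg <- screenPreset("tiny", nBatches = 3, plantedEffects = effects,
                      resistanceGain = 0.5)
  nw <- normalizeScreen(generateScreen(cfg, seed = 21))
  treated <- nw[!nw$perturbation %in% c("NC", "PLK1", "EMPTY") &
                  nw$co_treatment == "VEHICLE", ]
  vpc <- viabilityPerCell(treated$viability, treated$count)
  rho <- cor(treated$norm_count, vpc, method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("percent growth inhibition matches the defining formula", {
  # treatment identical to control
  expect_equal(percentGrowthInhibition(400, 1600, 1600), 100)
  # no net growth under treatment
  expect_equal(percentGrowthInhibition(400, 400, 1600), 0)
  # hand arithmetic: (800-400)/(1600-400) * 100
  expect_equal(percentGrowthInhibition(400, 800, 1600), 100 / 3,
               tolerance = 1e-9)
  # net kill below seeding is negative
  expect_lt(percentGrowthInhibition(400, 200, 1600), 0)
  expect_error(percentGrowthInhibition(400, 800, 400), "undefined")
})

test_that("percent growth inhibition is scale invariant", {
  set.seed(10)
  for (i in 1:10) {
    x <- sort(runif(3, 100, 5000))
    k <- runif(1, 0.1, 50)
    expect_equal(percentGrowthInhibition(x[1], x[2], x[3]),
                 percentGrowthInhibition(k * x[1], k * x[2], k * x[3]),
                 tolerance = 1e-9)
  }
})

test_that("additive expectation is the sum of single-treatment changes", {
  expect_equal(additiveExpectation(-30, -20), -50)
  expect_equal(additiveExpectation(0, -20), -20)
  expect_equal(additiveExpectation(0, 0), 0)
})

test_that("synergy flag is strict at the additive boundary", {
  expect_true(synergyFlag(-60, -50))
  expect_false(synergyFlag(-50, -50))        # exactly additive: not synergy
  expect_false(synergyFlag(-55, -50, tolerance = 10))
  expect_error(synergyFlag(-60, -50, tolerance = -1))
})

test_that("synergy flag is antisymmetric in the planted interaction sign", {
  # simulate four-condition percent changes with an interaction term of
  # either sign, well beyond the 2-sd tolerance
  simulate <- function(interaction, seed) {
    set.seed(seed)
    noise <- function() rnorm(1, 0, 1)
    dCis <- -30 + noise(); dSi <- -20 + noise()
    obs <- (dCis + dSi) + interaction + noise()
    synergyFlag(obs, additiveExpectation(dCis, dSi), tolerance = 2 * 1)
  }
  flagsPos <- vapply(1:25, function(s) simulate(-15, s), logical(1))
  flagsNul <- vapply(1:25, function(s) simulate(+15, s), logical(1))
  expect_true(all(flagsPos))
  expect_false(any(flagsNul))
})

test_that("self-renewal synergy table normalizes within seeding density", {
  df <- expand.grid(condition = c("siNC-DMF", "siNC-cisplatin", "siGPCR-DMF",
                                  "siGPCR-cisplatin"),
                    seeding_density = c(400, 800),
                    stringsAsFactors = FALSE)
  base <- c(`400` = 1000, `800` = 2000)
  mult <- c("siNC-DMF" = 1, "siNC-cisplatin" = 0.7, "siGPCR-DMF" = 0.8,
            "siGPCR-cisplatin" = 0.35)  # 15 points below additive (0.5)
  df$final_count <- base[as.character(df$seeding_density)] *
    mult[df$condition]
  res <- selfRenewalSynergy(df, tolerance = 5)
  perDensity <- res[!is.na(res$seeding_density), ]
  expect_equal(perDensity$pct_siNC_DMF, c(100, 100))
  expect_equal(perDensity$additive_expected, c(-50, -50))
  expect_equal(perDensity$observed_combined, c(-65, -65))
  expect_true(all(perDensity$synergy))
  # additive combination is not flagged
  df$final_count[df$condition == "siGPCR-cisplatin"] <-
    base[as.character(df$seeding_density[df$condition == "siGPCR-cisplatin"])] * 0.5
  res2 <- selfRenewalSynergy(df, tolerance = 5)
  expect_false(any(res2$synergy))
  expect_error(selfRenewalSynergy(df[df$condition != "siGPCR-DMF", ]),
               "siGPCR-DMF")
})

test_that("serial-treatment contrast reproduces the closed-form t-test", {
  res <- serialTreatmentContrast(fresh = c(80, 79, 81),
                                 pretreated = c(50, 52, 48))
  expect_equal(res$difference, -30)
  expect_equal(res$p_value, pooledTOracle(c(50, 52, 48), c(80, 79, 81)),
               tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)

  same <- serialTreatmentContrast(c(70, 72), c(70, 72))
  expect_equal(same$difference, 0)

  one <- serialTreatmentContrast(c(80), c(50, 52))
  expect_true(is.na(one$p_value))
  expect_equal(one$difference, -29)
})
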