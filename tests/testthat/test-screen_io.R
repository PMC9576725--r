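test_that("a small plate table parses row-for-row", {
  path <- writePlateFixture(c(
    "plate,batch,row,col,perturbation,co_treatment,viability,count",
    "P01,1,A,1,nc,vehicle,1000,500",
    "P01,1,B,1,plk1,vehicle,200,60",
    "P01,1,C,1,GENE1,vehicle,800,400"))
  se <- suppressWarnings(readPlateTable(path))
  w <- wells(se)
  expect_equal(nrow(w), 3)
  # reserved labels canonical uppercase, arm uppercased
  expect_equal(w$perturbation, c("NC", "PLK1", "GENE1"))
  expect_equal(unique(w$co_treatment), "VEHICLE")
})

test_that("structural errors name the offending column or line", {
  noArm <- writePlateFixture(c(
    "plate,batch,row,col,perturbation,viability,count",
    "P01,1,A,1,NC,1000,500"))
  expect_error(readPlateTable(noArm), "co_treatment")

  badRow <- writePlateFixture(c(
    "plate,batch,row,col,perturbation,co_treatment,viability,count",
    "P01,1,A,1,NC,VEHICLE,1000,500",
    "P01,1,Q,1,GENE1,VEHICLE,800,400"))
  expect_error(readPlateTable(badRow), "line 3")

  negative <- writePlateFixture(c(
    "plate,batch,row,col,perturbation,co_treatment,viability,count",
    "P01,1,A,1,NC,VEHICLE,-5,500"))
  expect_error(readPlateTable(negative), "negative viability at line 2")
})

test_that("empty wells are retained with missing readouts, never zero", {
  se <- generateScreen(screenPreset("tiny"))
  w <- wells(se)
  empty <- w[w$perturbation == "EMPTY", ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$count)))
  expect_true(all(is.na(empty$viability)))
})

test_that("screen tables round-trip losslessly, including missing values", {
  se <- generateScreen(screenPreset("tiny"))
  path <- tempfile(fileext = ".csv")
  writeScreenTable(se, path)
  back <- readPlateTable(path)
  expect_equal(wells(back)$count, wells(se)$count)
  expect_equal(wells(back)$viability, wells(se)$viability, tolerance = 1e-12)
  expect_identical(wells(back)$perturbation, wells(se)$perturbation)

  tsv <- tempfile(fileext = ".tsv")
  writeScreenTable(se, tsv)
  expect_equal(wells(readPlateTable(tsv))$count, wells(se)$count)
})

test_that("loading generated screens never warns", {
  expect_no_warning(se <- readPlateTable({
    p <- tempfile(fileext = ".csv")
    writeScreenTable(generateScreen(screenPreset("tiny")), p)
    p
  }))
  expect_s4_class(se, "ScreenExperiment")
})

test_that("a plate instance without controls warns at load", {
  path <- writePlateFixture(c(
    "plate,batch,row,col,perturbation,co_treatment,viability,count",
    "P01,1,A,1,NC,VEHICLE,1000,500",
    "P01,1,B,1,GENE1,VEHICLE,800,400"))
  expect_warning(readPlateTable(path), "PLK1")
})

test_that("cohort tables join on shared samples with warnings for drops", {
  coh <- generateCohort(cohortSimConfig(nSamples = 5, seed = 3))
  fc <- tempfile(fileext = ".csv"); fe <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  writeCohortTables(coh, fc, fe, fm)

  # drop one sample from the expression matrix: 5 clinical, 4 expressed
  ex <- read.csv(fe, check.names = FALSE)
  write.csv(ex[, -ncol(ex)], fe, row.names = FALSE)
  expect_warning(back <- readCohortTables(fc, fe, fm), "absent from expression")
  expect_equal(nSamples(back), 4)

  # a sample with no mutation rows gets an empty set
  noMut <- sampleIds(back)[lengths(mutationSets(back)) == 0]
  if (length(noMut) == 0) {
    mut <- read.csv(fm)
    write.csv(mut[mut$sample_id != sampleIds(back)[1], ], fm,
              row.names = FALSE)
    back <- suppressWarnings(readCohortTables(fc, fe, fm))
    expect_identical(mutationSets(back)[[1]], character(0))
  } else {
    expect_identical(mutationSets(back)[[noMut[1]]], character(0))
  }
})

test_that("duplicated clinical sample ids and zero overlap are errors", {
  coh <- generateCohort(cohortSimConfig(nSamples = 4, seed = 5))
  fc <- tempfile(fileext = ".csv"); fe <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  writeCohortTables(coh, fc, fe, fm)

  cl <- read.csv(fc)
  write.csv(rbind(cl, cl[1, ]), fc, row.names = FALSE)
  expect_error(readCohortTables(fc, fe, fm), "duplicated sample_id")

  write.csv(cl, fc, row.names = FALSE)
  ex <- read.csv(fe, check.names = FALSE)
  colnames(ex)[-1] <- paste0("OTHER", seq_len(ncol(ex) - 1))
  write.csv(ex, fe, row.names = FALSE)
  expect_error(readCohortTables(fc, fe, fm), "no overlapping samples")
})

test_that("cohort tables round-trip through write/read", {
  coh <- generateCohort(cohortSimConfig(nSamples = 30, seed = 11,
                                        interactionGeneset = c("KRAS", "TP53"),
                                        carrierFraction = 0.4))
  fc <- tempfile(fileext = ".csv"); fe <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  writeCohortTables(coh, fc, fe, fm)
  back <- readCohortTables(fc, fe, fm)
  expect_equal(clinicalData(back), clinicalData(coh))
  expect_equal(exprMatrix(back), exprMatrix(coh), tolerance = 1e-12)
  expect_identical(mutationSets(back), mutationSets(coh))
})

test_that("result tables round-trip, including empty and 48-row tables", {
  eff <- geneEffects(generateScreen(screenPreset("tiny")))
  path <- tempfile(fileext = ".csv")
  writeResultsTable(eff, path)
  back <- readResultsTable(path)
  expect_equal(back$log2fc_count, eff$log2fc_count, tolerance = 1e-12)
  expect_identical(back$gene, eff$gene)
  # NA p-values (2 batches only) survive the round trip as NA
  expect_identical(is.na(back$p_count), is.na(eff$p_count))

  empty <- eff[0, ]
  writeResultsTable(empty, path)
  expect_equal(length(readLines(path)), 1)  # header only

  coh <- generateCohort(cohortSimConfig(nSamples = 60, seed = 2))
  cells <- scan48(coh, "G1")$cells
  writeResultsTable(cells, path)
  expect_equal(length(readLines(path)), 49)  # header + 48 cells
})
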