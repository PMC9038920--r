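# Detection limit, internal calibration, peak assignment, normalization,
# weighted ratios, DomSet assembly.

test_that("relative detection limit keeps peaks at or above the cut", {
  pk <- data.frame(mz = c(200, 300, 400), intensity = c(100, 5, 1))
  expect_equal(applyDetectionLimit(pk, 0), pk)
  kept <- applyDetectionLimit(pk, 0.02)
  expect_equal(kept$intensity, c(100, 5))
  expect_equal(applyDetectionLimit(kept, 0.02), kept)  # idempotent
  expect_error(applyDetectionLimit(pk, 1), "relThreshold")
})

test_that("internal calibration removes an injected ppm offset", {
  set.seed(21)
  cal <- oracleGrid(510)
  cal <- cal[cal$o >= 1 & cal$mass > 150 & cal$mass < 450, ]
  cal <- cal[sample(nrow(cal), 20), c("c", "h", "o", "n", "s", "p")]
  trueMz <- monoisotopicMass(cal) - PROTON_MASS

  # calibrants already exact: identity transform
  pk <- data.frame(mz = trueMz, intensity = rep(1e6, 20))
  res <- internalCalibrate(pk, cal)
  expect_true(res$diagnostics$calibrated)
  expect_lt(max(abs(res$diagnostics$coefficients)), 1e-9)
  expect_equal(res$peaks$mz, trueMz, tolerance = 1e-12)

  # uniform +2 ppm offset: removed to < 0.05 ppm residual
  off <- data.frame(mz = trueMz * (1 + 2e-6), intensity = rep(1e6, 20))
  res2 <- internalCalibrate(off, cal)
  expect_lte(res2$diagnostics$rmsPost, res2$diagnostics$rmsPre)
  expect_lt(res2$diagnostics$rmsPost, 0.05)
  expect_equal(res2$peaks$mz, trueMz, tolerance = 1e-9)

  # fewer than 5 matches: pass-through with warning
  few <- data.frame(mz = trueMz[1:3], intensity = rep(1, 3))
  expect_warning(res3 <- internalCalibrate(few, cal[1:3, ]),
                 "calibration failed")
  expect_false(res3$diagnostics$calibrated)
  expect_equal(res3$peaks$mz, few$mz)
})

test_that("calibration never increases calibrant RMS error", {
  for (seed in 1:5) {
    set.seed(seed)
    cal <- oracleGrid(510)
    cal <- cal[cal$o >= 1 & cal$mass > 120 & cal$mass < 480, ]
    cal <- cal[sample(nrow(cal), 15), c("c", "h", "o", "n", "s", "p")]
    mz <- (monoisotopicMass(cal) - PROTON_MASS) *
      (1 + rnorm(15, 1e-6, 5e-7))
    res <- internalCalibrate(data.frame(mz = mz, intensity = 1), cal)
    expect_lte(res$diagnostics$rmsPost, res$diagnostics$rmsPre + 1e-12)
  }
})

test_that("assignment recovers simulated formulas and flags ambiguity", {
  sim <- simulatePeakList(spectrumSimConfig(nFormulas = 40, ppmSD = 0,
                                            nNoisePeaks = 0,
                                            mzWindow = c(95, 500),
                                            seed = 13))
  ds <- assignFormulas(sim$peaks, "s1")
  a <- assignments(ds)
  expect_equal(nrow(a), 40)
  tr <- sim$truth[order(sim$truth$mz), ]
  num <- function(df) data.frame(lapply(df, as.numeric))
  expect_equal(num(a[c("c", "h", "o", "n", "s", "p")]),
               num(tr[c("c", "h", "o", "n", "s", "p")]),
               ignore_attr = TRUE)
  expect_true(all(abs(a$error_ppm) < 1e-6))
  # derived columns are consistent
  expect_equal(a$ai_mod, aiMod(a$c, a$h, a$o, a$n, a$s, a$p))
  expect_equal(as.character(a$compound_class),
               as.character(classifyFormula(a$c, a$h, a$o, a$n, a$s, a$p)))
  expect_equal(sum(a$rel_intensity), 1, tolerance = 1e-12)
  # ambiguity flag mirrors the candidate count
  expect_identical(a$ambiguous, a$n_candidates >= 2)
})

test_that("normalization is idempotent and guards empty samples", {
  sim <- simulatePeakList(spectrumSimConfig(nFormulas = 3, ppmSD = 0,
                                            nNoisePeaks = 0,
                                            mzWindow = c(95, 400),
                                            seed = 2))
  pk <- sim$peaks
  pk$intensity <- c(1, 1, 2)
  ds <- assignFormulas(pk, "s1", normalize = FALSE)
  nds <- normalizeIntensities(ds)
  expect_equal(sort(assignments(nds)$rel_intensity), c(0.25, 0.25, 0.5))
  expect_equal(assignments(normalizeIntensities(nds)),
               assignments(nds))
  empty <- assignFormulas(data.frame(mz = 96.0001, intensity = 1)[0, ],
                          "e", normalize = FALSE)
  expect_error(normalizeIntensities(empty), "empty sample")
})

test_that("weighted ratios average per-formula ratios by relative intensity", {
  mkSample <- function(formulas, intensities) {
    f <- parseFormula(formulas)
    mz <- monoisotopicMass(f) - PROTON_MASS
    pk <- data.frame(mz = mz, intensity = intensities)
    assignFormulas(pk, "w", minOxygen = 0)
  }
  one <- mkSample("C6H12O6", 5)
  expect_equal(weightedRatios(one),
               c(hc = 2, oc = 1, nc = 0, sc = 0, pc = 0))
  # equal intensities average O/C 0.2 and 0.6 to 0.4
  two <- mkSample(c("C10H18O2", "C10H16O6"), c(7, 7))
  expect_equal(weightedRatios(two)[["oc"]], 0.4)
  # glucose:benzene at 0.75:0.25 -> weighted H/C 1.75
  gb <- mkSample(c("C6H12O6", "C6H6"), c(3, 1))
  expect_equal(weightedRatios(gb)[["hc"]], 0.75 * 2 + 0.25 * 1)
  # convexity: each weighted ratio lies within the per-formula range
  sim <- simulatePeakList(spectrumSimConfig(nFormulas = 25, ppmSD = 0,
                                            nNoisePeaks = 0,
                                            mzWindow = c(95, 500),
                                            seed = 31))
  ds <- assignFormulas(sim$peaks, "s")
  a <- assignments(ds)
  wr <- weightedRatios(ds)
  for (r in names(wr)) {
    expect_gte(wr[[r]], min(a[[r]]))
    expect_lte(wr[[r]], max(a[[r]]))
  }
})

test_that("DomSet assembles the union of formulas with zeros for absences", {
  sim <- simulateDomGroups(nPerGroup = 2, nFormulas = 30, seed = 8)
  x <- relIntensityMatrix(sim$set)
  expect_equal(unname(rowSums(x)), rep(1, nrow(x)), tolerance = 1e-12)
  expect_true(all(x >= 0))
  # rowData carries the formula annotations
  rd <- SummarizedExperiment::rowData(sim$set)
  expect_true(all(c("ai_mod", "compound_class", "hc", "oc") %in%
                    colnames(rd)))
  expect_error(domSet(list()), "length")
})
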