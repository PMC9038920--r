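# The qSIP chain: weighted densities, calibrations, molecular weights, EAF.

test_that("weighted mean density reproduces direct weighted-mean arithmetic", {
  wm <- function(df) weightedMeanDensity(df, minQuantified = 1)
  expect_equal(wm(data.frame(density = 1.70, copies = 100)), 1.70)
  expect_equal(wm(data.frame(density = c(1.68, 1.72), copies = c(50, 50))),
               1.70)
  expect_equal(wm(data.frame(density = c(1.66, 1.70), copies = c(10, 90))),
               1.696)
})

test_that("degenerate gradients are rejected", {
  expect_error(
    weightedMeanDensity(data.frame(density = c(1.68, 1.70, 1.72),
                                   copies = c(0, 0, 0))),
    "all copies")
  expect_error(
    weightedMeanDensity(data.frame(density = c(1.68, 1.70, 1.72),
                                   copies = c(0, 5, 5))),
    "quantified fraction")
  # below-detection fractions contribute nothing
  expect_equal(
    weightedMeanDensity(data.frame(density = c(1.66, 1.68, 1.70, 1.72),
                                   copies = c(1e6, 10, 20, 10),
                                   below_detection = c(TRUE, FALSE, FALSE,
                                                       FALSE))),
    (1.68 * 10 + 1.70 * 20 + 1.72 * 10) / 40)
})

test_that("GC-density calibrations evaluate and invert correctly", {
  expect_equal(round(densityFromGC(0.315), 2), 1.69)
  expect_equal(densityFromGC(0), 1.660)
  expect_equal(densityFromGC(1), 1.758)
  expect_error(densityFromGC(1.2), "GC")

  expect_equal(gcFromDensity(1.646057), 0)
  expect_equal(gcFromDensity(1.729563), 1)
  expect_equal(gcFromDensity(1.68781), 0.5, tolerance = 1e-4)
  # mutual inverses to 1e-12 on the EAF-chain calibration
  g <- seq(0, 1, by = 0.05)
  expect_equal(gcFromDensity(densityFromGC(g, "hungate")), g,
               tolerance = 1e-12)
  expect_warning(out <- gcFromDensity(1.7330), "clamping")
  expect_equal(out, 1)
  expect_error(gcFromDensity(1.7400), "implausible")
})

test_that("molecular-weight steps match the linear forms", {
  expect_equal(lightMolecularWeight(0), 307.691)
  expect_equal(lightMolecularWeight(1), 308.187)
  expect_equal(lightMolecularWeight(0.5), 307.939)

  m <- 307.939
  expect_equal(labeledMolecularWeight(1.700, 1.700, m), m)
  expect_equal(labeledMolecularWeight(1.717, 1.700, m), 311.018,
               tolerance = 1e-5)
  expect_equal(labeledMolecularWeight(1.7085, 1.700, m), 309.479,
               tolerance = 1e-5)
  expect_error(labeledMolecularWeight(1.7, 0, m), "positive")

  expect_equal(maxHeavyMolecularWeight(0, m), m + 9.974564)
  expect_equal(maxHeavyMolecularWeight(1, m), m + 9.4758358)
  expect_equal(maxHeavyMolecularWeight(0.5, m), m + 9.7252, tolerance = 1e-6)
  # heavy gain positive across the whole GC range
  g <- seq(0, 1, by = 0.01)
  ml <- lightMolecularWeight(g)
  expect_true(all(maxHeavyMolecularWeight(g, ml) > ml))
})

test_that("excess atom fraction has the stated fixed points and bound", {
  m <- 307.939
  hm <- maxHeavyMolecularWeight(0.5, m)
  expect_equal(excessAtomFraction(m, m, hm), 0)
  expect_equal(excessAtomFraction(hm, m, hm), 1 - NAT13C)
  expect_equal(round(excessAtomFraction(hm, m, hm), 5), 0.98889)
  expect_error(excessAtomFraction(m, m, m), "degenerate")
  # negative (noise) values come through unclipped
  expect_lt(excessAtomFraction(m - 0.5, m, hm), 0)
  expect_equal(eafToAtomPercent(0.3), 30)
})

test_that("EAF is scale invariant in copies and monotone in W_lab", {
  for (seed in 1:5) {
    sim <- simulateGradientPair(gradientSimConfig(taxonGC = 0.4,
                                                  trueEAF = 0.2,
                                                  qpcrCV = 0.2, seed = seed))
    scaleCopies <- function(p, k) {
      fr <- fractions(p)
      fr$copies <- fr$copies * k
      GradientProfile(sampleId(p), markerGene(p), labelState(p), fr,
                      replicateId = replicateId(p))
    }
    r1 <- eafFromProfiles(sim$labeled, sim$unlabeled)
    r2 <- eafFromProfiles(scaleCopies(sim$labeled, 17.3),
                          scaleCopies(sim$unlabeled, 0.02))
    expect_equal(eafSummary(r1)$mean, eafSummary(r2)$mean,
                 tolerance = 1e-12)
  }
  # monotonicity in W_lab, all else fixed
  m <- lightMolecularWeight(0.5)
  hm <- maxHeavyMolecularWeight(0.5, m)
  wl <- 1.70
  wlab <- seq(1.70, 1.74, by = 0.005)
  eafs <- excessAtomFraction(labeledMolecularWeight(wlab, wl, m), m, hm)
  expect_true(all(diff(eafs) > 0))
  expect_true(all(eafs <= 1 - NAT13C))
})

test_that("profile pairing validates markers and supports both schemes", {
  sim <- simulateGradientPair(gradientSimConfig(qpcrCV = 0))
  other <- GradientProfile("x", "16S", "unlabeled",
                           fractions(sim$unlabeled))
  expect_error(eafFromProfiles(sim$labeled, other), "mix markers")
  expect_error(eafFromProfiles(sim$unlabeled, sim$unlabeled),
               "pairing error")

  # identical labeled and unlabeled profiles give EAF 0 exactly
  asLabeled <- GradientProfile("sim", "18S", "labeled",
                               fractions(sim$unlabeled))
  r <- eafFromProfiles(asLabeled, sim$unlabeled)
  expect_identical(eafSummary(r)$mean, 0)
  expect_identical(eafPairs(r)$dW, 0)

  # three replicate pairs: per-pair EAFs plus mean/sd, negative values kept
  labs <- lapply(1:3, function(i) {
    s <- simulateGradientPair(gradientSimConfig(trueEAF = 0.3, qpcrCV = 0.2,
                                                seed = i))
    GradientProfile("s", "18S", "labeled", fractions(s$labeled),
                    replicateId = paste0("r", i))
  })
  ctls <- lapply(1:3, function(i) {
    s <- simulateGradientPair(gradientSimConfig(trueEAF = 0.3, qpcrCV = 0.2,
                                                seed = i + 100))
    GradientProfile("s", "18S", "unlabeled", fractions(s$unlabeled),
                    replicateId = paste0("r", i))
  })
  r <- eafFromProfiles(labs, ctls)
  expect_equal(nrow(eafPairs(r)), 3)
  expect_equal(eafSummary(r)$mean, mean(eafPairs(r)$eaf))
  expect_equal(eafSummary(r)$sd, sd(eafPairs(r)$eaf))
  expect_gte(eafSummary(r)$mean_clipped, eafSummary(r)$mean)

  rm <- eafFromProfiles(labs, ctls, pairing = "mean-control")
  expect_equal(length(unique(eafPairs(rm)$W_light)), 1)

  # seeded bootstrap is reproducible
  b1 <- eafFromProfiles(labs, ctls, bootstrap = 200, seed = 42)
  b2 <- eafFromProfiles(labs, ctls, bootstrap = 200, seed = 42)
  expect_identical(eafSummary(b1)$ci, eafSummary(b2)$ci)
  expect_length(eafSummary(b1)$ci, 2)
})

test_that("qPCR standard curves quantify and flag detection", {
  sc <- StandardCurve(slope = -3.3219, intercept = 38, rSquared = 0.999)
  expect_equal(efficiency(sc), 1.00, tolerance = 1e-4)
  expect_true(isValidCurve(sc))
  q <- quantifyFromCq(c(38, 36, 20), sc)
  expect_equal(q$copies[1], 1, tolerance = 1e-6)
  expect_identical(q$below_detection, c(TRUE, TRUE, FALSE))

  # 10-fold dilution spacing equals one log10 under 100% efficiency
  expect_equal(quantifyFromCq(38 - 3.3219, sc)$copies, 10, tolerance = 1e-4)

  weak <- StandardCurve(slope = -4.5, intercept = 38, rSquared = 0.99)
  expect_false(isValidCurve(weak))   # efficiency ~67%
  expect_error(quantifyFromCq(30, weak), "rejected")
  expect_error(StandardCurve(slope = 3.3, intercept = 38, rSquared = 0.99),
               "negative")
})
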