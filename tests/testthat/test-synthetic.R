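# Simulators: determinism, conservation, round trips, group structure.

test_that("gradient simulator conserves copies and is seed-deterministic", {
  cfg <- gradientSimConfig(taxonGC = 0.4, trueEAF = 0.2, qpcrCV = 0,
                           totalCopies = 5e5, seed = 3)
  sim <- simulateGradientPair(cfg)
  expect_equal(sum(fractions(sim$labeled)$copies), 5e5,
               tolerance = 1e-6)
  expect_equal(sum(fractions(sim$unlabeled)$copies), 5e5,
               tolerance = 1e-6)
  expect_equal(nrow(fractions(sim$labeled)), 15)

  noisy <- gradientSimConfig(trueEAF = 0.2, qpcrCV = 0.3, seed = 11)
  s1 <- simulateGradientPair(noisy)
  s2 <- simulateGradientPair(noisy)
  expect_identical(fractions(s1$labeled), fractions(s2$labeled))
  expect_identical(fractions(s1$unlabeled), fractions(s2$unlabeled))

  # EAF 0 without noise: labeled and unlabeled coincide
  s0 <- simulateGradientPair(gradientSimConfig(trueEAF = 0, qpcrCV = 0))
  expect_equal(fractions(s0$labeled)$copies,
               fractions(s0$unlabeled)$copies)
  expect_equal(s0$truth$W_lab, s0$truth$W_light)
})

test_that("bands outside the density span are a configuration error", {
  expect_error(
    simulateGradientPair(gradientSimConfig(taxonGC = 0.9, trueEAF = 0.9,
                                           densitySpan = c(1.66, 1.72))),
    "config error")
})

test_that("detection floor flags weak tail fractions", {
  sim <- simulateGradientPair(gradientSimConfig(taxonGC = 0.5, qpcrCV = 0,
                                                totalCopies = 1e6,
                                                detectionFloor = 100))
  fr <- fractions(sim$unlabeled)
  expect_true(any(fr$below_detection))
  expect_identical(fr$below_detection, fr$copies < 100)
  # flagged fractions do not move the weighted mean
  w <- weightedMeanDensity(sim$unlabeled)
  keep <- !fr$below_detection
  expect_equal(w, sum(fr$density[keep] * fr$copies[keep]) /
                 sum(fr$copies[keep]))
})

test_that("peak-list simulator respects the window and its seed", {
  cfg <- spectrumSimConfig(nFormulas = 60, nNoisePeaks = 15, seed = 5)
  sim <- simulatePeakList(cfg)
  expect_equal(nrow(sim$peaks), 75)
  expect_equal(sum(sim$truth$is_noise), 15)
  expect_true(all(sim$peaks$mz >= 95 - 1e-3 & sim$peaks$mz <= 1000 + 1e-3))
  expect_true(all(sim$peaks$intensity > 0))
  sim2 <- simulatePeakList(cfg)
  expect_identical(sim$peaks, sim2$peaks)
  # truth rows align with peaks
  expect_equal(sim$truth$mz, sim$peaks$mz)
  sig <- !sim$truth$is_noise
  ppmErr <- (sim$truth$mz[sig] -
               (monoisotopicMass(sim$truth[sig, c("c", "h", "o", "n", "s",
                                                  "p")]) - PROTON_MASS)) /
    sim$truth$mz[sig] * 1e6
  expect_lt(max(abs(ppmErr)), 5 * 0.2)  # ppmSD = 0.2, generous bound
})

test_that("zero mass error round trip recovers every truth formula", {
  sim <- simulatePeakList(spectrumSimConfig(nFormulas = 50, ppmSD = 0,
                                            nNoisePeaks = 0,
                                            mzWindow = c(95, 500),
                                            seed = 23))
  ds <- assignFormulas(sim$peaks, "rt")
  a <- assignments(ds)
  expect_equal(nrow(a), 50)
  tr <- sim$truth
  expect_equal(as.numeric(unlist(a[c("c", "h", "o", "n", "s", "p")])),
               as.numeric(unlist(tr[c("c", "h", "o", "n", "s", "p")])))
})

test_that("group simulator needs two groups of two and separates on demand", {
  expect_error(simulateDomGroups(nPerGroup = 1), "2 samples per group")
  expect_error(simulateDomGroups(groups = list(a = c())), "2 groups")

  strong <- simulateDomGroups(
    nPerGroup = 3,
    groups = list(water = c(),
                  sediment = c("Unsaturated with N" = 8,
                               "Highly unsaturated O-poor" = 0.25)),
    nFormulas = 80, seed = 17)
  d <- brayCurtis(strong$set)
  grp <- strong$truth$groups
  within <- d[outer(grp, grp, "==") & upper.tri(d)]
  between <- d[outer(grp, grp, "!=") & upper.tri(d)]
  expect_gt(mean(between), mean(within))

  # PCoA axis 1 separates groups: positive silhouette on axis-1 coordinates
  ord <- principalCoordinates(d)
  ax1 <- ord$coordinates[, 1]
  sil <- vapply(seq_along(ax1), function(i) {
    own <- mean(abs(ax1[i] - ax1[grp == grp[i]][-match(i, which(grp == grp[i]))]))
    oth <- mean(abs(ax1[i] - ax1[grp != grp[i]]))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil), 0)
})

test_that("zero effect size leaves within and between groups alike", {
  diffs <- vapply(1:30, function(seed) {
    sim <- simulateDomGroups(nPerGroup = 2,
                             groups = list(a = c(), b = c()),
                             nFormulas = 40, seed = seed)
    d <- brayCurtis(sim$set)
    grp <- sim$truth$groups
    mean(d[outer(grp, grp, "!=") & upper.tri(d)]) -
      mean(d[outer(grp, grp, "==") & upper.tri(d)])
  }, 0)
  # Monte-Carlo check: mean difference indistinguishable from zero
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})
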