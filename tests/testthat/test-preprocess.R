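test_that("signal flooring raises only sub-floor values", {
  ie <- makeIntensity(matrix(c(3, 5, 4096, rep(100, 9 * 4 - 3)), nrow = 3),
                      timepoints = c(3, 6, 12, 24, 36, 48),
                      replicates = c("A", "B"))
  fl <- floorSignal(ie, 5)
  sig <- assay(fl, "signal")
  expect_equal(sig[1, 1], 5)     # 3 -> 5
  expect_equal(sig[2, 1], 5)     # boundary unchanged
  expect_equal(sig[3, 1], 4096)  # untouched
  expect_error(floorSignal(ie, 0), class = "cypwaves_config_error")
})

test_that("baseline selection picks the median-of-medians array", {
  m <- matrix(rep(c(10, 30, 20), each = 4), nrow = 4)
  colnames(m) <- c("a1", "a2", "a3")
  expect_equal(selectBaselineArray(m), "a3")   # median 20

  same <- matrix(5, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(selectBaselineArray(same), "x") # tie -> lowest index

  # 24 simulated arrays vs a brute-force oracle
  sim <- simulateTimecourse(arrayDesign(nProbes = 300), seed = 21)
  sig <- assay(sim$intensities, "signal")
  meds <- apply(sig, 2L, median)
  ord <- order(meds)
  oracle <- colnames(sig)[ord[floor((length(meds) + 1) / 2)]]
  expect_equal(selectBaselineArray(sim$intensities), oracle)
})

test_that("rank-invariant selection keeps rank-preserved features", {
  x <- setNames(sort(rnorm(80, 10, 2)), sprintf("f%02d", 1:80))
  expect_setequal(rankInvariantProbes(x, x, minSize = 1L), names(x))
  # a strictly monotone transform preserves all ranks
  y <- 2 * x + 1
  expect_setequal(rankInvariantProbes(y, x, minSize = 1L), names(x))

  # planted rank swaps: swap 5 well-separated pairs and compare with the
  # independently coded oracle
  set.seed(77)
  base <- setNames(seq(4, 14, length.out = 50) + rnorm(50, 0, 0.01),
                   sprintf("g%02d", 1:50))
  tgt <- base
  for (pr in list(c(1, 25), c(5, 40), c(10, 45), c(15, 30), c(20, 50))) {
    tmp <- tgt[pr[1]]
    tgt[pr[1]] <- tgt[pr[2]]
    tgt[pr[2]] <- tmp
  }
  got <- rankInvariantProbes(tgt, base, thresholdFraction = 0.05,
                             minSize = 1L)
  expect_setequal(got, rankInvariantOracle(tgt, base, 0.05))

  # an everywhere-shifted ranking admits no invariant probe
  shifted <- setNames(base[c(11:50, 1:10)], names(base))
  expect_error(rankInvariantProbes(shifted, base,
                                   thresholdFraction = 0.02, minSize = 1L),
               class = "cypwaves_usage_error")
})

test_that("normalization curves reproduce planted monotone relations", {
  x <- seq(4, 14, length.out = 300)
  ident <- fitNormalizationCurve(x, x, window = 11L)
  xs <- seq(4.2, 13.8, length.out = 50)
  expect_equal(cypwaves:::evalCurve(ident, xs), xs, tolerance = 1e-9)

  shift <- fitNormalizationCurve(x, x + 1, window = 11L)
  expect_equal(cypwaves:::evalCurve(shift, xs), xs + 1, tolerance = 1e-9)

  set.seed(5)
  tgt <- runif(500, 4, 14)
  bas <- 0.9 * tgt + 0.5 + rnorm(500, 0, 0.05)
  cv <- fitNormalizationCurve(tgt, bas)
  central <- seq(quantile(tgt, 0.05), quantile(tgt, 0.95), length.out = 100)
  err <- abs(cypwaves:::evalCurve(cv, central) - (0.9 * central + 0.5))
  expect_lt(max(err), 0.1)
  expect_true(all(diff(cv$y) >= 0))          # monotone control points
  expect_error(fitNormalizationCurve(x[1:5], x[1:5], window = 11L),
               class = "cypwaves_usage_error")
})

test_that("array normalization fixes the baseline and preserves order", {
  sim <- simulateTimecourse(arrayDesign(nProbes = 400),
                            mix = archetypeMix(0, 0, 0, 1, 0),
                            sigmaRep = 0.1, sigmaSpot = 0.05, seed = 22)
  fl <- floorSignal(sim$intensities)
  model <- fitNormalization(fl)
  norm <- normalizeArrays(fl, model)
  base <- baselineArray(model)
  lg <- log2(assay(norm, "signal"))
  nl <- assay(norm, "normlog2")
  expect_equal(nl[, base], lg[, base], tolerance = 1e-12)  # fixed point
  for (aid in sample(setdiff(colnames(nl), base), 3L)) {
    ord <- order(lg[, aid])
    expect_true(all(diff(nl[ord, aid]) >= 0))  # monotone mapping
    expect_true(all(diff(normalizationCurves(model)[[aid]]$y) >= 0))
  }
  # an array missing from the model is refused
  model2 <- model
  model2@curves[[1]] <- NULL
  model2@invariant[[1]] <- NULL
  expect_error(normalizeArrays(fl, model2), class = "cypwaves_usage_error")
})

test_that("planted warps are removed and cross-array variation shrinks", {
  # zero biological noise isolates the warp: recovery must be near exact
  sim <- simulateTimecourse(arrayDesign(nProbes = 500),
                            mix = archetypeMix(0, 0, 0, 1, 0),
                            sigmaRep = 0, sigmaSpot = 0, seed = 23)
  fl <- floorSignal(sim$intensities)
  norm <- normalizeArrays(fl, fitNormalization(fl))
  nl <- assay(norm, "normlog2")
  base <- S4Vectors::metadata(norm)$baseline
  dev <- abs(nl[, colnames(nl) != base] - nl[, base])
  expect_lt(median(dev), 0.1)

  # with replicate noise, normalization should still reduce the
  # between-array coefficient of variation for nearly all flat probes
  sim2 <- simulateTimecourse(arrayDesign(nProbes = 600),
                             mix = archetypeMix(0, 0, 0, 1, 0), seed = 24)
  fl2 <- floorSignal(sim2$intensities)
  norm2 <- normalizeArrays(fl2, fitNormalization(fl2))
  before <- assay(averageDuplicates(fl2), "signal")
  after <- assay(averageDuplicates(norm2), "signal")
  cv <- function(m) apply(m, 1L, sd) / rowMeans(m)
  expect_gte(mean(cv(after) < cv(before)), 0.95)
})

test_that("duplicate averaging pools spots and aggregates flags", {
  sig <- matrix(100, 4, 12)
  sig[1, ] <- 4; sig[2, ] <- 6          # probe P001: spots 4 and 6
  sat <- matrix(FALSE, 4, 12); sat[3, 5] <- TRUE
  abv <- matrix(TRUE, 4, 12); abv[3, ] <- FALSE; abv[4, ] <- FALSE
  abv[4, 7] <- TRUE                     # P002 above background once
  ie <- makeIntensity(sig, spots = 2L, replicates = c("A", "B"),
                      saturated = sat, above = abv)
  pr <- averageDuplicates(ie)
  expect_equal(unname(assay(pr, "signal")[1, 1]), 5)  # mean(4, 6)
  rd <- rowData(pr)
  expect_true(rd$any_saturated[2])      # one saturated spot flags the probe
  expect_false(rd$any_saturated[1])
  expect_true(rd$any_above_background[2])
  single <- makeIntensity(matrix(7, 2, 12), spots = 1L,
                          replicates = c("A", "B"))
  expect_equal(unname(assay(averageDuplicates(single), "signal")[1, 1]), 7)
})

test_that("probe QC removes saturated then never-above-background probes", {
  n <- 200L
  sig <- matrix(100, n, 12)
  sat <- matrix(FALSE, n, 12)
  abv <- matrix(TRUE, n, 12)
  sat[1:7, 3] <- TRUE                   # 7 probes saturated once
  abv[8:19, ] <- FALSE                  # 12 probes never above background
  abv[20, ] <- FALSE; abv[20, 11] <- TRUE  # above background exactly once
  sat[8, ] <- TRUE                      # overlap: precedence to saturation
  ie <- makeIntensity(sig, spots = 1L, replicates = c("A", "B"),
                      saturated = sat, above = abv)
  qc <- qcFilterProbes(averageDuplicates(ie))
  counts <- qcCounts(qc$report)
  expect_equal(unname(counts["removed_saturated"]), 8L)
  expect_equal(unname(counts["removed_background"]), 11L)
  expect_equal(unname(counts["retained"]), n - 8L - 11L)
  expect_equal(sum(counts[2:4]), unname(counts["input"]))  # conservation
  expect_true("P020" %in% rownames(qc$matrix))  # single instance suffices
  clean <- makeIntensity(sig, spots = 1L, replicates = c("A", "B"))
  qc2 <- qcFilterProbes(averageDuplicates(clean))
  expect_equal(unname(qcCounts(qc2$report)["retained"]), n)
})
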