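test_that("z-normalization standardizes rows with population SD", {
  z <- zNormalize(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  m <- rbind(runif(6, 1, 10), rep(4, 6), rnorm(6))
  z2 <- zNormalize(m)
  expect_equal(unname(attr(z2, "degenerate")), c(FALSE, TRUE, FALSE))
  expect_equal(unname(z2[2, ]), rep(0, 6))
  nd <- z2[!attr(z2, "degenerate"), ]
  expect_equal(unname(rowMeans(nd)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(nd, 1L, function(v) sqrt(mean(v^2)))), c(1, 1),
               tolerance = 1e-12)
  # idempotence on non-degenerate rows
  expect_equal(unname(zNormalize(nd)[, ]), unname(nd), tolerance = 1e-12)
  expect_error(zNormalize(matrix(1, 3, 1)), class = "cypwaves_usage_error")
})

test_that("hierarchically initialized K-means recovers planted archetypes", {
  rec <- waveRecoverySim(200, sigmaRep = 0, seed = 41)
  km <- kmeansClusters(rec$z, K = 4L)
  expect_equal(mclust::adjustedRandIndex(km$assignment, rec$labels), 1.0)

  one <- kmeansClusters(rec$z, K = 1L)
  expect_equal(unname(unique(one$assignment)), 1L)
  expect_error(kmeansClusters(rec$z[1:3, ], K = 5L),
               class = "cypwaves_usage_error")

  dup <- rbind(rec$z[1:20, ], rec$z[1, , drop = FALSE])
  rownames(dup) <- c(rownames(rec$z)[1:20], "copy")
  kd <- kmeansClusters(dup, K = 3L)
  expect_equal(unname(kd$assignment["copy"]),
               unname(kd$assignment[rownames(rec$z)[1]]))
  # deterministic: same input, same result
  expect_identical(kmeansClusters(rec$z, K = 4L)$assignment, km$assignment)
})

test_that("CAST partitions by affinity and honours the 0-1 threshold", {
  z <- zNormalize(matrix(rep(c(1, 3, 2, 5, 4, 6), 5), 5, byrow = TRUE))
  ca <- castClusters(z)
  expect_equal(length(unique(ca$assignment)), 1L)  # identical profiles

  up <- c(1, 2, 3, 4, 5, 6)
  anti <- rbind(matrix(rep(up, 4), 4, byrow = TRUE),
                matrix(rep(rev(up), 4), 4, byrow = TRUE))
  rownames(anti) <- sprintf("g%d", 1:8)
  ca2 <- castClusters(zNormalize(anti), affinity = 0.7)
  expect_equal(length(unique(ca2$assignment)), 2L)  # affinity 0 across groups
  expect_true(all(table(ca2$assignment) == 4L))

  # partition + termination invariant on a planted mixture
  rec <- waveRecoverySim(120, sigmaRep = 0.25, seed = 42)
  ca3 <- castClusters(rec$z)
  expect_false(anyNA(ca3$assignment))
  aff <- castMemberAffinities(rec$z, ca3$assignment)
  expect_true(all(aff >= 0.7 - 1e-12))
  expect_error(castClusters(matrix(1, 3, 1)), class = "cypwaves_usage_error")
})

test_that("CAST matches an independent implementation of the greedy rule", {
  # plain re-implementation, kept deliberately simple
  castOracle <- function(m, th = 0.7) {
    cc <- suppressWarnings(cor(t(m)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    S <- (cc + 1) / 2
    n <- nrow(m)
    res <- rep(NA_integer_, n)
    free <- seq_len(n)
    k <- 0L
    while (length(free)) {
      k <- k + 1L
      conn <- rowSums(S[free, free, drop = FALSE]) - 1
      C <- free[which.max(conn)]
      free <- setdiff(free, C)
      repeat {
        moved <- FALSE
        repeat {
          if (!length(free)) break
          a <- vapply(free, function(g) mean(S[g, C]), numeric(1))
          i <- which.max(a)
          if (a[i] >= th) {
            C <- c(C, free[i]); free <- free[-i]; moved <- TRUE
          } else break
        }
        repeat {
          if (length(C) <= 1L) break
          a <- vapply(seq_along(C), function(j)
            mean(S[C[j], C[-j]]), numeric(1))
          j <- which.min(a)
          if (a[j] < th) {
            free <- c(free, C[j]); C <- C[-j]; moved <- TRUE
          } else break
        }
        if (!moved) break
      }
      res[C] <- k
    }
    res
  }
  for (seed in c(51, 52, 53)) {
    set.seed(seed)
    m <- zNormalize(matrix(rnorm(12 * 6), 12))
    rownames(m) <- sprintf("g%02d", 1:12)
    got <- castClusters(m)$assignment
    expect_equal(unname(got), castOracle(m))
  }
})

test_that("affinity search retrieves maternal-profile genes", {
  sim <- simulateTimecourse(arrayDesign(nProbes = 60, spotsPerProbe = 1L),
                            mix = archetypeMix(0.3, 0.4, 0, 0.3, 0),
                            sigmaRep = 0, sigmaSpot = 0,
                            warpSlopeRange = c(1, 1),
                            warpInterceptRange = c(0, 0),
                            waveCenters = 24, seed = 43)
  z <- zNormalize(timepointMeans(averageDuplicates(sim$intensities)))
  hits <- affinitySearch(z)
  truth <- sim$truth$probes
  maternal <- truth$probe_id[truth$archetype == "maternal_decay"]
  expect_setequal(hits, maternal)

  # a gene's own profile is a perfect seed (affinity 1)
  self <- affinitySearch(z, seedProfile = z[maternal[1], ])
  expect_true(maternal[1] %in% self)

  flat <- matrix(0, 1, 6, dimnames = list("flat", NULL))
  expect_length(affinitySearch(flat), 0L)  # affinity 0.5 < 0.7
})

test_that("modality classification separates waves, decay and bimodal", {
  tp <- c("3", "6", "12", "24", "36", "48")
  bi <- matrix(c(2, -1, -1, -1, -1, 1.5), 1, dimnames = list("b", tp))
  expect_equal(classifyModality(bi)$class, "bimodal")

  dec <- zNormalize(matrix(6:1, 1, dimnames = list("d", tp)))
  expect_equal(classifyModality(dec)$class, "peak_at_start")

  const <- matrix(0, 1, 6, dimnames = list("c", tp))
  expect_equal(classifyModality(const)$class, "flat")

  wave <- zNormalize(matrix(c(-1, 0, 3, 0, -1, -1), 1,
                            dimnames = list("w", tp)))
  res <- classifyModality(wave)
  expect_equal(res$class, "unimodal")
  expect_equal(res$peak_timepoint, "12")
})
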