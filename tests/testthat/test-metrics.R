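test_that("relative frequencies normalize labeled counts only", {
  f <- relativeFrequencies(c(150, 50, 50, rep(0, 7)))
  expect_equal(unname(f[1:3]), c(0.6, 0.2, 0.2))
  expect_equal(sum(f), 1, tolerance = 1e-9)

  mono <- relativeFrequencies(c(rep(0, 9), 42))
  expect_equal(unname(mono), c(rep(0, 9), 1))

  set.seed(1)
  for (i in 1:20) {
    expect_equal(sum(relativeFrequencies(rpois(10, 20) + 1)), 1, tolerance = 1e-9)
  }
  expect_error(relativeFrequencies(rep(0, 10)), "empty|zero")
})

test_that("dominance and top-two dominance are order statistics of the composition", {
  expect_equal(dominance(c(1, rep(0, 9))), 1)
  expect_equal(dominance(rep(c(0.25, 0), c(4, 6))), 0.25)
  expect_equal(dominance(c(0.6, 0.2, 0.2, rep(0, 7))), 0.6)

  expect_equal(top2Sum(c(1, rep(0, 9))), 1)
  expect_equal(top2Sum(c(0.5, 0.3, 0.2, rep(0, 7))), 0.8)
  expect_equal(top2Sum(rep(0.1, 10)), 0.2)

  # invariance under permutation of color labels
  set.seed(2)
  for (i in 1:20) {
    f <- randomComposition(10)
    p <- sample(10)
    expect_equal(dominance(f[p]), dominance(f))
    expect_equal(top2Sum(f[p]), top2Sum(f))
  }
})

test_that("divergence index is the L1 distance and a metric on the simplex", {
  unif <- uniformExpectedFrequencies()
  expect_equal(divergenceIndex(rep(0.1, 10), unif), 0)
  expect_equal(divergenceIndex(c(1, rep(0, 9)), unif), 1.8)
  expect_equal(divergenceIndex(c(0.5, 0.5, rep(0, 8)), unif), 1.6)

  set.seed(3)
  for (i in 1:200) {
    a <- randomComposition(10, sparse = i %% 2 == 0)
    b <- randomComposition(10, sparse = i %% 3 == 0)
    c_ <- randomComposition(10)
    expect_equal(divergenceIndex(a, b), l1Oracle(a, b), tolerance = 1e-12)
    expect_equal(divergenceIndex(a, b), divergenceIndex(b, a))
    expect_lte(divergenceIndex(a, c_),
               divergenceIndex(a, b) + divergenceIndex(b, c_) + 1e-12)
    expect_lte(divergenceIndex(a, b), 2)
  }
  expect_equal(divergenceIndex(rep(0.1, 10), rep(0.1, 10)), 0)
  expect_error(divergenceIndex(rep(0.5, 2), rep(0.1, 10)), "state space")
})

test_that("meander index is the cumulative path length through frequency space", {
  const <- matrix(rep(c(0.3, 0.7, rep(0, 8)), 5), nrow = 5, byrow = TRUE)
  expect_equal(meanderIndex(const), rep(0, 5))

  two <- rbind(c(0.6, 0.4, rep(0, 8)), c(0.4, 0.6, rep(0, 8)))
  expect_equal(meanderIndex(two)[2], sqrt(0.04 + 0.04), tolerance = 1e-9)

  three <- rbind(two, two[1, ])
  expect_equal(meanderIndex(three)[3], 2 * sqrt(0.08), tolerance = 1e-9)

  expect_equal(meanderIndex(matrix(randomComposition(10), nrow = 1)), 0)

  # alternative norms
  expect_equal(meanderIndex(two, norm = "l1")[2], 0.4)
  expect_equal(meanderIndex(two, norm = "sq")[2], 0.08)
  unif <- uniformExpectedFrequencies()
  dd <- meanderIndex(two, norm = "ddiv", expected = unif)
  expect_equal(dd[2], abs(divergenceIndex(two[2, ], unif) -
                          divergenceIndex(two[1, ], unif)))
  expect_error(meanderIndex(two, norm = "ddiv"), "expected")
})

test_that("meander agrees exactly with a brute-force path-length oracle", {
  set.seed(4)
  for (i in 1:200) {
    nT <- sample(2:8, 1)
    m <- t(replicate(nT, randomComposition(10, sparse = i %% 2 == 0)))
    expect_equal(meanderIndex(m), pathLengthOracle(m), tolerance = 1e-12)
    expect_equal(meanderIndex(m, norm = "l1"),
                 pathLengthOracle(m, function(d) sum(abs(d))), tolerance = 1e-12)
    # ddiv path equals the brute-force divergence path on the same series
    unif <- rep(0.1, 10)
    divs <- apply(m, 1, l1Oracle, b = unif)
    ddOracle <- c(0, cumsum(abs(diff(divs))))
    expect_equal(meanderIndex(m, norm = "ddiv", expected = unif), ddOracle,
                 tolerance = 1e-12)
  }
})

test_that("meander is additive over concatenated segments sharing a boundary", {
  set.seed(5)
  for (i in 1:20) {
    a <- t(replicate(4, randomComposition(10)))
    b <- t(replicate(3, randomComposition(10)))
    whole <- rbind(a, b)
    mWhole <- meanderIndex(whole)
    mA <- meanderIndex(a)
    mB <- meanderIndex(rbind(a[4, ], b))  # segment starting at the boundary
    expect_equal(mWhole[length(mWhole)], mA[4] + mB[4], tolerance = 1e-12)
  }
})

test_that("sparse observations are discarded below 50% occupation, strictly", {
  expect_identical(filterSparse(c(0.4, 0.5, 1.0)), c(FALSE, TRUE, TRUE))

  cnt <- matrix(rep(10, 30), nrow = 10, dimnames = list(colorStates(), NULL))
  gce <- GCExperiment(cnt, mouse_id = "m1", gc_id = c("A", "B", "C"),
                      time_h = c(1, 2, 3) * 24,
                      occupation = c(0.49, 0.5, 0.9),
                      total_examined = rep(200, 3))
  kept <- filterSparse(gce)
  expect_equal(ncol(kept), 2L)
  info <- S4Vectors::metadata(kept)$sparse_filter
  expect_equal(info$n_in, 3L)
  expect_equal(info$n_discarded, 1L)
  expect_match(info$reason, "occupation")
})

test_that("inversion events require a dominant identity change above threshold", {
  mk <- function(...) {
    rows <- list(...)
    m <- matrix(0, nrow = length(rows), ncol = 10,
                dimnames = list(NULL, colorStates()))
    for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
    # fill the remainder uniformly over the last color to keep rows on the simplex
    m[, 10] <- 1 - rowSums(m[, -10, drop = FALSE])
    m
  }
  # same color stays dominant: no event
  none <- mk(c(cRFP = 0.65), c(cRFP = 0.7), c(cRFP = 0.8))
  expect_equal(nrow(detectInversions(none)), 0L)

  # R -> Y -> C at 0.6: a double inversion is two events
  dbl <- mk(c(cRFP = 0.6, cYFP = 0.2, mCFP = 0.1),
            c(cYFP = 0.6, cRFP = 0.2, mCFP = 0.1),
            c(mCFP = 0.6, cYFP = 0.2, cRFP = 0.1))
  ev <- detectInversions(dbl, times = c(11, 13, 19))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$outgoing_color, c("cRFP", "cYFP"))
  expect_equal(ev$incoming_color, c("cYFP", "mCFP"))
  expect_equal(ev$time_from, c(11, 13))
  expect_true(all(ev$outgoing_color != ev$incoming_color))

  # dominance switches but never reaches the threshold: no event
  low <- mk(c(cRFP = 0.35, cYFP = 0.30, mCFP = 0.2),
            c(cYFP = 0.38, cRFP = 0.30, mCFP = 0.2))
  expect_equal(nrow(detectInversions(low)), 0L)

  expect_error(detectInversions(dbl[1, , drop = FALSE]), "two time points")
})

test_that("metric series combine all statistics per GC over time", {
  f1 <- c(0.25, 0.25, 0.25, 0.25, rep(0, 6))
  f2 <- c(0.7, 0.1, 0.1, 0.1, rep(0, 6))
  gce <- gceFromFrequencies(rbind(f1, f2), times = c(168, 216))
  m <- clonalityMetrics(gce)
  expect_equal(nrow(m), 2L)
  expect_equal(m$dominance, c(0.25, 0.7))
  expect_equal(m$top2, c(0.5, 0.8))
  expect_equal(m$divergence[1], divergenceIndex(f1, uniformExpectedFrequencies()))
  expect_equal(m$meander, c(0, sqrt(sum((f2 - f1)^2))))
  expect_true(all(diff(m$meander) >= 0))
})

test_that("selection drives median dominance upward over time across replicates", {
  cfg <- simConfig(fitnessSd = 0.1)
  set.seed(6)
  doms <- replicate(30, {
    tr <- simulateGCTrajectory(cfg)
    cc <- tr@colorCounts[colorStates(), ]
    lab <- colSums(cc)
    ok <- lab > 0
    d <- rep(NA_real_, ncol(cc))
    d[ok] <- apply(cc[, ok, drop = FALSE], 2, function(x) max(x) / sum(x))
    d
  })
  med <- apply(doms, 1, median, na.rm = TRUE)
  # distributional pauciclonality: the median trend never reverses materially
  expect_true(all(diff(med) > -0.02))
  expect_gt(med[length(med)], med[1])
})
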