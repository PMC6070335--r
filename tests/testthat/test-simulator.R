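test_that("seeding trajectories follow the closed-form exponential mean", {
  s0 <- simulateSeeding(1, 0, times = c(0, 5, 10))
  expect_equal(s0$count, c(1, 1, 1))

  s1 <- simulateSeeding(2, 0.5, times = 0:2)
  expect_equal(s1$count, c(2, 2 * exp(0.5), 2 * exp(1)))

  expect_error(simulateSeeding(-1, 0.1, times = 0:3), "nonnegative")
  expect_error(simulateSeeding(1, 0.1, times = c(2, 1)), "increasing")

  # Poisson replicate means track y0*exp(k t) (moderate scale for speed)
  ts <- seq(0, 48, by = 12)
  mu <- 5 * exp(0.05 * ts)
  set.seed(31)
  reps <- t(replicate(200, simulateSeeding(5, 0.05, ts, noise = "poisson")$count))
  se <- sqrt(mu / 200)
  expect_true(all(abs(colMeans(reps) - mu) <= 3 * se))
})

test_that("trajectories are reproducible under a fixed seed and vary across seeds", {
  cfg <- simConfig()
  a <- simulateGCTrajectory(cfg, seed = 123)
  b <- simulateGCTrajectory(cfg, seed = 123)
  c <- simulateGCTrajectory(cfg, seed = 124)
  expect_identical(a@colorCounts, b@colorCounts)
  expect_identical(a@cloneTables, b@cloneTables)
  expect_false(identical(a@colorCounts, c@colorCounts))
})

test_that("population size is conserved exactly in the capped phase", {
  cfg <- simConfig(nFounders = 100, populationCap = 400,
                   generationHours = 6, recordTimesH = seq(60, 300, by = 30))
  tr <- simulateGCTrajectory(cfg, seed = 2)
  tot <- colSums(tr@colorCounts)
  mature <- tot[tr@times >= 60]   # cap reached within ~2 generations
  expect_true(all(mature == 400))
})

test_that("neutral dynamics with a huge population freeze founder frequencies", {
  set.seed(30)
  founders <- data.frame(clone_id = 1:200,
                         color = sampleColorStates(200, RecombinationModel()),
                         log_fitness = 0, count = 5000)  # at cap: drift only
  cfg <- simConfig(populationCap = 1e6, fitnessSd = 0,
                   mutationRate = 0, generationHours = 1,
                   recordTimesH = c(0, 20))
  tr <- simulateGCTrajectory(cfg, seed = 3, founders = founders)
  f0 <- tr@colorCounts[, 1] / sum(tr@colorCounts[, 1])
  f1 <- tr@colorCounts[, 2] / sum(tr@colorCounts[, 2])
  expect_lt(max(abs(f1 - f0)), 0.01)
})

test_that("an overwhelmingly fit founder clone sweeps to fixation", {
  founders <- data.frame(
    clone_id = 1:20,
    color = c("cRFP", rep("mCFP", 19)),
    log_fitness = c(10, rep(0, 19)),
    count = 1
  )
  cfg <- simConfig(populationCap = 500, fitnessSd = 0, mutationRate = 0,
                   generationHours = 1, recordTimesH = c(0, 25))
  tr <- simulateGCTrajectory(cfg, seed = 4, founders = founders)
  final <- tr@colorCounts[, 2]
  expect_equal(unname(final["cRFP"]), 500)
})

test_that("neutral Wright-Fisher heterozygosity decays as H0 (1 - 1/N)^t", {
  N <- 50; tgen <- 10; nrep <- 500
  cfg <- simConfig(nFounders = N, populationCap = N, fitnessSd = 0,
                   mutationRate = 0, generationHours = 1, recordTimesH = tgen)
  set.seed(21)
  H <- replicate(nrep, {
    tr <- simulateGCTrajectory(cfg)
    1 - sum((tr@cloneTables[[1]]$count / N)^2)
  })
  expected <- (1 - 1 / N) * (1 - 1 / N)^tgen
  expect_lt(abs(mean(H) - expected), 3 * sd(H) / sqrt(nrep))
})

test_that("neutral color frequencies are a martingale", {
  founders <- data.frame(clone_id = 1:100,
                         color = rep(c("mCFP", "nGFP"), each = 50),
                         log_fitness = 0, count = 1)
  cfg <- simConfig(populationCap = 100, fitnessSd = 0, mutationRate = 0,
                   generationHours = 1, recordTimesH = 10)
  set.seed(22)
  f <- replicate(300, {
    tr <- simulateGCTrajectory(cfg, founders = founders)
    cc <- tr@colorCounts[, 1]
    cc["mCFP"] / sum(cc)
  })
  expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(300))
})

test_that("manual-count sampling is multinomial, unbiased and records occupation", {
  mono <- setNames(c(1000, rep(0, 9)), colorStates())
  obs <- sampleObservation(mono, depth = 250, seed = 1)
  expect_s4_class(obs, "GCExperiment")
  expect_equal(unname(assay(obs, "counts")[1, 1]), 250)

  half <- setNames(c(5e4, 5e4, rep(0, 8)), colorStates())
  big <- sampleObservation(half, depth = 1e5, seed = 2)
  f <- assay(big, "counts")[, 1] / 1e5
  expect_lt(abs(f[1] - 0.5), 0.01)
  expect_lt(abs(f[2] - 0.5), 0.01)

  obs2 <- sampleObservation(mono, depth = 250, labeledFraction = 0.4, seed = 3)
  expect_equal(colData(obs2)$occupation, 0.4)

  # occupation computed from an explicit unlabeled component
  dark <- c(setNames(c(400, rep(0, 9)), colorStates()), unlabeled = 600)
  obs3 <- sampleObservation(dark, depth = 100, seed = 4)
  expect_equal(colData(obs3)$occupation, 0.4)

  expect_error(sampleObservation(mono, depth = 0), "positive")

  # unbiasedness: replicate mean frequency equals the composition
  comp <- setNames(1000 * randomComposition(10), colorStates())
  set.seed(23)
  reps <- replicate(200, assay(sampleObservation(comp, depth = 250), "counts")[, 1] / 250)
  p <- comp / sum(comp)
  se <- sqrt(p * (1 - p) / (250 * 200))
  expect_true(all(abs(rowMeans(reps) - p) <= 3 * se + 1e-12))
})

test_that("a single-GC mouse reproduces the single-trajectory law exactly", {
  cfg <- simConfig(nGcsPerMouse = 1, reentryRate = 0.5)
  a <- simulateMouse(cfg, seed = 9)[[1]]
  b <- simulateGCTrajectory(cfg, seed = 9)
  expect_identical(a@colorCounts, b@colorCounts)
})

test_that("reentry injects high-fitness clones into sibling GCs", {
  cfg <- simConfig(nGcsPerMouse = 3, reentryRate = 1, fitnessSd = 0.2,
                   mutationRate = 0, recordTimesH = c(60, 120))
  trs <- simulateMouse(cfg, seed = 10)
  # with mutation off, only reentry mints clone ids beyond the 3 * 100 founders
  ids <- unlist(lapply(trs, function(tr) tr@cloneTables[[2]]$clone_id))
  expect_gt(max(ids), 300)
})
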