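test_that("fidelity regression recovers identity and proportional relations", {
  x <- seq(0.2, 0.9, length.out = 8)
  fid <- fidelityRegression(data.frame(value_ex_vivo = x, value_in_vivo = x))
  expect_equal(unname(fid$slope[["estimate"]]), 1, tolerance = 1e-12)
  expect_true(fid$fidelity_pass)
  expect_equal(fid$slope[["lo"]], fid$slope[["hi"]], tolerance = 1e-6)

  fid2 <- fidelityRegression(data.frame(value_ex_vivo = x, value_in_vivo = 2 * x))
  expect_equal(unname(fid2$slope[["estimate"]]), 2, tolerance = 1e-12)
  expect_false(fid2$fidelity_pass)

  expect_error(fidelityRegression(
    data.frame(value_ex_vivo = rep(0.5, 5), value_in_vivo = x[1:5])),
    "variance")
  expect_error(fidelityRegression(
    data.frame(value_ex_vivo = x[1:2], value_in_vivo = x[1:2])), "3 paired")
})

test_that("fidelity slope CI covers unity for faithful noisy measurements", {
  set.seed(10)
  cover <- replicate(200, {
    x <- runif(16, 0.2, 1)
    y <- x + rnorm(16, 0, 0.03)
    fid <- fidelityRegression(data.frame(value_ex_vivo = x, value_in_vivo = y))
    fid$fidelity_pass
  })
  expect_gte(mean(cover), 0.9)
})

test_that("the feature matrix is compositions over canonical columns", {
  f1 <- c(0.25, 0.25, 0.25, 0.25, rep(0, 6))
  f2 <- c(0.7, 0.1, 0.1, 0.1, rep(0, 6))
  f3 <- c(0.1, 0.8, 0.05, 0.05, rep(0, 6))
  gce <- gceFromFrequencies(rbind(f1, f2, f3), times = c(168, 216, 264))
  fm <- buildFeatureMatrix(gce)
  expect_equal(dim(fm$matrix), c(3L, 10L))
  expect_equal(unname(rowSums(fm$matrix)), rep(1, 3), tolerance = 1e-9)
  expect_identical(colnames(fm$matrix), colorStates())
  expect_equal(fm$metadata$time_h, c(168, 216, 264))

  # sparsity filtering happens before the matrix is built
  gce2 <- gceFromFrequencies(rbind(f1, f2, f3), times = c(168, 216, 264),
                             occupation = c(1, 0.3, 1))
  expect_equal(nrow(buildFeatureMatrix(gce2)$matrix), 2L)
})

test_that("PCA separates constructed clusters and satisfies its identities", {
  set.seed(11)
  a <- c(0.8, 0.1, 0.1, rep(0, 7))
  b <- c(0.05, 0.05, 0.1, 0.8, rep(0, 6))
  x <- rbind(t(replicate(10, pmax(a + rnorm(10, 0, 0.01), 0))),
             t(replicate(10, pmax(b + rnorm(10, 0, 0.01), 0))))
  x <- x / rowSums(x)
  p <- runPCA(x, nComponents = 3)
  expect_s4_class(p, "PCAResult")
  sil <- silhouetteOracle(p@scores[, 1, drop = FALSE], rep(c("A", "B"), each = 10))
  expect_gt(sil, 0.8)

  # orthonormal loadings, non-increasing explained variance
  expect_equal(crossprod(p@loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p@explainedVariance) <= 1e-12))

  # retained variance cannot exceed the total variance of the data
  total <- sum(apply(x, 2, var))
  expect_lte(sum(p@explainedVariance), total + 1e-12)

  # full-rank reconstruction reproduces the centered matrix
  pf <- runPCA(x, nComponents = 10)
  recon <- pf@scores %*% t(pf@loadings)
  centered <- sweep(x, 2, pf@center)
  expect_equal(recon, centered, tolerance = 1e-9, ignore_attr = TRUE)

  # row permutation permutes scores and leaves loadings fixed (sign convention)
  perm <- sample(nrow(x))
  p2 <- runPCA(x[perm, ], nComponents = 3)
  expect_equal(p2@loadings, p@loadings, tolerance = 1e-9)
  expect_equal(p2@scores, p@scores[perm, ], tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(runPCA(matrix(0.1, nrow = 8, ncol = 10)), "zero variance")
})

test_that("mouse association detects a true per-mouse offset on PC1 only", {
  set.seed(12)
  nMice <- 6; nObs <- 8
  hits <- replicate(100, {
    mouse <- rep(paste0("m", seq_len(nMice)), each = nObs)
    time <- rep(seq_len(nObs), nMice)
    off <- rnorm(nMice, 0, 1)[as.integer(factor(mouse))]
    scores <- cbind(PC1 = off + rnorm(length(mouse), 0, 0.3),
                    PC2 = rnorm(length(mouse)))
    r <- testMouseAssociation(scores,
                              data.frame(mouse_id = mouse, time_h = time))
    c(pc1 = r$components$p_value[1] < 0.01, pc2 = r$components$p_value[2] < 0.01)
  })
  expect_gte(mean(hits["pc1", ]), 0.9)
  expect_lt(mean(hits["pc2", ]), 0.2)   # noise component: near nominal size
})

test_that("permuted mouse labels give uniform association p-values", {
  set.seed(13)
  nMice <- 6; nObs <- 8
  mouse <- rep(paste0("m", seq_len(nMice)), each = nObs)
  time <- rep(seq_len(nObs), nMice)
  pvals <- replicate(200, {
    scores <- cbind(PC1 = rnorm(length(mouse)))
    r <- testMouseAssociation(scores,
                              data.frame(mouse_id = sample(mouse), time_h = time))
    r$components$p_value[1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("degenerate association inputs are rejected", {
  scores <- cbind(PC1 = rep(0, 12))
  md <- data.frame(mouse_id = rep(c("a", "b"), 6), time_h = 1:12)
  expect_error(testMouseAssociation(scores, md), "zero-variance")
  md1 <- data.frame(mouse_id = rep("a", 12), time_h = 1:12)
  expect_error(testMouseAssociation(cbind(PC1 = rnorm(12)), md1), "two mice")
})

test_that("reentry coupling shifts mouse-association p-values downward end-to-end", {
  runExperiment <- function(reentry, seed) {
    cfg <- simConfig(nGcsPerMouse = 3, reentryRate = reentry)
    obs <- list()
    for (m in 1:4) {
      trs <- simulateMouse(cfg, seed = seed * 100 + m, mouseId = paste0("m", m))
      o <- tryCatch(sampleTrajectories(trs, cfg, seed = seed * 100 + 50 + m),
                    error = function(e) NULL)
      if (!is.null(o)) obs[[length(obs) + 1]] <- o
    }
    gce <- combineGCExperiments(obs)
    fm <- tryCatch(buildFeatureMatrix(gce), error = function(e) NULL)
    if (is.null(fm) || length(unique(fm$metadata$mouse_id)) < 2) return(NA)
    testMouseAssociation(runPCA(fm))$components$p_value[1]
  }
  p0 <- vapply(1:12, function(s) runExperiment(0, s), numeric(1))
  p1 <- vapply(1:12, function(s) runExperiment(0.3, 5000 + s), numeric(1))
  w <- wilcox.test(p1[!is.na(p1)], p0[!is.na(p0)], alternative = "less")
  expect_lt(w$p.value, 0.05)
})
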