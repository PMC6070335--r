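# Independent brute-force oracles and small generators used across tests.
# These deliberately use naive loops so they share no code with the package.

suppressPackageStartupMessages(library(SummarizedExperiment))

# random point on the 10-simplex (occasionally sparse)
randomComposition <- function(k = 10, sparse = FALSE) {
  x <- rexp(k)
  if (sparse) x[sample(k, sample(0:(k - 2), 1))] <- 0
  x / sum(x)
}

# L1 distance by explicit loop
l1Oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s
}

# cumulative Euclidean (or other) path length by explicit loop
pathLengthOracle <- function(mat, step = function(d) sqrt(sum(d^2))) {
  out <- numeric(nrow(mat))
  for (j in 2:nrow(mat)) {
    out[j] <- out[j - 1] + step(mat[j, ] - mat[j - 1, ])
  }
  out
}

# mean silhouette width for a 2-group labelling, from pairwise distances
silhouetteOracle <- function(x, labels) {
  d <- as.matrix(dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(d[i, same])
    b <- mean(d[i, !same & seq_len(nrow(x)) != i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force enumeration of 1- and 2-subsets of a label set
subsetOracle <- function(labels) {
  singles <- labels
  pairs <- character(0)
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (i < j) {
        pairs <- c(pairs, paste(sort(c(labels[i], labels[j])), collapse = "+"))
      }
    }
  }
  c(singles, sort(pairs))
}

# tiny GCExperiment from explicit per-observation frequency rows
gceFromFrequencies <- function(freqRows, times, gcId = "G1", mouseId = "m1",
                               depth = 1000, occupation = 1) {
  counts <- t(round(freqRows * depth))
  rownames(counts) <- colorStates()
  GCExperiment(counts, mouse_id = mouseId, gc_id = gcId, time_h = times,
               occupation = occupation)
}
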