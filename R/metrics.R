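## Per-GC clonality statistics: clonal dominance, top-two dominance,
## clonal divergence score, meander index, the sparse-GC exclusion rule,
## and clonal inversion event detection.

asFreq <- function(freq) {
  v <- as.numeric(freq)
  if (anyNA(v) || any(v < 0)) stop("frequencies must be nonnegative")
  v
}

#' Clonal dominance
#'
#' Frequency of the most dominant color at one time point: the maximum entry
#' of the composition. Ties return the same value regardless of which color
#' attains the maximum.
#'
#' @param freq frequency vector over the canonical color states.
#' @return numeric in [0, 1] (at least 1/10 for a 10-state composition).
#' @examples
#' dominance(c(0.6, 0.2, 0.2, rep(0, 7)))  # 0.6
#' @export
dominance <- function(freq) max(asFreq(freq))

#' Sum of the two most dominant color frequencies
#'
#' @param freq frequency vector over the canonical color states.
#' @return numeric in [0, 1].
#' @examples
#' top2Sum(c(0.5, 0.3, 0.2, rep(0, 7)))  # 0.8
#' @export
top2Sum <- function(freq) {
  v <- sort(asFreq(freq), decreasing = TRUE)
  if (length(v) < 2L) v[1L] else v[1L] + v[2L]
}

#' Clonal divergence score
#'
#' L1 distance between an observed color composition and the expected
#' composition under random recombination:
#' \deqn{D(t) = \sum_{i=1}^{10} | \mathrm{obs}_i - \mathrm{exp}_i |}
#' Ranges over [0, 2] for two compositions on the simplex.
#'
#' @param observed observed frequency vector (canonical state order).
#' @param expected an \linkS4class{ExpectedFrequencies} or a frequency
#'   vector in the same canonical order.
#' @return numeric in [0, 2].
#' @examples
#' divergenceIndex(c(1, rep(0, 9)), uniformExpectedFrequencies())  # 1.8
#' @export
divergenceIndex <- function(observed, expected) {
  if (is(expected, "ExpectedFrequencies")) expected <- expected@values
  obs <- asFreq(observed)
  exp <- asFreq(expected)
  if (length(obs) != length(exp))
    stop("observed and expected are over different state spaces")
  if (!is.null(names(observed)) && !is.null(names(expected)) &&
      !identical(names(observed), names(expected)))
    stop("observed and expected must share the same canonical state order")
  sum(abs(obs - exp))
}

#' Meander index of a composition trajectory
#'
#' Cumulative path length of a GC's color composition through frequency
#' space: \code{meander(t_0) = 0} and
#' \code{meander(t_j) = meander(t_{j-1}) + ||f(t_j) - f(t_{j-1})||}.
#' The default step norm is Euclidean (a true path length, the "integral of
#' relative velocities" / "distance traveled" reading); alternative readings
#' are selectable: \code{"l1"} (sum of absolute per-color changes),
#' \code{"sq"} (sum of squared changes, no root), and \code{"ddiv"}
#' (absolute change of the divergence index, requiring \code{expected}).
#' The index is a pure path length: it does not depend on the spacing of
#' the time points.
#'
#' @param series T x 10 matrix of frequency vectors (rows = time points in
#'   order), or a list of frequency vectors.
#' @param norm step norm; one of \code{"l2"}, \code{"l1"}, \code{"sq"},
#'   \code{"ddiv"}.
#' @param expected expected frequencies, required for \code{norm = "ddiv"}.
#' @return numeric vector of cumulative meander values, one per time point;
#'   \code{0} for a single time point.
#' @examples
#' m <- rbind(c(0.6, 0.4, rep(0, 8)), c(0.4, 0.6, rep(0, 8)))
#' meanderIndex(m)  # 0, then sqrt(0.2^2 + 0.2^2) = 0.28284
#' @export
meanderIndex <- function(series, norm = c("l2", "l1", "sq", "ddiv"),
                         expected = NULL) {
  norm <- match.arg(norm)
  if (is.list(series)) series <- do.call(rbind, series)
  series <- as.matrix(series)
  nT <- nrow(series)
  if (nT < 1L) stop("series must contain at least one time point")
  if (nT == 1L) return(0)
  if (norm == "ddiv") {
    if (is.null(expected))
      stop("norm 'ddiv' requires expected frequencies")
    div <- apply(series, 1L, divergenceIndex, expected = expected)
    steps <- abs(diff(div))
  } else {
    d <- diff(series)
    steps <- switch(norm,
      l2 = sqrt(rowSums(d^2)),
      l1 = rowSums(abs(d)),
      sq = rowSums(d^2)
    )
  }
  c(0, cumsum(steps))
}

#' Sparse germinal center exclusion rule
#'
#' Observations with labeled occupation below the threshold (default 50\%)
#' are considered to contain at least one expanded dark clone and are
#' discarded before analysis. The inequality is strict, as the rule is
#' stated: exactly 50\% occupation is kept.
#'
#' @param x a \linkS4class{GCExperiment} or a numeric vector of occupation
#'   fractions.
#' @param threshold occupation threshold (default 0.5).
#' @return For a \code{GCExperiment}, the filtered object with the decision
#'   recorded in \code{metadata(x)$sparse_filter} (kept/discarded counts and
#'   the discarded observation names); for a numeric vector, a logical keep
#'   vector.
#' @examples
#' filterSparse(c(0.4, 0.5, 1.0))  # FALSE TRUE TRUE
#' @export
filterSparse <- function(x, threshold = 0.5) {
  if (is(x, "GCExperiment")) {
    occ <- SummarizedExperiment::colData(x)$occupation
    keep <- !(occ < threshold)
    out <- x[, keep]
    S4Vectors::metadata(out)$sparse_filter <- list(
      threshold = threshold,
      n_in = length(keep), n_kept = sum(keep), n_discarded = sum(!keep),
      discarded = colnames(x)[!keep],
      reason = sprintf("occupation < %g", threshold)
    )
    return(out)
  }
  !(as.numeric(x) < threshold)
}

#' Detect clonal inversion events
#'
#' A clonal inversion is the replacement of a previously dominant color by a
#' different color. An event is emitted when the identity of the dominant
#' color changes between consecutive retained time points, the outgoing
#' color reached dominance >= \code{dMin} at or before the change, and the
#' incoming color reaches dominance >= \code{dMin} at or after it.
#' Consecutive changes with distinct incoming colors count as separate
#' events (a double inversion is two events). The threshold \code{dMin} is a
#' declared convention of this package (the phenomenon is described, not
#' numerically defined, in the field) and is reported with every event.
#'
#' @param series T x 10 matrix of frequency vectors (rows = ordered time
#'   points), with canonical state columns.
#' @param times time stamps for the rows (default 1..T).
#' @param dMin dominance threshold for both colors (default 0.4).
#' @param gcId identifier copied into the result.
#' @return data.frame with one row per event: \code{gc_id}, \code{time_from},
#'   \code{time_to}, \code{outgoing_color}, \code{incoming_color},
#'   \code{outgoing_peak_dominance}, \code{incoming_peak_dominance},
#'   \code{d_min}.
#' @export
detectInversions <- function(series, times = NULL, dMin = 0.4, gcId = "GC") {
  if (is.list(series)) series <- do.call(rbind, series)
  series <- as.matrix(series)
  states <- if (!is.null(colnames(series))) colnames(series) else
    colorStates()[seq_len(ncol(series))]
  nT <- nrow(series)
  if (is.null(times)) times <- seq_len(nT)
  if (nT < 2L)
    stop("inversion detection requires at least two time points")
  empty <- data.frame(gc_id = character(0), time_from = numeric(0),
                      time_to = numeric(0), outgoing_color = character(0),
                      incoming_color = character(0),
                      outgoing_peak_dominance = numeric(0),
                      incoming_peak_dominance = numeric(0),
                      d_min = numeric(0))
  # dominant color per time; ties broken by canonical order for attribution
  domIdx <- apply(series, 1L, which.max)
  events <- empty
  for (j in 2:nT) {
    out <- domIdx[j - 1L]
    inc <- domIdx[j]
    if (inc == out) next
    outPeak <- max(series[seq_len(j - 1L), out])
    incPeak <- max(series[j:nT, inc])
    if (outPeak >= dMin && incPeak >= dMin) {
      events <- rbind(events, data.frame(
        gc_id = gcId, time_from = times[j - 1L], time_to = times[j],
        outgoing_color = states[out], incoming_color = states[inc],
        outgoing_peak_dominance = outPeak, incoming_peak_dominance = incPeak,
        d_min = dMin))
    }
  }
  events
}

#' Per-GC clonality metric series
#'
#' Computes, for every germinal center in a \linkS4class{GCExperiment}, the
#' time series of clonal dominance, top-two dominance, divergence index and
#' meander index. Observations failing the sparsity rule are discarded
#' first.
#'
#' @param gce a \linkS4class{GCExperiment}.
#' @param expected an \linkS4class{ExpectedFrequencies}; default uniform.
#' @param meanderNorm step norm passed to [meanderIndex()].
#' @param sparseThreshold occupation threshold for [filterSparse()]; set to
#'   0 to keep everything.
#' @return data.frame with columns \code{mouse_id}, \code{gc_id},
#'   \code{time_h}, \code{occupation}, \code{dominance}, \code{top2},
#'   \code{divergence}, \code{meander}, ordered by (mouse, GC, time).
#' @examples
#' tr <- simulateGCTrajectory(simConfig(), seed = 7)
#' gce <- sampleTrajectories(tr, simConfig(), seed = 8)
#' head(clonalityMetrics(gce))
#' @export
clonalityMetrics <- function(gce, expected = uniformExpectedFrequencies(),
                             meanderNorm = "l2", sparseThreshold = 0.5) {
  stopifnot(is(gce, "GCExperiment"))
  gce <- filterSparse(gce, threshold = sparseThreshold)
  if (ncol(gce) == 0L) stop("no observations left after sparsity filtering")
  cd <- SummarizedExperiment::colData(gce)
  freq <- relativeFrequencies(gce)
  key <- paste(cd$mouse_id, cd$gc_id, sep = "\r")
  res <- lapply(split(seq_len(ncol(gce)), key), function(idx) {
    idx <- idx[order(cd$time_h[idx])]
    f <- t(freq[, idx, drop = FALSE])
    data.frame(
      mouse_id = cd$mouse_id[idx], gc_id = cd$gc_id[idx],
      time_h = cd$time_h[idx], occupation = cd$occupation[idx],
      dominance = apply(f, 1L, dominance),
      top2 = apply(f, 1L, top2Sum),
      divergence = apply(f, 1L, divergenceIndex, expected = expected),
      meander = meanderIndex(f, norm = meanderNorm, expected = expected),
      row.names = NULL
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$mouse_id, out$gc_id, out$time_h), , drop = FALSE]
}

#' Inversion events for every GC in an experiment
#'
#' Applies [detectInversions()] per germinal center after sparsity
#' filtering.
#'
#' @inheritParams clonalityMetrics
#' @param dMin dominance threshold passed to [detectInversions()].
#' @return data.frame of events across all GCs (possibly zero rows).
#' @export
inversionEvents <- function(gce, dMin = 0.4, sparseThreshold = 0.5) {
  stopifnot(is(gce, "GCExperiment"))
  gce <- filterSparse(gce, threshold = sparseThreshold)
  cd <- SummarizedExperiment::colData(gce)
  freq <- relativeFrequencies(gce)
  key <- paste(cd$mouse_id, cd$gc_id, sep = "\r")
  evs <- lapply(split(seq_len(ncol(gce)), key), function(idx) {
    idx <- idx[order(cd$time_h[idx])]
    if (length(idx) < 2L) return(NULL)
    detectInversions(t(freq[, idx, drop = FALSE]),
                     times = cd$time_h[idx], dMin = dMin,
                     gcId = cd$gc_id[idx][1L])
  })
  out <- do.call(rbind, evs)
  if (is.null(out) || nrow(out) == 0L)
    return(detectInversions(matrix(c(1, rep(0, 19)), nrow = 2, byrow = TRUE),
                            dMin = 2)[0, ])  # typed empty frame
  rownames(out) <- NULL
  out
}
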