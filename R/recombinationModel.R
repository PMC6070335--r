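#' @import methods
NULL

#' RecombinationModel: stochastic Confetti labeling model
#'
#' A cell-level model of stochastic Confetti recombination. With probability
#' \code{cellLabelingEfficiency} a cell recombines and becomes labeled;
#' conditional on labeling, a fraction \code{doubleLabelFraction} of cells
#' carry two independently recombined alleles expressing two distinct XFPs
#' (an unordered pair), and the remainder express a single XFP. Each
#' recombined allele picks an XFP according to \code{perXfpProb}; pair draws
#' are two independent picks conditioned on being distinct.
#'
#' Allele-level biology (the biallelic knock-in) is deliberately collapsed to
#' this cell-level parameterization: downstream analysis only ever observes
#' cell-level color states.
#'
#' @slot cellLabelingEfficiency numeric in [0,1]; one minus the probability
#'   that a cell stays unlabeled. Default 0.475, the midpoint of the 45--50\%
#'   efficiency measured for a single tamoxifen gavage.
#' @slot perXfpProb named numeric probability vector over the four XFPs,
#'   summing to 1. Default uniform.
#' @slot doubleLabelFraction numeric in [0,1]; fraction of labeled cells
#'   expressing two XFPs. Default 0.1 (double labeling is the rarer outcome).
#'
#' @seealso [colorStateDistribution()], [sampleColorStates()]
#' @export
setClass("RecombinationModel",
  representation(
    cellLabelingEfficiency = "numeric",
    perXfpProb = "numeric",
    doubleLabelFraction = "numeric"
  )
)

setValidity("RecombinationModel", function(object) {
  msg <- character(0)
  e <- object@cellLabelingEfficiency
  p <- object@perXfpProb
  d <- object@doubleLabelFraction
  if (length(e) != 1L || is.na(e) || e < 0 || e > 1)
    msg <- c(msg, "cellLabelingEfficiency must be a single value in [0,1]")
  if (length(d) != 1L || is.na(d) || d < 0 || d > 1)
    msg <- c(msg, "doubleLabelFraction must be a single value in [0,1]")
  if (length(p) != 4L || anyNA(p) || any(p < 0))
    msg <- c(msg, "perXfpProb must be 4 nonnegative probabilities")
  else {
    if (abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "perXfpProb must sum to 1")
    if (is.null(names(p)) || anyDuplicated(names(p)))
      msg <- c(msg, "perXfpProb must be named by distinct XFPs")
    if (length(p) == 4L && abs(sum(p) - 1) <= 1e-9 &&
        d > 0 && sum(p^2) >= 1 - 1e-12)
      msg <- c(msg, "doubleLabelFraction > 0 requires at least two XFPs with positive probability")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RecombinationModel
#'
#' @param cellLabelingEfficiency probability that a cell is labeled at all.
#' @param perXfpProb probability of each XFP per recombined allele; named
#'   numeric over the four XFPs, or unnamed in the default XFP order.
#' @param doubleLabelFraction fraction of labeled cells with two XFPs.
#' @return A validated \linkS4class{RecombinationModel}.
#' @examples
#' RecombinationModel()  # defaults: efficiency 0.475, uniform XFPs, 10% double
#' @export
RecombinationModel <- function(cellLabelingEfficiency = 0.475,
                               perXfpProb = rep(0.25, 4),
                               doubleLabelFraction = 0.1) {
  xfps <- c("mCFP", "nGFP", "cYFP", "cRFP")
  if (is.null(names(perXfpProb)) && length(perXfpProb) == 4L)
    names(perXfpProb) <- xfps
  new("RecombinationModel",
      cellLabelingEfficiency = cellLabelingEfficiency,
      perXfpProb = perXfpProb[xfps],
      doubleLabelFraction = doubleLabelFraction)
}

setMethod("show", "RecombinationModel", function(object) {
  cat("RecombinationModel\n")
  cat("  labeling efficiency:  ", object@cellLabelingEfficiency, "\n")
  cat("  double-label fraction:", object@doubleLabelFraction, "\n")
  cat("  per-XFP probabilities:",
      paste(sprintf("%s=%.3g", names(object@perXfpProb), object@perXfpProb),
            collapse = " "), "\n")
})

#' Analytic distribution over unlabeled and the 10 color states
#'
#' Computes the probability of each observable cell state under a
#' \linkS4class{RecombinationModel}: \code{P(unlabeled) = 1 - efficiency};
#' conditional on labeling, a single-XFP state \eqn{i} has probability
#' \eqn{(1-d)\,p_i} and an unordered pair \eqn{\{i,j\}} has probability
#' \eqn{d \cdot 2 p_i p_j / (1 - \sum_k p_k^2)} (two independent allele draws
#' conditioned on being distinct), where \eqn{d} is the double-label fraction.
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @return Named numeric vector over \code{c("unlabeled", colorStates())},
#'   summing to 1.
#' @examples
#' d <- colorStateDistribution(RecombinationModel())
#' sum(d)  # 1
#' @export
colorStateDistribution <- function(model) {
  stopifnot(is(model, "RecombinationModel"))
  validObject(model)
  states <- colorStates()
  p <- model@perXfpProb
  eff <- model@cellLabelingEfficiency
  d <- model@doubleLabelFraction
  out <- stats::setNames(numeric(length(states) + 1L), c(UNLABELED, states))
  out[UNLABELED] <- 1 - eff
  cons <- attr(enumerateColorStates(), "constituents")
  for (s in states) {
    xs <- cons[[s]]
    if (length(xs) == 1L) {
      out[s] <- eff * (1 - d) * p[xs]
    } else {
      denom <- 1 - sum(p^2)
      out[s] <- if (d == 0) 0 else eff * d * 2 * p[xs[1L]] * p[xs[2L]] / denom
    }
  }
  out
}

#' Draw cell color states from a recombination model
#'
#' Random sample of per-cell states (including \code{"unlabeled"}) from the
#' analytic distribution of [colorStateDistribution()]. Used by the germinal
#' center simulator to assign heritable founder colors.
#'
#' @param n number of cells.
#' @param model a \linkS4class{RecombinationModel}.
#' @return Character vector of length \code{n} of state labels.
#' @export
sampleColorStates <- function(n, model) {
  pr <- colorStateDistribution(model)
  sample(names(pr), n, replace = TRUE, prob = pr)
}

#' ExpectedFrequencies: reference color composition
#'
#' The expected color frequencies a germinal center would show under purely
#' random recombination, before any selection. The divergence score compares
#' each observed composition against this reference. The reference may come
#' from pooled early observations (the analogue of day-3 explant data, taken
#' before selection has acted), from the analytic recombination model, or be
#' the uniform fallback.
#'
#' @slot source one of \code{"reference-data"}, \code{"model"},
#'   \code{"uniform"}.
#' @slot values named numeric frequency vector over the 10 canonical states,
#'   nonnegative and summing to 1.
#' @export
setClass("ExpectedFrequencies",
  representation(source = "character", values = "numeric")
)

setValidity("ExpectedFrequencies", function(object) {
  msg <- character(0)
  v <- object@values
  if (!identical(names(v), colorStates()))
    msg <- c(msg, "values must be named by the canonical color states")
  if (anyNA(v) || any(v < 0))
    msg <- c(msg, "values must be nonnegative")
  else if (abs(sum(v) - 1) > 1e-9)
    msg <- c(msg, "values must sum to 1 (tolerance 1e-9)")
  if (!(length(object@source) == 1L &&
        object@source %in% c("reference-data", "model", "uniform")))
    msg <- c(msg, "source must be one of reference-data, model, uniform")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExpectedFrequencies", function(object) {
  cat("ExpectedFrequencies (source:", object@source, ")\n")
  print(round(object@values, 4))
})

#' Construct ExpectedFrequencies
#'
#' @param values frequency vector over the canonical states (normalized if
#'   needed); named or in canonical order.
#' @param source provenance label.
#' @return An \linkS4class{ExpectedFrequencies} object.
#' @export
ExpectedFrequencies <- function(values, source = "uniform") {
  states <- colorStates()
  if (is.null(names(values))) {
    stopifnot(length(values) == length(states))
    names(values) <- states
  }
  values <- values[states]
  s <- sum(values)
  if (!is.finite(s) || s <= 0) stop("expected frequencies must have positive total")
  new("ExpectedFrequencies", source = source, values = values / s)
}

#' Uniform expected frequencies (0.1 per state)
#' @return An \linkS4class{ExpectedFrequencies} with uniform values.
#' @export
uniformExpectedFrequencies <- function() {
  ExpectedFrequencies(rep(0.1, 10), source = "uniform")
}

#' Expected frequencies from the analytic recombination model
#'
#' The distribution of [colorStateDistribution()] conditioned on being
#' labeled, as an \linkS4class{ExpectedFrequencies} with source
#' \code{"model"}.
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @return An \linkS4class{ExpectedFrequencies}.
#' @export
expectedFrequenciesFromModel <- function(model) {
  pr <- colorStateDistribution(model)
  lab <- pr[colorStates()]
  ExpectedFrequencies(lab / sum(lab), source = "model")
}

#' Expected frequencies from reference observations
#'
#' Pools labeled-cell color counts across a set of reference observations
#' (typically the earliest available time point, where the color distribution
#' most closely mimics random recombination) and normalizes to a frequency
#' vector.
#'
#' @param x a \linkS4class{GCExperiment}, or a counts matrix/vector over the
#'   canonical color states (states in rows for a matrix).
#' @return An \linkS4class{ExpectedFrequencies} with source
#'   \code{"reference-data"}.
#' @export
expectedFrequenciesFromReference <- function(x) {
  states <- colorStates()
  if (is(x, "GCExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
  } else if (is.matrix(x)) {
    counts <- x
  } else {
    counts <- matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  }
  if (is.null(rownames(counts)) && nrow(counts) == length(states))
    rownames(counts) <- states
  if (!all(states %in% rownames(counts)))
    stop("reference counts must cover the canonical color states")
  pooled <- rowSums(counts[states, , drop = FALSE])
  if (sum(pooled) <= 0)
    stop("no labeled cells in reference observations: cannot derive expected frequencies")
  ExpectedFrequencies(pooled / sum(pooled), source = "reference-data")
}
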