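#' GCExperiment: container for germinal center color-count observations
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one column per
#' observation of a germinal center at one time point. The single assay
#' \code{"counts"} is a 10 x n matrix of labeled-cell counts over the
#' canonical Confetti color states; unlabeled ("dark") cells never enter the
#' matrix but are reflected in the per-observation \code{occupation} fraction.
#'
#' Required \code{colData} columns:
#' \describe{
#'   \item{mouse_id}{animal identifier}
#'   \item{gc_id}{germinal center (or follicle) identifier}
#'   \item{time_h}{observation time in hours (day-denominated inputs are
#'     converted at ingest)}
#'   \item{occupation}{fraction of germinal center B cells carrying any
#'     Confetti label, in [0,1]; observations below 50\% are conventionally
#'     excluded as containing an expanded dark clone}
#'   \item{total_examined}{total number of cells examined for the
#'     observation (labeled counts sum to at most this)}
#' }
#'
#' @seealso [readCounts()], [clonalityMetrics()], [filterSparse()]
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @export
setClass("GCExperiment", contains = "SummarizedExperiment")

setValidity("GCExperiment", function(object) {
  msg <- character(0)
  if (!identical(rownames(object), colorStates()))
    msg <- c(msg, "rows must be the 10 canonical color states, in canonical order")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("mouse_id", "gc_id", "time_h", "occupation", "total_examined")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  } else if (ncol(object) > 0L) {
    occ <- cd$occupation
    if (anyNA(occ) || any(occ < 0 | occ > 1))
      msg <- c(msg, "occupation must lie in [0,1]")
    counts <- SummarizedExperiment::assay(object, "counts")
    if (any(counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(colSums(counts) > cd$total_examined + 1e-9))
      msg <- c(msg, "labeled counts exceed total_examined")
    key <- paste(cd$mouse_id, cd$gc_id, cd$time_h, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (mouse_id, gc_id, time_h) observations")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GCExperiment
#'
#' @param counts 10 x n matrix of labeled-cell counts; rows must be (or are
#'   named as) the canonical color states.
#' @param mouse_id,gc_id character/factor vectors of length n.
#' @param time_h numeric observation times in hours.
#' @param occupation labeled occupation fractions in [0,1]; if \code{NULL},
#'   computed as labeled/total_examined.
#' @param total_examined total cells examined; if \code{NULL}, the labeled
#'   column sums.
#' @return A validated \linkS4class{GCExperiment}.
#' @examples
#' cnt <- matrix(rpois(20, 25), nrow = 10, dimnames = list(colorStates(), NULL))
#' gce <- GCExperiment(cnt, mouse_id = "m1", gc_id = c("A", "B"),
#'                     time_h = c(168, 168))
#' gce
#' @export
GCExperiment <- function(counts, mouse_id, gc_id, time_h,
                         occupation = NULL, total_examined = NULL) {
  states <- colorStates()
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stopifnot(nrow(counts) == length(states))
    rownames(counts) <- states
  }
  if (!all(states %in% rownames(counts)))
    stop("counts must have a row per canonical color state")
  counts <- counts[states, , drop = FALSE]
  n <- ncol(counts)
  if (is.null(total_examined)) total_examined <- colSums(counts)
  if (is.null(occupation)) {
    occupation <- ifelse(total_examined > 0, colSums(counts) / total_examined, 0)
  }
  cd <- S4Vectors::DataFrame(
    mouse_id = rep_len(as.character(mouse_id), n),
    gc_id = rep_len(as.character(gc_id), n),
    time_h = rep_len(as.numeric(time_h), n),
    occupation = rep_len(as.numeric(occupation), n),
    total_examined = rep_len(as.numeric(total_examined), n)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd
  )
  colnames(se) <- paste(cd$mouse_id, cd$gc_id, cd$time_h, sep = ".")
  new("GCExperiment", se)
}

#' Combine GCExperiment objects column-wise
#'
#' @param ... \linkS4class{GCExperiment} objects (or a single list of them)
#'   over the same canonical color states.
#' @return A single \linkS4class{GCExperiment}.
#' @export
combineGCExperiments <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is(args[[1L]], "GCExperiment"))
    args <- args[[1L]]
  stopifnot(all(vapply(args, is, logical(1), "GCExperiment")))
  out <- do.call(cbind, args)
  validObject(out)
  out
}

setMethod("show", "GCExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("GCExperiment:", ncol(object), "observations,",
      length(unique(cd$gc_id)), "GCs,",
      length(unique(cd$mouse_id)), "mice\n")
  if (ncol(object) > 0L)
    cat("  time range (h):", min(cd$time_h), "-", max(cd$time_h), "\n")
  cat("  color states:", paste(utils::head(rownames(object), 4), collapse = ", "),
      "... (10)\n")
})

#' Per-observation relative color frequencies
#'
#' Converts raw labeled-cell counts to relative frequencies over the 10 color
#' states, per observation. Frequencies are computed over labeled cells only;
#' dark cells influence the occupation fraction but never the composition.
#'
#' @param x a \linkS4class{GCExperiment}, or a nonnegative count vector over
#'   the canonical states.
#' @return For a \code{GCExperiment}, a 10 x n matrix of frequencies (columns
#'   sum to 1); for a vector, a named frequency vector.
#' @examples
#' relativeFrequencies(c(150, 50, 50, rep(0, 7)))
#' @export
relativeFrequencies <- function(x) {
  if (is(x, "GCExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    tot <- colSums(counts)
    if (any(tot <= 0))
      stop("observation(s) with zero labeled counts: ",
           paste(colnames(counts)[tot <= 0], collapse = ", "))
    return(sweep(counts, 2L, tot, "/"))
  }
  v <- as.numeric(x)
  if (length(v) != 10L) stop("frequency vectors are length 10")
  if (any(v < 0)) stop("counts must be nonnegative")
  s <- sum(v)
  if (s <= 0) stop("empty observation: all counts zero")
  stats::setNames(v / s, colorStates())
}
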