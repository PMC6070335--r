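#' Enumerate the observable Confetti color states
#'
#' The Confetti reporter carries a stop-floxed cassette of four fluorescent
#' proteins (XFPs) on both alleles. Tamoxifen-induced Cre recombines one, or
#' less frequently both, alleles, so a labeled cell expresses either a single
#' XFP or an unordered combination of two distinct XFPs. With the four
#' canonical XFPs this yields ten observable color states.
#'
#' The canonical order is: the single-XFP states in declaration order of
#' \code{xfps}, followed by the two-XFP states sorted lexicographically by
#' label. Two-XFP labels join the constituent names, sorted alphabetically,
#' with \code{"+"} (e.g. \code{"cYFP+mCFP"}). This order is stable across
#' calls and defines the column order of every frequency vector and CSV
#' written by the package.
#'
#' @param xfps character vector of distinct fluorescent protein names.
#'   Defaults to the four Confetti XFPs \code{c("mCFP","nGFP","cYFP","cRFP")}.
#'
#' @return A character vector of state labels, of length
#'   \eqn{n + n(n-1)/2} for \eqn{n} XFPs; for the default four XFPs, length 10.
#'   The constituent XFPs of each state are attached as the
#'   \code{"constituents"} attribute (a named list of character vectors).
#'
#' @examples
#' enumerateColorStates()              # the 10 Confetti states
#' enumerateColorStates(c("A", "B"))   # 3 states: A, B, A+B
#' @export
enumerateColorStates <- function(xfps = c("mCFP", "nGFP", "cYFP", "cRFP")) {
  xfps <- as.character(xfps)
  if (length(xfps) < 1L || anyDuplicated(xfps) || anyNA(xfps))
    stop("'xfps' must be a non-empty set of distinct names")
  singles <- xfps
  pairs <- character(0)
  if (length(xfps) >= 2L) {
    cmb <- utils::combn(sort(xfps), 2L)
    pairs <- sort(apply(cmb, 2L, paste, collapse = "+"))
  }
  states <- c(singles, pairs)
  constituents <- c(
    as.list(singles),
    lapply(strsplit(pairs, "+", fixed = TRUE), identity)
  )
  names(constituents) <- states
  attr(states, "constituents") <- constituents
  states
}

#' Canonical Confetti color state labels
#'
#' Convenience accessor for the default ten-state enumeration without the
#' constituents attribute; used throughout for row and column naming.
#'
#' @return Character vector of the 10 canonical state labels.
#' @seealso [enumerateColorStates()]
#' @export
colorStates <- function() {
  s <- enumerateColorStates()
  attributes(s) <- NULL
  s
}

# Label for cells with no recombined allele (never part of frequency vectors).
UNLABELED <- "unlabeled"
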