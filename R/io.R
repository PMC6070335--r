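## Readers and writers for the long / wide count-table formats, seeding
## tables, and the validated run configuration.

#' Read a germinal center count table
#'
#' Two dialects are accepted. \emph{long}: columns \code{mouse_id},
#' \code{gc_id}, \code{time_h}, \code{color}, \code{count} and optionally
#' \code{occupation}; one row per (observation, color), colors drawn from
#' the canonical state set plus \code{"unlabeled"}. \emph{wide}: columns
#' \code{mouse_id}, \code{gc_id}, \code{time_h}, optionally
#' \code{occupation} and \code{unlabeled}, plus one column per canonical
#' color state. Unknown color labels, duplicate (mouse, GC, time, color)
#' rows and malformed values are rejected with informative errors naming
#' the offending rows.
#'
#' When unlabeled counts are present and \code{occupation} is absent, the
#' occupation fraction is computed as labeled / (labeled + unlabeled).
#' A \code{time_d} column (days) may be used instead of \code{time_h};
#' it is converted to hours at ingest.
#'
#' @param path CSV (or TSV) file path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @param sep field separator; inferred from the extension by default.
#' @return A \linkS4class{GCExperiment}.
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path, dialect = c("long", "wide"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  states <- colorStates()
  if ("time_d" %in% colnames(df) && !"time_h" %in% colnames(df)) {
    df$time_h <- 24 * df$time_d
    df$time_d <- NULL
  }
  if (dialect == "long") {
    need <- c("mouse_id", "gc_id", "time_h", "color", "count")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("missing required columns: ", paste(miss, collapse = ", "))
    bad <- !df$color %in% c(states, UNLABELED)
    if (any(bad))
      stop("unknown color label(s) ",
           paste(unique(df$color[bad]), collapse = ", "),
           " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
           "; canonical set: ", paste(states, collapse = ", "),
           ", ", UNLABELED)
    if (anyNA(df$count) || any(df$count < 0))
      stop("malformed counts at row(s) ",
           paste(utils::head(which(is.na(df$count) | df$count < 0), 5),
                 collapse = ", "))
    key4 <- paste(df$mouse_id, df$gc_id, df$time_h, df$color, sep = "\r")
    if (anyDuplicated(key4))
      stop("duplicate (mouse_id, gc_id, time_h, color) at row(s) ",
           paste(utils::head(which(duplicated(key4)), 5), collapse = ", "))
    key <- paste(df$mouse_id, df$gc_id, df$time_h, sep = "\r")
    obs <- unique(data.frame(mouse_id = df$mouse_id, gc_id = df$gc_id,
                             time_h = df$time_h, key = key,
                             stringsAsFactors = FALSE))
    counts <- matrix(0, nrow = length(states), ncol = nrow(obs),
                     dimnames = list(states, NULL))
    dark <- numeric(nrow(obs))
    idx <- match(key, obs$key)
    for (r in seq_len(nrow(df))) {
      if (df$color[r] == UNLABELED) {
        dark[idx[r]] <- dark[idx[r]] + df$count[r]
      } else {
        counts[df$color[r], idx[r]] <- counts[df$color[r], idx[r]] + df$count[r]
      }
    }
    occ <- if ("occupation" %in% colnames(df)) {
      vapply(seq_len(nrow(obs)), function(i)
        df$occupation[idx == i][1L], numeric(1))
    } else {
      lab <- colSums(counts)
      ifelse(lab + dark > 0, lab / (lab + dark), 0)
    }
    GCExperiment(counts, mouse_id = obs$mouse_id, gc_id = obs$gc_id,
                 time_h = obs$time_h, occupation = occ,
                 total_examined = colSums(counts) + dark)
  } else {
    need <- c("mouse_id", "gc_id", "time_h")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("missing required columns: ", paste(miss, collapse = ", "))
    extra <- setdiff(colnames(df),
                     c(need, "occupation", UNLABELED, states))
    if (length(extra))
      stop("unknown color column(s): ", paste(extra, collapse = ", "),
           "; canonical set: ", paste(states, collapse = ", "))
    missStates <- setdiff(states, colnames(df))
    if (length(missStates))
      stop("missing color column(s): ", paste(missStates, collapse = ", "))
    counts <- t(as.matrix(df[, states, drop = FALSE]))
    dark <- if (UNLABELED %in% colnames(df)) df[[UNLABELED]] else 0
    occ <- if ("occupation" %in% colnames(df)) df$occupation else {
      lab <- colSums(counts)
      ifelse(lab + dark > 0, lab / (lab + dark), 0)
    }
    GCExperiment(counts, mouse_id = df$mouse_id, gc_id = df$gc_id,
                 time_h = df$time_h, occupation = occ,
                 total_examined = colSums(counts) + dark)
  }
}

#' Write a germinal center count table
#'
#' Inverse of [readCounts()]; round-trips a \linkS4class{GCExperiment}
#' losslessly in either dialect. Labeled color states appear in canonical
#' order; unlabeled cells are written when \code{total_examined} exceeds
#' the labeled sum.
#'
#' @param gce a \linkS4class{GCExperiment}.
#' @param path output CSV path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(gce, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(is(gce, "GCExperiment"))
  cd <- SummarizedExperiment::colData(gce)
  counts <- SummarizedExperiment::assay(gce, "counts")
  dark <- pmax(cd$total_examined - colSums(counts), 0)
  states <- colorStates()
  if (dialect == "long") {
    n <- ncol(gce)
    rows <- data.frame(
      mouse_id = rep(cd$mouse_id, each = length(states)),
      gc_id = rep(cd$gc_id, each = length(states)),
      time_h = rep(cd$time_h, each = length(states)),
      color = rep(states, n),
      count = as.vector(counts),
      occupation = rep(cd$occupation, each = length(states))
    )
    darkRows <- data.frame(
      mouse_id = cd$mouse_id, gc_id = cd$gc_id, time_h = cd$time_h,
      color = UNLABELED, count = dark, occupation = cd$occupation
    )[dark > 0, , drop = FALSE]
    out <- rbind(rows, darkRows)
    out <- out[order(out$mouse_id, out$gc_id, out$time_h), , drop = FALSE]
  } else {
    out <- data.frame(mouse_id = cd$mouse_id, gc_id = cd$gc_id,
                      time_h = cd$time_h, occupation = cd$occupation,
                      t(counts), check.names = FALSE)
    if (any(dark > 0)) out[[UNLABELED]] <- dark
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a seeding (follicle growth) table
#'
#' @param path CSV with columns \code{follicle_id}, \code{time_h} (or
#'   \code{time_d}, converted), \code{count}.
#' @return data.frame ready for [fitSeedingTable()].
#' @export
readSeeding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_d" %in% colnames(df) && !"time_h" %in% colnames(df)) {
    df$time_h <- 24 * df$time_d
    df$time_d <- NULL
  }
  need <- c("follicle_id", "time_h", "count")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (anyNA(df$count) || any(df$count < 0)) stop("malformed counts")
  df[order(df$follicle_id, df$time_h), need]
}
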