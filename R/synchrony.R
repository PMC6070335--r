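## Cross-GC analyses: fidelity regression between paired in vivo and
## ex vivo clonality measurements, PCA of color compositions over
## (GC x time) observations, and tests for mouse-level association of the
## principal components (the inter-GC synchrony signal).

#' Fidelity regression of in vivo on ex vivo clonality measurements
#'
#' Ordinary least squares of the in vivo (window-imaged) value of a
#' clonality metric on the paired ex vivo (explant) value across
#' (mouse x time) units. A slope whose confidence interval contains 1
#' indicates that window imaging faithfully reproduces the explant
#' measurement ("fidelity pass").
#'
#' @param pairs data.frame with columns \code{value_in_vivo} and
#'   \code{value_ex_vivo} (one row per paired unit); or two numeric vectors
#'   via \code{value_in_vivo}/\code{value_ex_vivo}.
#' @param value_in_vivo,value_ex_vivo numeric vectors, used when
#'   \code{pairs} is missing.
#' @param level confidence level (default 0.95).
#' @return list with \code{slope} (\code{c(estimate, lo, hi)}),
#'   \code{intercept}, \code{fidelity_pass} (CI contains 1), \code{n},
#'   \code{r_squared}, and the underlying \code{lm} fit.
#' @examples
#' x <- seq(0.2, 0.9, length.out = 8)
#' fidelityRegression(data.frame(value_ex_vivo = x, value_in_vivo = x))$slope
#' @export
fidelityRegression <- function(pairs = NULL, value_in_vivo = NULL,
                               value_ex_vivo = NULL, level = 0.95) {
  if (!is.null(pairs)) {
    stopifnot(all(c("value_in_vivo", "value_ex_vivo") %in% colnames(pairs)))
    value_in_vivo <- pairs$value_in_vivo
    value_ex_vivo <- pairs$value_ex_vivo
  }
  if (length(value_in_vivo) < 3L)
    stop("at least 3 paired observations are required")
  if (stats::var(value_ex_vivo) == 0)
    stop("zero variance in the ex vivo predictor")
  fit <- stats::lm(value_in_vivo ~ value_ex_vivo)
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = level))
  slope <- c(estimate = unname(cf[2L]),
             lo = ci[2L, 1L], hi = ci[2L, 2L])
  # an exact linear relation has zero residual variance; its CI collapses
  slope[is.na(slope)] <- unname(cf[2L])
  list(slope = slope,
       intercept = unname(cf[1L]),
       fidelity_pass = slope[["lo"]] <= 1 && 1 <= slope[["hi"]],
       n = length(value_in_vivo),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Build the PCA feature matrix from observations
#'
#' One row per (GC x time) observation that passes the sparsity filter, one
#' column per canonical color state, entries the relative color
#' frequencies. Row metadata (mouse, GC, time) is returned alongside.
#'
#' @param gce a \linkS4class{GCExperiment}.
#' @param sparseThreshold occupation threshold (default 0.5).
#' @return list with \code{matrix} (n x 10, rows sum to 1) and
#'   \code{metadata} (data.frame with \code{mouse_id}, \code{gc_id},
#'   \code{time_h}).
#' @export
buildFeatureMatrix <- function(gce, sparseThreshold = 0.5) {
  stopifnot(is(gce, "GCExperiment"))
  gce <- filterSparse(gce, threshold = sparseThreshold)
  if (ncol(gce) == 0L) stop("no observations left after sparsity filtering")
  cd <- SummarizedExperiment::colData(gce)
  list(
    matrix = t(relativeFrequencies(gce)),
    metadata = data.frame(mouse_id = cd$mouse_id, gc_id = cd$gc_id,
                          time_h = cd$time_h, row.names = colnames(gce))
  )
}

#' PCAResult: principal components of GC color compositions
#'
#' @slot scores n x k matrix of component scores.
#' @slot loadings 10 x k orthonormal loading matrix.
#' @slot explainedVariance variance per component (non-increasing).
#' @slot center column means removed before rotation.
#' @slot metadata data.frame of row metadata (mouse, GC, time), aligned
#'   with \code{scores}.
#' @export
setClass("PCAResult",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", center = "numeric",
                 metadata = "data.frame")
)

setMethod("show", "PCAResult", function(object) {
  k <- ncol(object@scores)
  pct <- 100 * object@explainedVariance / sum(object@explainedVariance)
  cat("PCAResult:", nrow(object@scores), "observations,", k, "components\n")
  cat("  variance explained (% of retained):",
      paste(sprintf("PC%d=%.1f", seq_len(k), pct), collapse = " "), "\n")
})

#' Principal components analysis of the composition matrix
#'
#' Column-centered, unscaled PCA (all columns are frequencies sharing
#' units). Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x a feature matrix (n x 10), or the list from
#'   [buildFeatureMatrix()].
#' @param nComponents number of components retained (default 3).
#' @param metadata optional row metadata (taken from
#'   \code{buildFeatureMatrix} output automatically).
#' @return A \linkS4class{PCAResult}.
#' @export
runPCA <- function(x, nComponents = 3, metadata = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    if (is.null(metadata)) metadata <- x$metadata
    x <- x$matrix
  }
  x <- as.matrix(x)
  if (nrow(x) < nComponents + 1L)
    stop("need at least nComponents + 1 rows")
  if (all(apply(x, 2L, stats::var) == 0))
    stop("all rows identical: zero variance, PCA undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (is.null(metadata))
    metadata <- data.frame(row.names = rownames(x) %||% seq_len(nrow(x)))
  new("PCAResult", scores = sco, loadings = rot,
      explainedVariance = pc$sdev[seq_len(k)]^2,
      center = pc$center, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test association of principal components with individual mice
#'
#' For each retained component, fits a linear model of the scores on the
#' mouse factor plus covariates (time, and treatment when present) and
#' reports the mouse-factor F test, together with per-mouse indicator
#' contrasts (each mouse vs the rest, same covariate adjustment).
#'
#' @param pca a \linkS4class{PCAResult}, or a scores matrix.
#' @param metadata data.frame with \code{mouse_id}, \code{time_h} and
#'   optionally \code{treatment}; taken from the \code{PCAResult} when
#'   omitted.
#' @return list with \code{components} (data.frame: component, F statistic,
#'   df, p value for the mouse factor) and \code{per_mouse} (data.frame:
#'   component, mouse, estimate, p value).
#' @export
testMouseAssociation <- function(pca, metadata = NULL) {
  if (is(pca, "PCAResult")) {
    scores <- pca@scores
    if (is.null(metadata)) metadata <- pca@metadata
  } else {
    scores <- as.matrix(pca)
  }
  if (is.null(metadata) || !"mouse_id" %in% colnames(metadata))
    stop("metadata with a 'mouse_id' column is required")
  mouse <- factor(metadata$mouse_id)
  if (nlevels(mouse) < 2L)
    stop("at least two mice are required for a between-mouse contrast")
  covs <- list()
  if ("time_h" %in% colnames(metadata)) covs$time_h <- metadata$time_h
  if ("treatment" %in% colnames(metadata) &&
      length(unique(metadata$treatment)) > 1L)
    covs$treatment <- factor(metadata$treatment)
  compRows <- list(); mouseRows <- list()
  for (j in seq_len(ncol(scores))) {
    y <- scores[, j]
    if (stats::var(y) == 0)
      stop("zero-variance scores for component ", j, ": degenerate model")
    df <- data.frame(y = y, mouse = mouse, covs)
    full <- stats::lm(y ~ ., data = df)
    red <- stats::lm(y ~ . - mouse, data = df)
    av <- stats::anova(red, full)
    compRows[[j]] <- data.frame(
      component = paste0("PC", j),
      statistic = av$F[2L], df1 = av$Df[2L], df2 = av$Res.Df[2L],
      p_value = av$`Pr(>F)`[2L])
    for (m in levels(mouse)) {
      dfm <- data.frame(y = y, is_m = mouse == m, covs)
      fm <- stats::lm(y ~ ., data = dfm)
      sm <- summary(fm)$coefficients
      row <- grep("^is_m", rownames(sm))
      mouseRows[[length(mouseRows) + 1L]] <- data.frame(
        component = paste0("PC", j), mouse = m,
        estimate = sm[row, 1L], p_value = sm[row, 4L])
    }
  }
  list(components = do.call(rbind, compRows),
       per_mouse = {
         pm <- do.call(rbind, mouseRows); rownames(pm) <- NULL; pm
       })
}
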