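## Synthetic generator of Confetti-labeled germinal center clonal dynamics:
## exponential seeding, Wright-Fisher evolution with selection and mutation,
## optional inter-GC reentry coupling, and the manual-counting observation
## model (multinomial sampling across z-planes).

# Evaluate expr with a temporary RNG state seeded by `seed` (NULL = use the
# current stream). Restores the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration for germinal center clonal dynamics
#'
#' Bundles and validates all tunable parameters of the generator. Defaults
#' emulate the study conditions of longitudinal single-GC Confetti imaging:
#' founder cohorts of order 100 cells, a mature GC of ~1500 B cells, a 6 h
#' generation (the fastest fitted seeding doubling time), manual counts of
#' 250 cells per GC and time point split over 3 z-planes, 4 GCs per mouse,
#' and observation on alternating days from day 7 to day 19.
#'
#' @param nFounders number of founder cells seeding the GC.
#' @param populationCap mature GC population size (cells); held exactly
#'   constant once reached.
#' @param generationHours duration of one division/resampling generation.
#' @param fitnessSd standard deviation of founder log-fitness (selection
#'   strength; 0 = neutral).
#' @param mutationRate per-cell per-generation probability of a fitness
#'   mutation.
#' @param mutationSd standard deviation of log-fitness mutation steps.
#' @param nGcsPerMouse number of GCs simulated per mouse.
#' @param reentryRate per-GC per-generation probability that its fittest
#'   clone is exported via a shared mouse-level pool into another GC of the
#'   same mouse.
#' @param reentryFraction injected abundance as a fraction of
#'   \code{populationCap} (at least one cell).
#' @param recombination a \linkS4class{RecombinationModel} assigning
#'   heritable founder colors (including unlabeled).
#' @param samplingDepth cells counted per observation.
#' @param nZplanes number of independent z-plane sub-draws per observation.
#' @param recordTimesH times (hours) at which the trajectory is recorded.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nFounders = 100,
                      populationCap = 1500,
                      generationHours = 6,
                      fitnessSd = 0.1,
                      mutationRate = 0.01,
                      mutationSd = 0.1,
                      nGcsPerMouse = 4,
                      reentryRate = 0,
                      reentryFraction = 0.01,
                      recombination = RecombinationModel(),
                      samplingDepth = 250,
                      nZplanes = 3,
                      recordTimesH = 24 * seq(7, 19, by = 2)) {
  cfg <- list(nFounders = nFounders, populationCap = populationCap,
              generationHours = generationHours, fitnessSd = fitnessSd,
              mutationRate = mutationRate, mutationSd = mutationSd,
              nGcsPerMouse = nGcsPerMouse, reentryRate = reentryRate,
              reentryFraction = reentryFraction, recombination = recombination,
              samplingDepth = samplingDepth, nZplanes = nZplanes,
              recordTimesH = sort(as.numeric(recordTimesH)))
  stopifnot(
    cfg$nFounders >= 1, cfg$populationCap >= 1, cfg$generationHours > 0,
    cfg$fitnessSd >= 0, cfg$mutationSd >= 0,
    cfg$mutationRate >= 0, cfg$mutationRate <= 1,
    cfg$nGcsPerMouse >= 1,
    cfg$reentryRate >= 0, cfg$reentryRate <= 1,
    cfg$reentryFraction > 0, cfg$reentryFraction <= 1,
    cfg$samplingDepth >= 1, cfg$nZplanes >= 1,
    length(cfg$recordTimesH) >= 1, all(cfg$recordTimesH >= 0)
  )
  validObject(cfg$recombination)
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:\n")
  flat <- x[!vapply(x, is, logical(1), "RecombinationModel")]
  for (nm in names(flat))
    cat(sprintf("  %-16s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  show(x$recombination)
  invisible(x)
}

#' GCTrajectory: simulated clonal history of one germinal center
#'
#' @slot mouseId,gcId identifiers.
#' @slot times recorded times in hours.
#' @slot cloneTables list (one per time) of data.frames with columns
#'   \code{clone_id}, \code{color}, \code{log_fitness}, \code{count}.
#' @slot colorCounts (10+1) x T matrix of cell counts per canonical color
#'   state plus \code{"unlabeled"}; columns sum to the population size.
#' @slot extinct TRUE if the population died out before the first recorded
#'   time.
#' @export
setClass("GCTrajectory",
  representation(mouseId = "character", gcId = "character",
                 times = "numeric", cloneTables = "list",
                 colorCounts = "matrix", extinct = "logical")
)

setMethod("show", "GCTrajectory", function(object) {
  cat("GCTrajectory", paste0(object@mouseId, "/", object@gcId), "-",
      length(object@times), "recorded times,",
      "final population", sum(object@colorCounts[, ncol(object@colorCounts)]),
      if (object@extinct) "(extinct)" else "", "\n")
})

# --- internal Wright-Fisher machinery ---------------------------------------

# Clone table in the hot loop: a list of parallel vectors
# (clone_id, color, log_fitness, count); materialized as a data.frame only
# when a time point is recorded.
newFounders <- function(cfg, idOffset = 0L) {
  n <- cfg$nFounders
  list(
    clone_id = idOffset + seq_len(n),
    color = sampleColorStates(n, cfg$recombination),
    log_fitness = if (cfg$fitnessSd > 0) stats::rnorm(n, 0, cfg$fitnessSd) else numeric(n),
    count = rep(1, n)
  )
}

cloneSubset <- function(cl, keep) {
  list(clone_id = cl$clone_id[keep], color = cl$color[keep],
       log_fitness = cl$log_fitness[keep], count = cl$count[keep])
}

# One generation. Growth phase: fitness-weighted Poisson branching with mean
# factor-2 growth; once at/above cap, fitness-weighted multinomial resampling
# at exactly `cap` cells (Wright-Fisher with selection via differential
# survival). Mutation perturbs log-fitness of a binomial share of each clone.
wfStep <- function(clones, cfg, nextId) {
  total <- sum(clones$count)
  if (total <= 0) return(list(clones = clones, nextId = nextId))
  w <- exp(clones$log_fitness)
  if (total < cfg$populationCap) {
    wbar <- sum(clones$count * w) / total
    lambda <- clones$count * 2 * w / wbar
    clones$count <- stats::rpois(length(lambda), lambda)
    if (sum(clones$count) > cfg$populationCap) {
      clones$count <- as.numeric(stats::rmultinom(
        1L, cfg$populationCap, clones$count))
    }
  } else {
    clones$count <- as.numeric(stats::rmultinom(
      1L, cfg$populationCap, clones$count * w))
  }
  clones <- cloneSubset(clones, clones$count > 0)
  if (cfg$mutationRate > 0 && length(clones$count) > 0) {
    nMut <- stats::rbinom(length(clones$count), size = clones$count,
                          prob = cfg$mutationRate)
    hit <- which(nMut > 0)
    if (length(hit)) {
      newIds <- nextId + seq_along(hit)
      nextId <- nextId + length(hit)
      mutFit <- clones$log_fitness[hit] +
        stats::rnorm(length(hit), 0, cfg$mutationSd)
      clones$count[hit] <- clones$count[hit] - nMut[hit]
      keep <- clones$count > 0
      clones <- list(
        clone_id = c(clones$clone_id[keep], newIds),
        color = c(clones$color[keep], clones$color[hit]),
        log_fitness = c(clones$log_fitness[keep], mutFit),
        count = c(clones$count[keep], nMut[hit])
      )
    }
  }
  list(clones = clones, nextId = nextId)
}

colorCountsOf <- function(clones) {
  lv <- c(colorStates(), UNLABELED)
  out <- stats::setNames(numeric(length(lv)), lv)
  if (length(clones$count)) {
    agg <- rowsum(clones$count, factor(clones$color, levels = lv))
    out[rownames(agg)] <- agg[, 1L]
  }
  out
}

# Lockstep core for >=1 GCs of one mouse; consumes a single RNG stream.
# `founders` optionally overrides the random founder draw with an explicit
# clone table (clone_id, color, log_fitness, count), replicated per GC.
simulateGCsCore <- function(cfg, nGCs, mouseId, seed, founders = NULL) {
  withSeed(seed, {
    recordGens <- round(cfg$recordTimesH / cfg$generationHours)
    maxGen <- max(recordGens)
    gcs <- vector("list", nGCs)
    nextId <- 0L
    for (g in seq_len(nGCs)) {
      if (is.null(founders)) {
        gcs[[g]] <- newFounders(cfg, idOffset = nextId)
        nextId <- nextId + cfg$nFounders
      } else {
        f <- list(clone_id = founders$clone_id + nextId,
                  color = as.character(founders$color),
                  log_fitness = as.numeric(founders$log_fitness),
                  count = as.numeric(founders$count))
        gcs[[g]] <- f
        nextId <- nextId + max(founders$clone_id)
      }
    }
    rec <- lapply(seq_len(nGCs), function(g) list())
    recordState <- function(g, slot) {
      rec[[g]][[slot]] <<- gcs[[g]]
    }
    slot <- 0L
    if (0L %in% recordGens) {
      slot <- slot + 1L
      for (g in seq_len(nGCs)) recordState(g, slot)
    }
    for (gen in seq_len(maxGen)) {
      for (g in seq_len(nGCs)) {
        st <- wfStep(gcs[[g]], cfg, nextId)
        gcs[[g]] <- st$clones
        nextId <- st$nextId
      }
      if (nGCs > 1L && cfg$reentryRate > 0) {
        inject <- max(1, round(cfg$reentryFraction * cfg$populationCap))
        for (g in seq_len(nGCs)) {
          if (stats::runif(1) < cfg$reentryRate && length(gcs[[g]]$count) > 0) {
            d <- which.max(gcs[[g]]$log_fitness)
            target <- sample(setdiff(seq_len(nGCs), g), 1L)
            tg <- gcs[[target]]
            gcs[[target]] <- list(
              clone_id = c(tg$clone_id, nextId + 1L),
              color = c(tg$color, gcs[[g]]$color[d]),
              log_fitness = c(tg$log_fitness, gcs[[g]]$log_fitness[d]),
              count = c(tg$count, inject)
            )
            nextId <- nextId + 1L
          }
        }
      }
      if (gen %in% recordGens) {
        slot <- slot + 1L
        for (g in seq_len(nGCs)) recordState(g, slot)
      }
    }
    lapply(seq_len(nGCs), function(g) {
      tabs <- rec[[g]]
      cc <- vapply(tabs, colorCountsOf,
                   numeric(length(colorStates()) + 1L))
      tabs <- lapply(tabs, function(cl)
        data.frame(clone_id = cl$clone_id, color = cl$color,
                   log_fitness = cl$log_fitness, count = cl$count))
      new("GCTrajectory",
          mouseId = mouseId, gcId = sprintf("GC%02d", g),
          times = cfg$recordTimesH[seq_along(tabs)],
          cloneTables = tabs, colorCounts = cc,
          extinct = sum(cc[, 1L]) == 0)
    })
  })
}

#' Simulate one germinal center trajectory
#'
#' Founders receive heritable colors from the recombination model and
#' log-fitness values from Normal(0, fitnessSd). The population grows by
#' fitness-weighted branching to \code{populationCap}, then evolves by
#' fitness-weighted multinomial resampling at constant size (Wright-Fisher
#' with selection acting through differential survival). Fitness mutations
#' arise at \code{mutationRate} per cell per generation. Extinction before
#' the first recorded time is flagged, not an error.
#'
#' @param config a [simConfig()] object.
#' @param seed integer seed (reproducible trajectories) or NULL.
#' @param mouseId,gcId identifiers stored in the result.
#' @param founders optional explicit founder clone table (columns
#'   \code{clone_id}, \code{color}, \code{log_fitness}, \code{count})
#'   overriding the random founder draw; useful for controlled scenarios.
#' @return A \linkS4class{GCTrajectory}.
#' @examples
#' tr <- simulateGCTrajectory(simConfig(), seed = 1)
#' tr
#' @export
simulateGCTrajectory <- function(config = simConfig(), seed = NULL,
                                 mouseId = "m1", gcId = "GC01",
                                 founders = NULL) {
  tr <- simulateGCsCore(config, nGCs = 1L, mouseId = mouseId, seed = seed,
                        founders = founders)[[1L]]
  tr@gcId <- gcId
  tr
}

#' Simulate all germinal centers of one mouse
#'
#' Runs \code{nGcsPerMouse} GCs in generation lockstep. When
#' \code{reentryRate > 0}, each generation each GC exports, with that
#' probability, its fittest clone through a shared mouse-level pool into a
#' randomly chosen other GC at low abundance (\code{reentryFraction} of the
#' population cap) — an artifact-level generator of the hypothesized
#' memory-B-cell reentry coupling between GCs. With \code{reentryRate = 0}
#' the GCs are independent, and with a single GC the result has exactly the
#' law (and RNG stream) of [simulateGCTrajectory()].
#'
#' @inheritParams simulateGCTrajectory
#' @return List of \linkS4class{GCTrajectory}, one per GC.
#' @export
simulateMouse <- function(config = simConfig(), seed = NULL, mouseId = "m1") {
  simulateGCsCore(config, nGCs = config$nGcsPerMouse,
                  mouseId = mouseId, seed = seed)
}

#' Simulate an exponentially growing seeding trajectory
#'
#' Early labeled cells expand exponentially within a follicle; this draws a
#' per-follicle count series with mean \eqn{y_0 e^{k t}}, optionally with
#' Poisson count noise.
#'
#' @param y0 initial abundance (cells) at t = 0; must be nonnegative.
#' @param k growth rate per hour.
#' @param times observation times in hours, strictly increasing.
#' @param noise \code{"none"} (deterministic mean) or \code{"poisson"}.
#' @param seed integer seed or NULL.
#' @param follicleId identifier stored in the result.
#' @return data.frame with columns \code{follicle_id}, \code{time_h},
#'   \code{count}.
#' @examples
#' simulateSeeding(2, 0.5, times = 0:3)
#' @export
simulateSeeding <- function(y0, k, times, noise = c("none", "poisson"),
                            seed = NULL, follicleId = "Fo1") {
  noise <- match.arg(noise)
  if (!is.numeric(y0) || length(y0) != 1L || is.na(y0) || y0 < 0)
    stop("'y0' must be a single nonnegative number")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("'times' must be nonempty and strictly increasing")
  mu <- y0 * exp(k * times)
  count <- switch(noise,
    none = mu,
    poisson = withSeed(seed, stats::rpois(length(mu), mu))
  )
  data.frame(follicle_id = follicleId, time_h = as.numeric(times),
             count = as.numeric(count))
}

#' Sample a manual-count observation from a color composition
#'
#' The observation model of manual counting: \code{depth} cells are drawn
#' multinomially from the labeled color composition, partitioned into
#' \code{nZplanes} independent sub-draws (z-planes spaced to preclude double
#' counting). The labeled occupation fraction is carried into the
#' observation's metadata for the downstream sparsity filter.
#'
#' @param abundance named nonnegative vector of cell abundances over the 10
#'   canonical states, optionally including \code{"unlabeled"}.
#' @param depth number of cells counted (default 250).
#' @param labeledFraction occupation fraction to record; if NULL, computed
#'   from \code{abundance} when it includes unlabeled cells, else 1.
#' @param nZplanes number of z-plane sub-draws.
#' @param seed integer seed or NULL.
#' @param mouseId,gcId,timeH metadata for the observation.
#' @return A one-column \linkS4class{GCExperiment}.
#' @examples
#' ab <- setNames(c(500, 500, rep(0, 8)), colorStates())
#' sampleObservation(ab, depth = 250, seed = 1)
#' @export
sampleObservation <- function(abundance, depth = 250, labeledFraction = NULL,
                              nZplanes = 3, seed = NULL,
                              mouseId = "m1", gcId = "GC01", timeH = 0) {
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("'depth' must be a positive count")
  states <- colorStates()
  if (is.null(names(abundance))) {
    stopifnot(length(abundance) == length(states))
    names(abundance) <- states
  }
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  bad <- setdiff(names(abundance), c(states, UNLABELED))
  if (length(bad))
    stop("unknown color state(s): ", paste(bad, collapse = ", "))
  lab <- stats::setNames(numeric(length(states)), states)
  common <- intersect(states, names(abundance))
  lab[common] <- abundance[common]
  total <- sum(abundance)
  if (total <= 0) stop("abundance must have positive total")
  if (sum(lab) <= 0) stop("no labeled cells to sample")
  if (is.null(labeledFraction)) {
    labeledFraction <- if (UNLABELED %in% names(abundance))
      sum(lab) / total else 1
  }
  depth <- as.integer(round(depth))
  sizes <- diff(round(seq(0, depth, length.out = nZplanes + 1L)))
  counts <- withSeed(seed, {
    draws <- vapply(sizes, function(sz)
      as.numeric(stats::rmultinom(1L, sz, lab)), numeric(length(states)))
    rowSums(draws)
  })
  GCExperiment(matrix(counts, ncol = 1L, dimnames = list(states, NULL)),
               mouse_id = mouseId, gc_id = gcId, time_h = timeH,
               occupation = labeledFraction, total_examined = depth)
}

#' Sample observations along simulated trajectories
#'
#' Applies the manual-counting observation model at every recorded time of
#' one or more simulated trajectories, producing the count container the
#' analysis functions consume.
#'
#' @param trajectories a \linkS4class{GCTrajectory} or list of them.
#' @param config a [simConfig()] supplying \code{samplingDepth} and
#'   \code{nZplanes}.
#' @param seed integer seed or NULL.
#' @return A \linkS4class{GCExperiment} with one column per (GC, time).
#' @export
sampleTrajectories <- function(trajectories, config = simConfig(), seed = NULL) {
  if (is(trajectories, "GCTrajectory")) trajectories <- list(trajectories)
  withSeed(seed, {
    cols <- list()
    for (tr in trajectories) {
      cc <- tr@colorCounts
      for (j in seq_along(tr@times)) {
        ab <- cc[, j]
        if (sum(ab[colorStates()]) <= 0) next  # extinct or fully dark
        cols[[length(cols) + 1L]] <- sampleObservation(
          ab, depth = config$samplingDepth, nZplanes = config$nZplanes,
          mouseId = tr@mouseId, gcId = tr@gcId, timeH = tr@times[j])
      }
    }
    if (!length(cols)) stop("no observable (labeled, non-extinct) states to sample")
    do.call(cbind, cols)
  })
}
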