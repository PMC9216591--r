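#' Degree-preserving connected rewiring by double-edge swaps
#'
#' Randomises a connected simple network while keeping every node's degree
#' fixed: two edges \eqn{(u,v)} and \eqn{(x,y)} are replaced by
#' \eqn{(u,x)} and \eqn{(v,y)}. A swap is rejected if it would create a
#' self-loop or a duplicate edge; connectivity is enforced by checking the
#' network every few accepted swaps and rolling the window back when it
#' breaks. Swapping continues until \code{swapMultiplier} times the edge
#' count of \emph{accepted} swaps have been committed (default 10x), with an
#' attempt cap of 100 times the target after which the run aborts.
#'
#' Degenerate networks admitting no valid swap (e.g. a triangle) are
#' returned unchanged with a warning.
#'
#' @param net connected simple \code{igraph} with at least 2 edges.
#' @param swapMultiplier accepted swaps per edge (default 10).
#' @param seed RNG seed.
#' @param window accepted swaps between connectivity checks (default 10).
#' @return a rewired \code{igraph} with the identical degree sequence.
#' @export
rewireNetwork <- function(net, swapMultiplier = 10, seed = 1L, window = 10L) {
  checkNetwork(net, connected = TRUE)
  m <- igraph::ecount(net)
  if (m < 2L) stop("need at least 2 edges to rewire")
  stopifnot(isSingleNumber(swapMultiplier), swapMultiplier > 0)
  el <- igraph::as_edgelist(net, names = FALSE)
  nodeNames <- igraph::V(net)$name
  n <- length(nodeNames)
  target <- ceiling(swapMultiplier * m)
  cap <- 100 * target
  set.seed(as.integer(seed))

  keys <- new.env(hash = TRUE, size = 2L * m)
  for (i in seq_len(m)) assign(edgeKey(el[i, 1L], el[i, 2L]), TRUE, keys)
  hasEdge <- function(a, b) !is.null(keys[[edgeKey(a, b)]])

  accepted <- 0L
  attempts <- 0L
  windowStart <- el        # committed state to roll back to
  pendingSwaps <- list()   # (edge index, old a, old b) records in window
  pending <- 0L

  commitOrRollback <- function() {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ok <- igraph::is_connected(g)
    if (ok) {
      windowStart <<- el
      accepted <<- accepted + pending
    } else {
      el <<- windowStart
      ## rebuild the key set from the rolled-back edge list
      rm(list = ls(keys), envir = keys)
      for (i in seq_len(m)) assign(edgeKey(el[i, 1L], el[i, 2L]), TRUE, keys)
    }
    pending <<- 0L
  }

  while (accepted + pending < target) {
    attempts <- attempts + 1L
    if (attempts > cap) {
      if (accepted == 0L) {
        warning("no valid degree-preserving swap found; returning input")
        return(net)
      }
      stop("rewiring stalled after ", attempts, " attempts (",
           accepted + pending, "/", target, " swaps)")
    }
    e <- sample.int(m, 2L)
    u <- el[e[1L], 1L]; v <- el[e[1L], 2L]
    x <- el[e[2L], 1L]; y <- el[e[2L], 2L]
    if (runif(1L) < 0.5) { tmp <- x; x <- y; y <- tmp }
    ## propose (u,x) and (v,y)
    if (u == x || v == y) next
    if (hasEdge(u, x) || hasEdge(v, y)) next
    rm(list = c(edgeKey(u, v), edgeKey(x, y)), envir = keys)
    assign(edgeKey(u, x), TRUE, keys)
    assign(edgeKey(v, y), TRUE, keys)
    el[e[1L], ] <- c(u, x)
    el[e[2L], ] <- c(v, y)
    pending <- pending + 1L
    if (pending >= window) commitOrRollback()
  }
  if (pending > 0L) commitOrRollback()
  while (accepted < target) {
    ## a rollback at the tail can leave us short; keep swapping
    if (attempts > cap) stop("rewiring stalled near completion")
    attempts <- attempts + 1L
    e <- sample.int(m, 2L)
    u <- el[e[1L], 1L]; v <- el[e[1L], 2L]
    x <- el[e[2L], 1L]; y <- el[e[2L], 2L]
    if (runif(1L) < 0.5) { tmp <- x; x <- y; y <- tmp }
    if (u == x || v == y) next
    if (hasEdge(u, x) || hasEdge(v, y)) next
    rm(list = c(edgeKey(u, v), edgeKey(x, y)), envir = keys)
    assign(edgeKey(u, x), TRUE, keys)
    assign(edgeKey(v, y), TRUE, keys)
    el[e[1L], ] <- c(u, x)
    el[e[2L], ] <- c(v, y)
    pending <- pending + 1L
    commitOrRollback()
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- nodeNames[as.integer(igraph::V(g))]
  g
}

#' Empirical p-value from a null sample
#'
#' \eqn{p = (r+1)/(n+1)} where \eqn{r} counts null values at least as
#' extreme as the observation in the stated direction; ties count as extreme
#' (conservative). The p-value is therefore bounded in
#' \eqn{[1/(n+1), 1]} and never exactly zero.
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of null-model statistics.
#' @param direction \code{"greater"} (observation hypothesised larger than
#'   null) or \code{"less"}.
#' @return list with \code{observed}, \code{r}, \code{n}, \code{p},
#'   \code{direction}.
#' @export
empiricalPValue <- function(observed, nullValues,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(isSingleNumber(observed), is.numeric(nullValues),
            length(nullValues) >= 1L)
  r <- if (direction == "greater") sum(nullValues >= observed)
       else sum(nullValues <= observed)
  n <- length(nullValues)
  list(observed = observed, r = as.integer(r), n = as.integer(n),
       p = (r + 1) / (n + 1), direction = direction)
}

#' Permutation test for a group-mean difference
#'
#' Statistic: \code{mean(values[group]) - mean(values[rest])}. The node
#' labels are shuffled \code{nShuffles} times (default 10,000) and the
#' p-value computed as \eqn{(r+1)/(n+1)} with ties counted as exceedances.
#'
#' @param values named per-node statistic (e.g. effectiveness).
#' @param group node labels forming the group; must be a proper nonempty
#'   subset.
#' @param nShuffles number of label shuffles.
#' @param seed RNG seed.
#' @param direction \code{"greater"} tests whether the group mean exceeds
#'   the rest; \code{"less"} the reverse.
#' @return list as in [empiricalPValue()] plus \code{nullValues}.
#' @export
permutationTest <- function(values, group, nShuffles = 10000L, seed = 1L,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(group %in% names(values)), length(group) >= 1L)
  n <- length(values)
  k <- length(group)
  if (k >= n) stop("group must be a proper subset of the nodes")
  inGroup <- names(values) %in% group
  observed <- mean(values[inGroup]) - mean(values[!inGroup])
  tot <- sum(values)
  set.seed(as.integer(seed))
  nullValues <- vapply(seq_len(nShuffles), function(s) {
    gs <- sum(values[sample.int(n, k)])
    gs / k - (tot - gs) / (n - k)
  }, numeric(1L))
  out <- empiricalPValue(observed, nullValues, direction)
  out$nullValues <- nullValues
  out
}

#' Rewired-ensemble summary statistics
#'
#' Runs the full analysis pipeline — GNM, PRS, sensor selection, sensor
#' clustering — on \code{nReplicates} connected degree-preserving rewirings
#' of a network and collects per-replicate summaries: mean effectiveness and
#' sensitivity, degree-effectiveness Pearson r, degree-sensitivity Spearman
#' rho, and the number of sensor clusters and antenna clusters found.
#' Per-replicate seeds are spawned deterministically from the master seed.
#'
#' @param net connected \code{igraph}.
#' @param nReplicates number of rewired replicates (default 100).
#' @param seed master seed.
#' @param swapMultiplier accepted swaps per edge for each rewiring.
#' @param convention PRS convention.
#' @param sensorFraction top-sensitivity fraction for sensor selection.
#' @param minClusterSize minimum sensor-cluster size.
#' @return a [RewiredEnsemble-class].
#' @export
ensembleStats <- function(net, nReplicates = 100L, seed = 1L,
                          swapMultiplier = 10, convention = "squared",
                          sensorFraction = 0.01, minClusterSize = 3L) {
  checkNetwork(net, connected = TRUE)
  seeds <- spawnSeeds(seed, nReplicates)
  deg <- igraph::degree(net)
  rows <- lapply(seq_len(nReplicates), function(i) {
    g <- rewireNetwork(net, swapMultiplier = swapMultiplier, seed = seeds[i])
    prs <- computePRS(gnmCovariance(gnmModel(g)), convention = convention)
    eff <- effectiveness(prs)
    sens <- sensitivity(prs)
    d <- deg[names(eff)]
    sensors <- selectTop(sens, sensorFraction, role = "sensor")
    cl <- findClusters(sensors, g, minSize = minClusterSize)
    data.frame(
      replicate = i, seed = seeds[i],
      mean_effectiveness = mean(eff), mean_sensitivity = mean(sens),
      degree_effectiveness_r = cor(d, eff, method = "pearson"),
      degree_sensitivity_rho = cor(d, sens, method = "spearman"),
      n_sensor_clusters = length(cl$clusters),
      n_antenna_clusters = sum(vapply(cl$clusters, isAntenna, logical(1L)))
    )
  })
  new("RewiredEnsemble", summaries = do.call(rbind, rows),
      seeds = as.integer(seeds), masterSeed = as.numeric(seed),
      params = list(nReplicates = nReplicates,
                    swapMultiplier = swapMultiplier,
                    convention = convention,
                    sensorFraction = sensorFraction,
                    minClusterSize = minClusterSize))
}

#' @describeIn ensembleStats accessor for the per-replicate summary table.
#' @param x a \code{RewiredEnsemble}.
#' @export
ensembleSummaries <- function(x) {
  stopifnot(is(x, "RewiredEnsemble"))
  x@summaries
}

setMethod("show", "RewiredEnsemble", function(object) {
  cat("RewiredEnsemble:", nrow(object@summaries), "replicates (master seed",
      object@masterSeed, ")\n")
  print(head(object@summaries, 3L))
})
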