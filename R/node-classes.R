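#' Select the top-percentile nodes of a profile
#'
#' Sensors are the nodes with the largest sensitivity and effectors those
#' with the largest effectiveness. The selection size is
#' \code{k = round(fraction * n)} with halves rounded away from zero — the
#' rule consistent with the published selections (1% of 5,183 genes is 52
#' sensors, 1% of 3,238 is 32, 5% of 1,145 is 57). Ties at the k-th value
#' are broken by descending value then ascending node label.
#'
#' @param values named per-node profile (sensitivity or effectiveness).
#' @param fraction selection fraction in (0, 1).
#' @param role \code{"sensor"} or \code{"effector"} (metadata only; the
#'   caller chooses which profile to pass).
#' @return a [NodeClassSet-class].
#' @examples
#' selectionSize(5183, 0.01)  # 52
#' @export
selectTop <- function(values, fraction, role = c("sensor", "effector")) {
  role <- match.arg(role)
  stopifnot(is.numeric(values), !is.null(names(values)),
            isSingleNumber(fraction), fraction > 0, fraction < 1)
  n <- length(values)
  k <- selectionSize(n, fraction)
  if (k < 1L) stop("fraction yields an empty selection")
  ord <- order(-values, names(values))
  members <- names(values)[ord][seq_len(k)]
  new("NodeClassSet", role = role, fraction = fraction,
      members = members, values = values)
}

#' @describeIn selectTop the selection size rule,
#'   \code{round(fraction * n)} half away from zero.
#' @param n number of nodes.
#' @export
selectionSize <- function(n, fraction) {
  as.integer(roundHalfAway(fraction * n))
}

#' @describeIn selectTop accessor for the selected node labels.
#' @param x a \code{NodeClassSet}.
#' @export
classMembers <- function(x) {
  stopifnot(is(x, "NodeClassSet"))
  x@members
}

setMethod("show", "NodeClassSet", function(object) {
  cat("NodeClassSet: ", length(object@members), " ", object@role,
      "s (top ", format(100 * object@fraction), "% of ",
      length(object@values), " nodes)\n", sep = "")
})

#' Connected clusters of a node class
#'
#' Induces the subgraph on the class members only and takes its connected
#' components. Components with at least \code{minSize} members (default 3,
#' the published cluster definition) become [NodeCluster-class] objects,
#' labelled by descending size with ties broken by smallest member label;
#' smaller components are returned separately as unclustered members.
#' Antenna detection ([detectAntenna()]) is applied to every cluster.
#'
#' @param cls a [NodeClassSet-class] (or plain character vector of members).
#' @param net the full network.
#' @param minSize minimum cluster size (default 3).
#' @return list with elements \code{clusters} (list of
#'   [NodeCluster-class]) and \code{unclustered} (character).
#' @export
findClusters <- function(cls, net, minSize = 3L) {
  members <- if (is(cls, "NodeClassSet")) classMembers(cls) else cls
  checkNetwork(net)
  stopifnot(all(members %in% igraph::V(net)$name), minSize >= 1L)
  sub <- igraph::induced_subgraph(net, members)
  comp <- igraph::components(sub)
  groups <- split(igraph::V(sub)$name, comp$membership)
  sizes <- lengths(groups)
  keep <- sizes >= minSize
  unclustered <- sort(unlist(groups[!keep], use.names = FALSE))
  if (is.null(unclustered)) unclustered <- character()
  groups <- groups[keep]
  if (length(groups)) {
    firsts <- vapply(groups, min, character(1L))
    ord <- order(-lengths(groups), firsts)
    groups <- groups[ord]
  }
  clusters <- lapply(seq_along(groups), function(i) {
    anteced <- detectAntenna(groups[[i]], members, net)
    new("NodeCluster", id = paste0("C", i),
        members = sort(groups[[i]]),
        connectors = anteced$connectors, isAntenna = anteced$isAntenna)
  })
  list(clusters = clusters, unclustered = unclustered)
}

#' Antenna-motif detection for a node cluster
#'
#' The connectors of a cluster are the non-class nodes adjacent to any
#' cluster member. A cluster is an antenna motif when it touches the rest of
#' the network through exactly one connector — the bottleneck through which
#' perturbations enter but cannot easily leave.
#'
#' @param cluster a [NodeCluster-class] or character vector of members.
#' @param cls the node class (a [NodeClassSet-class] or character vector);
#'   connectors are sought outside the class.
#' @param net the full network.
#' @return list with \code{isAntenna} (logical) and \code{connectors}
#'   (character).
#' @export
detectAntenna <- function(cluster, cls, net) {
  members <- if (is(cluster, "NodeCluster")) cluster@members else cluster
  classMem <- if (is(cls, "NodeClassSet")) classMembers(cls) else cls
  checkNetwork(net)
  if (length(setdiff(igraph::V(net)$name, members)) == 0L)
    stop("cluster spans the whole network; antenna detection undefined")
  nbIdx <- unique(unlist(igraph::adjacent_vertices(net, members)))
  nb <- igraph::V(net)$name[nbIdx]
  connectors <- sort(setdiff(nb, classMem))
  list(isAntenna = length(connectors) == 1L, connectors = connectors)
}

setMethod("show", "NodeCluster", function(object) {
  cat("NodeCluster ", object@id, ": ", length(object@members), " members, ",
      length(object@connectors), " connector(s)",
      if (object@isAntenna) " [antenna]" else "", "\n", sep = "")
})

#' @describeIn findClusters accessor for a cluster's member labels.
#' @param x a \code{NodeCluster}.
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "NodeCluster"))
  x@members
}

#' @describeIn findClusters accessor for a cluster's antenna flag.
#' @export
isAntenna <- function(x) {
  stopifnot(is(x, "NodeCluster"))
  x@isAntenna
}

#' Average-neighbour-degree comparison between a class and the rest
#'
#' Computes the mean degree of each node's first neighbours and compares the
#' class members against all other nodes with an unpaired rank-sum test
#' (\code{wilcox.test}). Sensor neighbours in genetic similarity networks
#' are expected to have markedly lower degree than the neighbours of other
#' genes.
#'
#' @param cls a [NodeClassSet-class] or character member vector.
#' @param net the network.
#' @param alternative passed to \code{wilcox.test}; e.g. \code{"less"} when
#'   testing that class neighbours have lower degree.
#' @return list with per-node \code{avgNeighborDegree}, group means, the test
#'   \code{statistic} and \code{p.value}.
#' @export
neighborDegreeStats <- function(cls, net,
                                alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  members <- if (is(cls, "NodeClassSet")) classMembers(cls) else cls
  checkNetwork(net)
  deg <- igraph::degree(net)
  isolated <- names(deg)[deg == 0]
  if (length(isolated))
    message(length(isolated), " isolated node(s) excluded")
  nodes <- setdiff(igraph::V(net)$name, isolated)
  annd <- vapply(nodes, function(v) {
    nb <- igraph::neighbors(net, v)
    mean(deg[igraph::V(net)$name[nb]])
  }, numeric(1L))
  inCls <- names(annd) %in% members
  if (!any(inCls) || all(inCls)) stop("class must be a proper nonempty subset")
  ht <- wilcox.test(annd[inCls], annd[!inCls], alternative = alternative,
                    exact = FALSE)
  list(avgNeighborDegree = annd,
       classMean = mean(annd[inCls]), restMean = mean(annd[!inCls]),
       statistic = unname(ht$statistic), p.value = ht$p.value)
}

## % of edges incident to a node set that are internal to the set;
## "total edges the nodes have" counts each incident edge once
withinEdgePercent <- function(net, members) {
  deg <- igraph::degree(net)
  inEdges <- igraph::ecount(igraph::induced_subgraph(net, members))
  tot <- sum(deg[members]) - inEdges
  if (tot == 0) return(0)
  100 * inEdges / tot
}

#' Class-internal edge enrichment against degree-matched node samples
#'
#' Measures the percentage of the class's incident edges that connect class
#' members to each other, and compares it with the same statistic for
#' \code{nSamples} random node sets matched to the class's exact degree
#' multiset (per member, a distinct uniformly random node of identical
#' degree; if none remains, the nearest degree is used and a notice logged).
#' The permutation p-value is \eqn{(r+1)/(n+1)} with \eqn{r} the number of
#' null samples at least as large as the observed percentage; the fold is
#' observed over the null mean.
#'
#' @param cls a [NodeClassSet-class] or character member vector.
#' @param net the network.
#' @param nSamples number of degree-matched null samples (default 999).
#' @param seed RNG seed.
#' @param returnSamples also return the sampled node sets (default
#'   \code{FALSE}; mainly for auditing the degree matching).
#' @return list with \code{observedPct}, \code{nullPcts}, \code{fold},
#'   \code{p.value}, \code{nSamples}, \code{seed} and, if requested,
#'   \code{samples}.
#' @export
edgeEnrichment <- function(cls, net, nSamples = 999L, seed = 1L,
                           returnSamples = FALSE) {
  members <- if (is(cls, "NodeClassSet")) classMembers(cls) else cls
  checkNetwork(net)
  stopifnot(length(members) >= 1L, nSamples >= 1L)
  deg <- igraph::degree(net)
  observed <- withinEdgePercent(net, members)
  byDeg <- split(names(deg), deg)
  degsNeeded <- table(deg[members])
  uniqDegs <- sort(unique(deg))
  fallbackUsed <- FALSE
  set.seed(as.integer(seed))
  samples <- lapply(seq_len(nSamples), function(s) {
    drawn <- character(0)
    for (d in names(degsNeeded)) {
      need <- degsNeeded[[d]]
      cand <- setdiff(byDeg[[d]], drawn)
      if (length(cand) < need) {
        ## nearest-degree fallback for the shortfall
        fallbackUsed <<- TRUE
        short <- need - length(cand)
        pool <- setdiff(names(deg), c(drawn, cand))
        dd <- abs(deg[pool] - as.numeric(d))
        extra <- pool[order(dd, pool)][seq_len(short)]
        drawn <- c(drawn, cand, extra)
      } else {
        drawn <- c(drawn, cand[sample.int(length(cand), need)])
      }
    }
    drawn
  })
  nullPcts <- vapply(samples, function(s) withinEdgePercent(net, s),
                     numeric(1L))
  if (fallbackUsed)
    message("exact degree matching incomplete; nearest-degree fallback used")
  r <- sum(nullPcts >= observed)
  meanNull <- mean(nullPcts)
  out <- list(observedPct = observed, nullPcts = nullPcts,
              fold = if (meanNull > 0) observed / meanNull else Inf,
              p.value = (r + 1) / (nSamples + 1),
              nSamples = as.integer(nSamples), seed = as.integer(seed))
  if (returnSamples) out$samples <- samples
  out
}

#' Write class/cluster assignments as a tab-delimited table
#'
#' @param cls a [NodeClassSet-class].
#' @param clusters result of [findClusters()].
#' @param path output TSV path (or NULL to only return the table).
#' @return data.frame with node, role, cluster id, antenna flag, connectors.
#' @export
writeClassTable <- function(cls, clusters, path = NULL) {
  stopifnot(is(cls, "NodeClassSet"))
  rows <- lapply(clusters$clusters, function(cl) {
    data.frame(node = cl@members, role = cls@role, cluster = cl@id,
               antenna = cl@isAntenna,
               connectors = paste(cl@connectors, collapse = ","))
  })
  uncl <- clusters$unclustered
  if (length(uncl))
    rows <- c(rows, list(data.frame(node = uncl, role = cls@role,
                                    cluster = NA_character_, antenna = NA,
                                    connectors = NA_character_)))
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
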