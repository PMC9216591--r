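#' Maximum-information shortest path between two nodes
#'
#' All unweighted shortest paths between \code{source} and \code{target} are
#' considered; each candidate is scored by the sum of the PRS responses of
#' its nodes (endpoints included) to perturbation at the source, i.e. the
#' source's row of the PRS matrix serves as node weights. The path with the
#' maximal total weight is returned; exact weight ties are broken by the
#' lexicographically smallest node sequence.
#'
#' The selection is computed by dynamic programming over the BFS shortest-
#' path DAG, which is exact without enumerating the (possibly exponential)
#' set of shortest paths.
#'
#' @param prs a [PRSResult-class] computed on \code{net}.
#' @param net connected \code{igraph}.
#' @param source,target distinct node labels.
#' @return a [PRSPath-class].
#' @export
prsPath <- function(prs, net, source, target) {
  checkNetwork(net)
  stopifnot(is(prs, "PRSResult"), isSingleString(source),
            isSingleString(target), source != target)
  nodes <- igraph::V(net)$name
  stopifnot(source %in% nodes, target %in% nodes)
  w <- prsMatrix(prs)[source, ]
  distS <- igraph::distances(net, v = source)[1L, ]
  dT <- distS[target]
  if (!is.finite(dT)) stop("target unreachable from source")
  ## restrict to nodes on some shortest source->target path
  distT <- igraph::distances(net, v = target)[1L, ]
  onPath <- names(distS)[distS + distT == dT]
  ## DP in order of distance from source: best total weight and, among
  ## equal-weight alternatives, the lexicographically smallest path
  best <- stats::setNames(rep(-Inf, length(onPath)), onPath)
  paths <- stats::setNames(vector("list", length(onPath)), onPath)
  best[source] <- w[source]
  paths[[source]] <- source
  for (d in seq_len(dT)) {
    layer <- onPath[distS[onPath] == d]
    for (v in layer) {
      nb <- igraph::V(net)$name[igraph::neighbors(net, v)]
      preds <- nb[nb %in% onPath & distS[nb] == d - 1]
      cand <- best[preds]
      top <- max(cand)
      tied <- preds[cand >= top - 1e-12 * max(1, abs(top))]
      bestPred <- tied[1L]
      if (length(tied) > 1L) {
        for (p in tied[-1L]) {
          if (compareSequences(paths[[p]], paths[[bestPred]]) < 0)
            bestPred <- p
        }
      }
      best[v] <- best[bestPred] + w[v]
      paths[[v]] <- c(paths[[bestPred]], v)
    }
  }
  sel <- paths[[target]]
  new("PRSPath", source = source, target = target, nodes = sel,
      nodeWeights = w[sel], totalWeight = sum(w[sel]))
}

#' @describeIn prsPath accessor for the ordered node sequence.
#' @param x a \code{PRSPath}.
#' @export
pathNodes <- function(x) {
  stopifnot(is(x, "PRSPath"))
  x@nodes
}

#' @describeIn prsPath accessor for the summed node weight.
#' @export
pathWeight <- function(x) {
  stopifnot(is(x, "PRSPath"))
  x@totalWeight
}

setMethod("show", "PRSPath", function(object) {
  cat("PRSPath ", object@source, " -> ", object@target, ": ",
      length(object@nodes), " nodes, total weight ",
      format(object@totalWeight, digits = 6), "\n  ",
      paste(object@nodes, collapse = " - "), "\n", sep = "")
})

#' Maximum-information path between two node clusters
#'
#' Computes [prsPath()] for every (source member, target member) pair across
#' two disjoint clusters — typically an effector cluster and a sensor
#' cluster — and returns the pair path with the highest total weight.
#' Ties are broken by shorter path, then by lexicographically smallest node
#' sequence. Because responses are nonnegative, raw totals favour longer
#' paths that sweep up extra weight; \code{normalize = "mean"} scores each
#' candidate by its per-node mean weight instead.
#'
#' @param prs a [PRSResult-class].
#' @param net connected \code{igraph}.
#' @param sourceCluster,targetCluster [NodeCluster-class] objects or
#'   character member vectors; must be disjoint.
#' @param normalize \code{"total"} (default; highest summed response) or
#'   \code{"mean"} (highest per-node mean response).
#' @return a [PRSPath-class].
#' @export
clusterPairPath <- function(prs, net, sourceCluster, targetCluster,
                            normalize = c("total", "mean")) {
  normalize <- match.arg(normalize)
  src <- if (is(sourceCluster, "NodeCluster")) clusterMembers(sourceCluster)
         else sourceCluster
  tgt <- if (is(targetCluster, "NodeCluster")) clusterMembers(targetCluster)
         else targetCluster
  if (length(intersect(src, tgt))) stop("clusters must be disjoint")
  score <- function(p) {
    if (normalize == "total") p@totalWeight
    else p@totalWeight / length(p@nodes)
  }
  bestPath <- NULL
  for (s in sort(src)) {
    for (t in sort(tgt)) {
      p <- tryCatch(prsPath(prs, net, s, t), error = function(e) NULL)
      if (is.null(p)) next
      if (is.null(bestPath)) { bestPath <- p; next }
      dw <- score(p) - score(bestPath)
      tol <- 1e-12 * max(1, abs(score(bestPath)))
      if (dw > tol) {
        bestPath <- p
      } else if (abs(dw) <= tol) {
        if (length(p@nodes) < length(bestPath@nodes) ||
            (length(p@nodes) == length(bestPath@nodes) &&
             compareSequences(p@nodes, bestPath@nodes) < 0)) {
          bestPath <- p
        }
      }
    }
  }
  if (is.null(bestPath)) stop("no connected source-target pair")
  bestPath
}

#' All cluster-pair maximum-information paths
#'
#' One [clusterPairPath()] per (source cluster, target cluster) combination
#' — e.g. 3 effector clusters x 9 sensor clusters yields 27 paths.
#'
#' @param prs a [PRSResult-class].
#' @param net connected \code{igraph}.
#' @param sourceClusters,targetClusters lists of clusters (or member
#'   vectors).
#' @return list of [PRSPath-class], in source-major order.
#' @export
allClusterPairPaths <- function(prs, net, sourceClusters, targetClusters) {
  out <- list()
  for (i in seq_along(sourceClusters)) {
    for (j in seq_along(targetClusters)) {
      out[[length(out) + 1L]] <-
        clusterPairPath(prs, net, sourceClusters[[i]], targetClusters[[j]])
    }
  }
  out
}

#' Write paths as a tab-delimited table (and optional SIF union)
#'
#' @param paths list of [PRSPath-class].
#' @param path output TSV path or NULL.
#' @param sifPath optional path for a SIF export of the union of path edges.
#' @return the table, invisibly.
#' @export
writePathTable <- function(paths, path = NULL, sifPath = NULL) {
  tab <- do.call(rbind, lapply(paths, function(p) {
    data.frame(source = p@source, target = p@target,
               length = length(p@nodes), total_weight = p@totalWeight,
               nodes = paste(p@nodes, collapse = ","))
  }))
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sifPath)) {
    edges <- unique(do.call(rbind, lapply(paths, function(p) {
      nd <- p@nodes
      if (length(nd) < 2L) return(NULL)
      cbind(nd[-length(nd)], nd[-1L])
    })))
    writeLines(paste(edges[, 1L], "pp", edges[, 2L], sep = "\t"), sifPath)
  }
  invisible(tab)
}
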