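#' Perturbation-response scanning of a Gaussian network model
#'
#' Perturbs every node in turn and records the displacement response of every
#' other node, normalising each row by the perturbed node's own
#' square fluctuation so that the self-response is 1. Two conventions are
#' supported:
#' \describe{
#'   \item{\code{"squared"} (default)}{\eqn{P_{ij} = C_{ij}^2 / C_{ii}^2},
#'     the squared-covariance response magnitude; all entries nonnegative.}
#'   \item{\code{"linear"}}{\eqn{P_{ij} = C_{ij} / C_{ii}}, the literal
#'     linear-response form; off-diagonal entries may be negative.}
#' }
#' Effectiveness of node \eqn{i} is the mean of row \eqn{i} (how strongly a
#' perturbation at \eqn{i} propagates) and sensitivity of node \eqn{j} the
#' mean of column \eqn{j} (how strongly \eqn{j} responds to perturbations
#' anywhere). With the unit diagonal included both profiles share the same
#' grand mean; including it shifts every profile by the same constant and
#' cannot change rankings.
#'
#' The spring constant \eqn{\gamma} cancels in the normalisation, so the PRS
#' matrix is independent of it.
#'
#' @param cov a [GNMCovariance-class].
#' @param convention \code{"squared"} or \code{"linear"}.
#' @param includeDiagonal include the unit diagonal in the row/column means
#'   (default \code{TRUE}).
#' @return a [PRSResult-class] object.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' prs <- computePRS(gnmCovariance(gnmModel(g)))
#' effectiveness(prs)  # (0.56, 0.50, 0.56)
#' @export
computePRS <- function(cov, convention = c("squared", "linear"),
                       includeDiagonal = TRUE) {
  convention <- match.arg(convention)
  stopifnot(is(cov, "GNMCovariance"))
  C <- covMatrix(cov)
  sigma <- squareFluctuations(cov)
  if (any(sigma <= 0)) stop("nonpositive square fluctuation")
  P <- if (convention == "squared") (C / sigma)^2 else C / sigma
  diag(P) <- 1                       # exact, up to the same normalisation
  n <- nrow(P)
  if (includeDiagonal) {
    eff <- rowMeans(P)
    sens <- colMeans(P)
  } else {
    eff <- (rowSums(P) - 1) / (n - 1)
    sens <- (colSums(P) - 1) / (n - 1)
  }
  new("PRSResult", matrix = P, convention = convention,
      effectiveness = eff, sensitivity = sens,
      includeDiagonal = includeDiagonal)
}

#' @describeIn computePRS accessor for the PRS matrix (perturbed nodes in
#'   rows, responding nodes in columns).
#' @param x a \code{PRSResult}.
#' @export
prsMatrix <- function(x) {
  stopifnot(is(x, "PRSResult"))
  x@matrix
}

#' @describeIn computePRS accessor for the effectiveness profile (row means).
#' @export
effectiveness <- function(x) {
  stopifnot(is(x, "PRSResult"))
  x@effectiveness
}

#' @describeIn computePRS accessor for the sensitivity profile (column means).
#' @export
sensitivity <- function(x) {
  stopifnot(is(x, "PRSResult"))
  x@sensitivity
}

setMethod("show", "PRSResult", function(object) {
  cat("PRSResult (", object@convention, " convention): ",
      nrow(object@matrix), " nodes\n", sep = "")
  cat("  effectiveness range: [",
      format(min(object@effectiveness), digits = 4), ",",
      format(max(object@effectiveness), digits = 4), "]\n")
  cat("  sensitivity range:   [",
      format(min(object@sensitivity), digits = 4), ",",
      format(max(object@sensitivity), digits = 4), "]\n")
})

#' Top-level clustering of the PRS matrix
#'
#' Winsorises the PRS matrix at the \code{capQuantile} quantile of all
#' \eqn{n^2} entries, takes rows (perturbed axis) or columns (responding
#' axis) as observations, computes pairwise standardised Euclidean distances
#' (each coordinate divided by its standard deviation across observations;
#' zero-variance coordinates are dropped with a notice), builds a Ward
#' dendrogram and cuts it at the top-level merge into two clusters. The
#' smaller cluster is the "distinct" perturbed or responding gene set.
#'
#' @param prs a [PRSResult-class].
#' @param axis \code{"perturbed"} (cluster rows) or \code{"responding"}
#'   (cluster columns).
#' @param capQuantile winsorisation quantile over all matrix entries
#'   (default 0.95).
#' @return a [DistinctClusters-class] object.
#' @export
clusterPRSMatrix <- function(prs, axis = c("perturbed", "responding"),
                             capQuantile = 0.95) {
  axis <- match.arg(axis)
  stopifnot(is(prs, "PRSResult"), isSingleNumber(capQuantile),
            capQuantile > 0, capQuantile <= 1)
  P <- prsMatrix(prs)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 nodes to cluster")
  cap <- stats::quantile(P, capQuantile, names = FALSE)
  P[P > cap] <- cap
  obs <- if (axis == "perturbed") P else t(P)
  sds <- apply(obs, 2L, sd)
  zero <- sds == 0
  if (all(zero)) stop("degenerate PRS matrix: all coordinates constant")
  if (any(zero)) {
    message(sum(zero), " zero-variance coordinate(s) dropped")
    obs <- obs[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  std <- sweep(obs, 2L, sds, "/")
  tree <- hclust(dist(std), method = "ward.D2")
  cut2 <- cutree(tree, k = 2L)
  sizes <- table(cut2)
  smaller <- as.integer(names(sizes)[which.min(sizes)])
  members <- rownames(P)[cut2 == smaller]
  if (length(members) == 1L)
    warning("top-level split isolates a single node")
  new("DistinctClusters", axis = axis, tree = tree, members = members,
      capQuantile = capQuantile)
}

#' @describeIn clusterPRSMatrix members of the smaller top-level sub-tree.
#' @param x a \code{DistinctClusters}.
#' @export
distinctMembers <- function(x) {
  stopifnot(is(x, "DistinctClusters"))
  x@members
}

setMethod("show", "DistinctClusters", function(object) {
  cat("DistinctClusters (", object@axis, " axis): ",
      length(object@members), " distinct members\n", sep = "")
})

#' Export node profiles as a tab-delimited table
#'
#' Writes one row per node with degree, effectiveness, sensitivity and
#' optional distinct-cluster flags — a convenient node-attribute table for
#' external viewers.
#'
#' @param prs a [PRSResult-class].
#' @param net the network the PRS was computed on.
#' @param path output TSV path.
#' @param perturbed,responding optional [DistinctClusters-class] objects to
#'   flag membership of.
#' @return the table, invisibly (also written to \code{path} if non-NULL).
#' @export
writeProfiles <- function(prs, net, path = NULL,
                          perturbed = NULL, responding = NULL) {
  checkNetwork(net)
  nodes <- names(effectiveness(prs))
  stopifnot(setequal(nodes, igraph::V(net)$name))
  deg <- igraph::degree(net)[nodes]
  tab <- data.frame(node = nodes, degree = as.integer(deg),
                    effectiveness = effectiveness(prs),
                    sensitivity = sensitivity(prs),
                    row.names = NULL, check.names = FALSE)
  if (!is.null(perturbed))
    tab$distinct_perturbed <- tab$node %in% distinctMembers(perturbed)
  if (!is.null(responding))
    tab$distinct_responding <- tab$node %in% distinctMembers(responding)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
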