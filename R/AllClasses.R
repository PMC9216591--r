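#' Gaussian network model of an undirected network
#'
#' Holds the Kirchhoff (Laplacian) matrix of a connected, simple, undirected
#' network together with its full symmetric eigendecomposition and the uniform
#' spring constant \eqn{\gamma}. The Laplacian has node degrees on the
#' diagonal and \eqn{-1} for every connected pair; it is singular with a
#' single zero mode when (and only when) the network is connected.
#'
#' @slot network the underlying \code{igraph} object (named vertices).
#' @slot laplacian numeric \eqn{n \times n} Kirchhoff matrix.
#' @slot gamma uniform spring constant (arbitrary units; rescales the
#'   covariance only, never the PRS matrix).
#' @slot values eigenvalues in ascending order.
#' @slot vectors orthonormal eigenvectors, columns matching \code{values}.
#' @slot zeroModeTol absolute tolerance below which an eigenvalue is treated
#'   as a null-space mode.
#'
#' @seealso [gnmModel()], [gnmCovariance()]
#' @export
setClass("GNMModel",
  representation(
    network = "ANY",
    laplacian = "matrix",
    gamma = "numeric",
    values = "numeric",
    vectors = "matrix",
    zeroModeTol = "numeric"
  )
)

setValidity("GNMModel", function(object) {
  L <- object@laplacian
  n <- nrow(L)
  msg <- character()
  if (n < 2L) msg <- c(msg, "model needs at least 2 nodes")
  if (ncol(L) != n) msg <- c(msg, "Laplacian must be square")
  if (max(abs(L - t(L))) > 1e-10) msg <- c(msg, "Laplacian must be symmetric")
  if (max(abs(rowSums(L))) > 1e-8) msg <- c(msg, "Laplacian rows must sum to 0")
  if (length(object@values) != n) msg <- c(msg, "need n eigenvalues")
  if (is.unsorted(object@values)) msg <- c(msg, "eigenvalues must be ascending")
  if (min(object@values) < -object@zeroModeTol)
    msg <- c(msg, "negative eigenvalue beyond tolerance")
  nzero <- sum(object@values < object@zeroModeTol)
  if (nzero != 1L)
    msg <- c(msg, sprintf(
      "expected exactly one zero mode, found %d (disconnected network?)", nzero))
  if (length(msg)) msg else TRUE
})

#' Covariance matrix of a Gaussian network model
#'
#' The equilibrium covariance \eqn{C = (1/\gamma)\,\Gamma^{+}}, the scaled
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix over its nonzero
#' modes. The diagonal \eqn{\sigma_i = C_{ii}} is the square fluctuation of
#' node \eqn{i}; every row of \eqn{C} sums to zero (orthogonality to the
#' uniform mode).
#'
#' @slot matrix numeric symmetric \eqn{n \times n} covariance matrix.
#' @slot sigma named numeric vector, the diagonal of the covariance.
#' @slot gamma the spring constant the covariance was scaled by.
#'
#' @seealso [gnmCovariance()], [computePRS()]
#' @export
setClass("GNMCovariance",
  representation(matrix = "matrix", sigma = "numeric", gamma = "numeric")
)

setValidity("GNMCovariance", function(object) {
  C <- object@matrix
  msg <- character()
  if (nrow(C) != ncol(C)) msg <- c(msg, "covariance must be square")
  if (max(abs(C - t(C))) > 1e-8) msg <- c(msg, "covariance must be symmetric")
  if (any(object@sigma <= 0)) msg <- c(msg, "square fluctuations must be > 0")
  if (max(abs(rowSums(C))) > 1e-6 * max(abs(C)))
    msg <- c(msg, "covariance rows must sum to 0")
  if (length(msg)) msg else TRUE
})

#' Perturbation-response scanning result
#'
#' The PRS matrix \eqn{P} of a network: entry \eqn{P_{ij}} is the response of
#' node \eqn{j} to a unit perturbation applied at node \eqn{i}, normalised so
#' that \eqn{P_{ii} = 1}. Under the default \code{"squared"} convention
#' \eqn{P_{ij} = C_{ij}^2 / C_{ii}^2}; under \code{"linear"}
#' \eqn{P_{ij} = C_{ij}/C_{ii}}. Effectiveness is the row average (ability to
#' transmit a perturbation), sensitivity the column average (propensity to
#' respond to perturbations anywhere in the network).
#'
#' @slot matrix the \eqn{n \times n} PRS matrix (perturbed nodes in rows).
#' @slot convention \code{"squared"} or \code{"linear"}.
#' @slot effectiveness named numeric row means.
#' @slot sensitivity named numeric column means.
#' @slot includeDiagonal logical; whether the (constant, unit) diagonal was
#'   included in the profile averages.
#'
#' @seealso [computePRS()], [selectTop()]
#' @export
setClass("PRSResult",
  representation(
    matrix = "matrix",
    convention = "character",
    effectiveness = "numeric",
    sensitivity = "numeric",
    includeDiagonal = "logical"
  )
)

setValidity("PRSResult", function(object) {
  P <- object@matrix
  msg <- character()
  if (nrow(P) != ncol(P)) msg <- c(msg, "PRS matrix must be square")
  if (max(abs(diag(P) - 1)) > 1e-8) msg <- c(msg, "PRS diagonal must be 1")
  if (object@convention == "squared" && min(P) < 0)
    msg <- c(msg, "squared-convention PRS entries must be nonnegative")
  if (!object@convention %in% c("squared", "linear"))
    msg <- c(msg, "convention must be 'squared' or 'linear'")
  if (length(object@effectiveness) != nrow(P) ||
      length(object@sensitivity) != nrow(P))
    msg <- c(msg, "profiles must have one value per node")
  if (length(msg)) msg else TRUE
})

#' Top-level split of the clustered PRS matrix
#'
#' Result of hierarchically clustering the (winsorised) PRS matrix along one
#' axis and cutting the tree at its top merge: the smaller of the two
#' top-level sub-trees is the "distinct" perturbed (row axis) or responding
#' (column axis) gene cluster.
#'
#' @slot axis \code{"perturbed"} (rows) or \code{"responding"} (columns).
#' @slot tree the \code{hclust} merge tree.
#' @slot members node labels of the smaller top-level sub-tree.
#' @slot capQuantile winsorisation quantile applied to the matrix entries.
#' @export
setClass("DistinctClusters",
  representation(axis = "character", tree = "ANY", members = "character",
                 capQuantile = "numeric")
)

#' A top-percentile node class (sensors or effectors)
#'
#' @slot role \code{"sensor"} (top sensitivity) or \code{"effector"}
#'   (top effectiveness).
#' @slot fraction selection fraction of the node count.
#' @slot members the \code{round(fraction * n)} selected node labels
#'   (rounding half away from zero).
#' @slot values the full named profile the selection was made from.
#' @seealso [selectTop()], [findClusters()]
#' @export
setClass("NodeClassSet",
  representation(role = "character", fraction = "numeric",
                 members = "character", values = "numeric")
)

setValidity("NodeClassSet", function(object) {
  msg <- character()
  if (!object@role %in% c("sensor", "effector"))
    msg <- c(msg, "role must be 'sensor' or 'effector'")
  k <- roundHalfAway(object@fraction * length(object@values))
  if (length(object@members) != k)
    msg <- c(msg, sprintf("expected %d members, found %d", k,
                          length(object@members)))
  if (!all(object@members %in% names(object@values)))
    msg <- c(msg, "members must come from the profile")
  if (length(msg)) msg else TRUE
})

#' A connected cluster of same-class nodes
#'
#' A connected component of the class-member-only induced subgraph with at
#' least \code{minSize} members. \code{connectors} are the non-member nodes
#' adjacent to any member; a cluster with exactly one connector is an
#' "antenna" motif — a sensor cluster hanging off the network through a
#' single bottleneck node.
#'
#' @slot id cluster label (clusters are numbered by descending size, ties by
#'   smallest member label).
#' @slot members node labels of the cluster.
#' @slot connectors non-member neighbours of the cluster.
#' @slot isAntenna \code{TRUE} iff exactly one connector.
#' @export
setClass("NodeCluster",
  representation(id = "character", members = "character",
                 connectors = "character", isAntenna = "logical")
)

#' Degree-preserving rewired-network null ensemble
#'
#' Per-replicate summaries of the full PRS pipeline run on connected
#' degree-preserving rewirings of a source network.
#'
#' @slot summaries data.frame, one row per replicate: mean effectiveness,
#'   mean sensitivity, degree-effectiveness Pearson r, degree-sensitivity
#'   Spearman rho, number of sensor clusters, number of antenna clusters.
#' @slot seeds per-replicate RNG seeds spawned from the master seed.
#' @slot masterSeed the master seed.
#' @slot params list of the pipeline parameters used.
#' @seealso [ensembleStats()], [rewireNetwork()]
#' @export
setClass("RewiredEnsemble",
  representation(summaries = "data.frame", seeds = "integer",
                 masterSeed = "numeric", params = "list")
)

#' Maximum-information shortest path
#'
#' Among all unweighted shortest paths between a source and a target node,
#' the one maximising the summed PRS response (row of the source) over its
#' nodes, endpoints included.
#'
#' @slot source,target endpoint node labels.
#' @slot nodes the ordered node sequence of the selected path.
#' @slot nodeWeights PRS responses of the path nodes to perturbation at the
#'   source.
#' @slot totalWeight sum of \code{nodeWeights}.
#' @seealso [prsPath()], [clusterPairPath()]
#' @export
setClass("PRSPath",
  representation(source = "character", target = "character",
                 nodes = "character", nodeWeights = "numeric",
                 totalWeight = "numeric")
)

#' Gene Ontology annotation set
#'
#' An ontology term graph (parsed from OBO) plus gene-to-term annotations
#' (parsed from GAF) restricted to a background population, with selected
#' evidence codes removed.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace} for non-obsolete terms.
#' @slot parents named list: term id -> character vector of \code{is_a}/
#'   \code{part_of} parent ids.
#' @slot geneTerms named list: gene id -> character vector of term ids.
#' @slot population character vector, the background gene set.
#' @slot excludedCodes evidence codes that were filtered out.
#' @seealso [loadAnnotations()], [enrichGO()]
#' @export
setClass("AnnotationSet",
  representation(terms = "data.frame", parents = "list", geneTerms = "list",
                 population = "character", excludedCodes = "character")
)

#' Synthetic core-periphery network with planted antenna clusters
#'
#' A dense random core plus small peripheral cliques ("antennae"), each
#' attached to the core through a single connector node. Ground-truth roles
#' are recorded so downstream sensor/antenna detection can be validated.
#'
#' @slot network the generated \code{igraph}.
#' @slot coreNodes labels of core nodes.
#' @slot antennaClusters named list of antenna member label vectors; each has
#'   attribute-free membership, connectors are in \code{connectors}.
#' @slot connectors named character: antenna id -> its core connector node.
#' @slot labels named character, ground-truth role per node
#'   (\code{"core"} or \code{"antenna"}).
#' @slot params generator parameters including the seed.
#' @seealso [makeCorePeriphery()]
#' @export
setClass("PlantedNetwork",
  representation(network = "ANY", coreNodes = "character",
                 antennaClusters = "list", connectors = "character",
                 labels = "character", params = "list")
)
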