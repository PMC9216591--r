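#' Build a Gaussian network model from a connected network
#'
#' Constructs the Kirchhoff (Laplacian) matrix \eqn{\Gamma} of a simple,
#' undirected, connected network — node degrees on the diagonal, \eqn{-1}
#' for every connected pair — and computes its full symmetric
#' eigendecomposition. The decomposition is the workhorse for the covariance
#' and PRS matrices, so it is performed once here and cached in the model.
#'
#' The dense decomposition is the contract up to \code{maxNodes} nodes;
#' larger networks are rejected rather than silently approximated.
#'
#' @param net connected \code{igraph} network with named vertices and at
#'   least two nodes.
#' @param gamma uniform spring constant (arbitrary units, default 1; it only
#'   rescales the covariance and cancels out of the PRS matrix).
#' @param maxNodes guard on the dense eigendecomposition size.
#' @return a [GNMModel-class] object.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' gnmModel(g)
#' @export
gnmModel <- function(net, gamma = 1, maxNodes = 10000L) {
  checkNetwork(net, connected = TRUE)
  n <- igraph::vcount(net)
  if (n < 2L) stop("need at least 2 nodes")
  if (n > maxNodes)
    stop("network too large for dense eigendecomposition (", n, " > ",
         maxNodes, " nodes)")
  stopifnot(isSingleNumber(gamma), gamma > 0)
  L <- as.matrix(igraph::laplacian_matrix(net, sparse = TRUE))
  dimnames(L) <- list(igraph::V(net)$name, igraph::V(net)$name)
  ee <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_len(n))            # eigen() returns descending
  values <- ee$values[ord]
  vectors <- ee$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(values)
  new("GNMModel", network = net, laplacian = L, gamma = gamma,
      values = values, vectors = vectors, zeroModeTol = tol)
}

#' Covariance matrix of a GNM
#'
#' Computes \eqn{C = (1/\gamma)\,\Gamma^{+}} from the cached
#' eigendecomposition, summing \eqn{(1/\lambda_k)\,u_k u_k^T} over the
#' nonzero modes. For a connected network exactly one eigenvalue lies in the
#' null space; anything else is an error. The diagonal
#' \eqn{\sigma_i = C_{ii}} is the square fluctuation of node \eqn{i}.
#'
#' @param model a [GNMModel-class].
#' @return a [GNMCovariance-class] object.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' covMatrix(gnmCovariance(gnmModel(g)))["a", "a"]  # 5/9
#' @export
gnmCovariance <- function(model) {
  stopifnot(is(model, "GNMModel"))
  validObject(model)
  lam <- model@values
  tol <- model@zeroModeTol
  if (min(lam) < -tol) stop("negative eigenvalue beyond tolerance")
  nonzero <- lam > tol
  if (sum(!nonzero) != 1L)
    stop("expected exactly one zero mode; network disconnected or degenerate")
  U <- model@vectors[, nonzero, drop = FALSE]
  C <- (U %*% (t(U) / lam[nonzero])) / model@gamma
  C <- (C + t(C)) / 2               # enforce exact symmetry
  dimnames(C) <- dimnames(model@laplacian)
  sigma <- diag(C)
  new("GNMCovariance", matrix = C, sigma = sigma, gamma = model@gamma)
}

#' @describeIn gnmCovariance accessor for the covariance matrix.
#' @param x a \code{GNMCovariance}.
#' @export
covMatrix <- function(x) {
  stopifnot(is(x, "GNMCovariance"))
  x@matrix
}

#' @describeIn gnmCovariance accessor for the square fluctuations
#'   \eqn{\sigma_i} (diagonal of the covariance).
#' @export
squareFluctuations <- function(x) {
  stopifnot(is(x, "GNMCovariance"))
  x@sigma
}

#' Effective resistance between two nodes
#'
#' The electrical-network distance \eqn{C_{ii} + C_{jj} - 2 C_{ij}} computed
#' from the Laplacian pseudo-inverse (with \eqn{\gamma = 1} this is the
#' classical effective resistance, proportional to random-walk commute time).
#'
#' @param cov a [GNMCovariance-class].
#' @param i,j node labels.
#' @return a single number.
#' @export
effectiveResistance <- function(cov, i, j) {
  C <- covMatrix(cov) * cov@gamma   # undo gamma: resistance is gamma-free
  C[i, i] + C[j, j] - 2 * C[i, j]
}

#' @describeIn gnmModel accessor for the Laplacian matrix.
#' @param model a \code{GNMModel}.
#' @export
laplacianMatrix <- function(model) {
  stopifnot(is(model, "GNMModel"))
  model@laplacian
}

setMethod("show", "GNMModel", function(object) {
  n <- nrow(object@laplacian)
  cat("GNMModel with", n, "nodes,",
      sum(diag(object@laplacian)) / 2, "edges\n")
  cat("  gamma:", object@gamma,
      " nonzero modes:", sum(object@values > object@zeroModeTol), "\n")
})

setMethod("show", "GNMCovariance", function(object) {
  cat("GNMCovariance:", nrow(object@matrix), "x", ncol(object@matrix),
      " gamma:", object@gamma, "\n")
  cat("  sigma range: [", format(min(object@sigma), digits = 4), ",",
      format(max(object@sigma), digits = 4), "]\n")
})
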