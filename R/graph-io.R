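#' Read a gene-by-gene profile-similarity matrix
#'
#' Reads a tab-delimited square similarity matrix in the layout used by
#' public genetic-interaction profile similarity exports: a
#' header row and a leading column both carrying gene identifiers, numeric
#' Pearson correlation entries. The matrix is validated to be square,
#' numeric, free of duplicate identifiers and symmetric within
#' \code{asymTol}; asymmetry beyond tolerance is an error rather than being
#' silently symmetrised.
#'
#' @param path path to the tab-delimited file.
#' @param asymTol absolute tolerance for symmetry (default \code{1e-8}).
#' @return numeric symmetric matrix with gene identifiers as dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, .25, .1, .25, 1, .3, .1, .3, 1), 3,
#'             dimnames = list(c("g1","g2","g3"), c("g1","g2","g3")))
#' writeSimilarityMatrix(m, tf)
#' readSimilarityMatrix(tf)[1, 2]
#' @export
readSimilarityMatrix <- function(path, asymTol = 1e-8) {
  stopifnot(isSingleString(path))
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("malformed similarity matrix: fewer than 2 columns")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in similarity matrix")
  rownames(m) <- ids
  validateSimilarityMatrix(m, asymTol = asymTol)
}

#' Validate an in-memory similarity matrix
#'
#' @param m numeric square matrix with gene ids as dimnames.
#' @param asymTol absolute symmetry tolerance.
#' @return the validated matrix (row order), invisibly unchanged.
#' @export
validateSimilarityMatrix <- function(m, asymTol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("similarity matrix must be numeric")
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m)))
    stop("similarity matrix must carry gene identifiers as dimnames")
  if (anyDuplicated(ids)) stop("duplicate gene identifiers")
  if (!identical(ids, colnames(m)))
    stop("row and column gene identifiers differ")
  if (anyNA(m)) stop("missing values in similarity matrix")
  asym <- max(abs(m - t(m)))
  if (asym > asymTol)
    stop(sprintf("similarity matrix asymmetric (max |m - t(m)| = %g)", asym))
  m
}

#' Write a similarity matrix in the tab-delimited layout read back by
#' [readSimilarityMatrix()]
#' @param m numeric symmetric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold a similarity matrix into an unweighted undirected network
#'
#' An edge joins genes \eqn{i \ne j} when their similarity exceeds
#' \code{cutoff} (strictly when \code{strict = TRUE}, the default, otherwise
#' \eqn{\ge}). The diagonal never yields edges and genes left with no passing
#' edge are dropped from the network entirely.
#'
#' @param sim validated similarity matrix (see [readSimilarityMatrix()]).
#' @param cutoff similarity cutoff in \eqn{(-1, 1]}; the yeast genetic
#'   interaction profile similarity network uses 0.2.
#' @param strict logical; \code{TRUE} keeps edges with similarity
#'   \code{> cutoff}, \code{FALSE} keeps \code{>= cutoff}.
#' @return an \code{igraph} simple undirected network with named vertices.
#' @export
thresholdNetwork <- function(sim, cutoff = 0.2, strict = TRUE) {
  sim <- validateSimilarityMatrix(sim)
  stopifnot(isSingleNumber(cutoff), cutoff > -1, cutoff <= 1)
  keep <- if (strict) sim > cutoff else sim >= cutoff
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  ids <- rownames(sim)
  if (nrow(idx) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  el <- cbind(ids[idx[, 1L]], ids[idx[, 2L]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  checkNetwork(g)
}

#' Extract the giant (largest connected) component
#'
#' Ties on component size are broken by the component containing the
#' lexicographically smallest node label, so the result is deterministic.
#'
#' @param net an \code{igraph} network with named vertices.
#' @return the induced subgraph of the largest connected component.
#' @export
giantComponent <- function(net) {
  checkNetwork(net)
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## deterministic tie-break: smallest lexicographic member label
    firsts <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1L))
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Read a two-column tab-delimited edge list
#'
#' Duplicate edges are collapsed; extra columns (e.g. weights) are ignored
#' with a notice; self-loop rows are rejected (error) or dropped with a
#' warning, per \code{selfLoops}.
#'
#' @param path path to the edge list file (no header).
#' @param selfLoops \code{"error"} (default) or \code{"warn"}.
#' @return an \code{igraph} simple undirected network.
#' @export
readEdgeList <- function(path, selfLoops = c("error", "warn")) {
  selfLoops <- match.arg(selfLoops)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs two columns")
  if (ncol(tab) > 2L)
    message("edge list has ", ncol(tab), " columns; extra columns ignored")
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  loops <- a == b
  if (any(loops)) {
    if (selfLoops == "error")
      stop(sum(loops), " self-loop row(s) in edge list")
    warning(sum(loops), " self-loop row(s) dropped")
    a <- a[!loops]; b <- b[!loops]
  }
  keep <- !duplicated(edgeKey(a, b))
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  checkNetwork(g)
}

#' Write a network as TSV edge list, GraphML or SIF
#'
#' @param net an \code{igraph} network with named vertices.
#' @param path output path.
#' @param format \code{"tsv"} (two-column edge list), \code{"graphml"} or
#'   \code{"sif"} (Cytoscape simple interaction format, relation \code{pp}).
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "graphml", "sif")) {
  format <- match.arg(format)
  checkNetwork(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (format == "tsv") {
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(el[, 1L], "pp", el[, 2L], sep = "\t"), path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}
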