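## Independent oracles and graph builders used across the suite.

## random connected Erdos-Renyi graph with named vertices
randomConnectedGraph <- function(n, p, seed) {
  set.seed(seed)
  for (try in 1:200) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
      return(g)
    }
  }
  stop("no connected graph after 200 tries")
}

## covariance oracle: SVD pseudo-inverse of the Laplacian (independent of
## the package's eigendecomposition route)
covOracle <- function(g, gamma = 1) {
  L <- as.matrix(igraph::laplacian_matrix(g, sparse = TRUE))
  dimnames(L) <- list(igraph::V(g)$name, igraph::V(g)$name)
  MASS::ginv(L) / gamma
}

## brute-force max-weight shortest path: enumerate all shortest paths with
## igraph and maximise the summed node weights directly
pathOracle <- function(g, w, source, target) {
  asp <- igraph::all_shortest_paths(g, from = source, to = target)$vpaths
  seqs <- lapply(asp, function(v) igraph::V(g)$name[v])
  ws <- vapply(seqs, function(s) sum(w[s]), numeric(1))
  best <- which(ws >= max(ws) - 1e-12 * max(1, abs(max(ws))))
  cand <- seqs[best]
  ## lexicographically smallest among ties
  key <- vapply(cand, function(s) paste(s, collapse = "\r"), character(1))
  cand[[order(key)[1]]]
}

## hypergeometric upper-tail oracle by direct summation
hyperTailOracle <- function(studyCount, popCount, popN, studyN) {
  k <- studyCount:min(studyN, popCount)
  sum(stats::dhyper(k, popCount, popN - popCount, studyN))
}

## a PRSResult with a hand-crafted matrix (diagonal forced to 1), for
## path-selection tests with planted weights
fakePRS <- function(P) {
  diag(P) <- 1
  new("PRSResult", matrix = P, convention = "squared",
      effectiveness = rowMeans(P), sensitivity = colMeans(P),
      includeDiagonal = TRUE)
}

## tiny similarity matrix with given off-diagonals (g1-g2, g1-g3, g2-g3)
simFixture <- function(s12 = 0.25, s13 = 0.10, s23 = 0.30) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- s12
  m[1, 3] <- m[3, 1] <- s13
  m[2, 3] <- m[3, 2] <- s23
  dimnames(m) <- list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  m
}
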