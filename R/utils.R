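#' @import methods
#' @importFrom stats cor dist hclust cutree sd phyper wilcox.test runif
#' @importFrom utils read.delim write.table head
NULL

## round-half-away-from-zero; base round() rounds half to even, which would
## give the wrong selection size for e.g. 57.25 -> 57 vs 32.5-type inputs
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @noRd
isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @noRd
isSingleNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## undirected edge key, order-free
edgeKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

## lexicographic comparison of two character vectors (node sequences):
## -1 if a < b, 0 if equal, 1 if a > b; shorter prefix sorts first
compareSequences <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  if (length(a) < length(b)) return(-1L)
  if (length(a) > length(b)) return(1L)
  0L
}

## deterministic child RNG seeds derived from a master seed (kept < 2^31)
spawnSeeds <- function(masterSeed, n) {
  stopifnot(isSingleNumber(masterSeed), n >= 1)
  (as.integer(masterSeed) + 1000003L * seq_len(as.integer(n))) %% 2147483647L
}

## validate an igraph input used throughout the package
checkNetwork <- function(net, connected = FALSE, arg = "net") {
  if (!igraph::is_igraph(net))
    stop(sprintf("'%s' must be an igraph object", arg), call. = FALSE)
  if (igraph::is_directed(net))
    stop(sprintf("'%s' must be undirected", arg), call. = FALSE)
  if (is.null(igraph::V(net)$name))
    stop(sprintf("'%s' must have named vertices", arg), call. = FALSE)
  if (anyDuplicated(igraph::V(net)$name))
    stop(sprintf("'%s' has duplicate vertex names", arg), call. = FALSE)
  if (igraph::any_loop(net) || igraph::any_multiple(net))
    stop(sprintf("'%s' must be a simple graph (no loops/multi-edges)", arg),
         call. = FALSE)
  if (connected && !igraph::is_connected(net))
    stop(sprintf("'%s' must be connected; extract the giant component first",
                 arg), call. = FALSE)
  invisible(net)
}
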