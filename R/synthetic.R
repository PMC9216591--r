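#' Synthetic core-periphery network with planted antenna clusters
#'
#' Generates the topology that sensor analysis is designed to detect: a
#' dense Erdos-Renyi core of \code{nCore} nodes (edge probability
#' \code{pCore}; regenerated with a new sub-seed until connected, up to
#' \code{maxRetries}), plus \code{nAntennas} peripheral cliques of
#' \code{antennaSize} nodes each, attached to the core through a single
#' connector — a core node of median degree, so that the sensitivity signal
#' of the antenna is attributable to its bottleneck topology rather than to
#' connector degree. Core nodes are labelled \code{core001, ...} and antenna
#' nodes \code{antA1...}; ground truth is recorded in the returned object.
#'
#' @param nCore core size (default 40).
#' @param pCore core edge probability (default 0.3).
#' @param nAntennas number of antenna cliques (default 3).
#' @param antennaSize nodes per antenna, at least 3 so antennae are
#'   detectable as clusters (default 4).
#' @param seed RNG seed.
#' @param maxRetries connectivity retries for the core.
#' @return a [PlantedNetwork-class].
#' @examples
#' pn <- makeCorePeriphery(seed = 7)
#' igraph::vcount(plantedGraph(pn))  # 52
#' @export
makeCorePeriphery <- function(nCore = 40L, pCore = 0.3, nAntennas = 3L,
                              antennaSize = 4L, seed = 1L,
                              maxRetries = 50L) {
  stopifnot(nCore >= 3L, pCore > 0, pCore <= 1, nAntennas >= 1L)
  if (antennaSize < 3L)
    stop("antennaSize must be >= 3 so antennae form detectable clusters")
  set.seed(as.integer(seed))
  coreNames <- sprintf("core%03d", seq_len(nCore))
  core <- NULL
  for (try in seq_len(maxRetries)) {
    g <- igraph::sample_gnp(nCore, pCore)
    if (igraph::is_connected(g)) { core <- g; break }
  }
  if (is.null(core)) stop("could not generate a connected core; raise pCore")
  igraph::V(core)$name <- coreNames
  deg <- igraph::degree(core)
  ## connectors: core nodes closest to the median degree, one per antenna
  ord <- order(abs(deg - stats::median(deg)), coreNames)
  if (nAntennas > nCore) stop("more antennas than candidate connectors")
  connectors <- coreNames[ord][seq_len(nAntennas)]
  g <- core
  antennaClusters <- list()
  for (a in seq_len(nAntennas)) {
    mem <- sprintf("ant%s%d", LETTERS[a], seq_len(antennaSize))
    g <- igraph::add_vertices(g, antennaSize, name = mem)
    ## clique among antenna members
    pairs <- t(utils::combn(mem, 2L))
    edges <- c(t(pairs))
    ## single attachment edge: first member to the connector
    edges <- c(edges, mem[1L], connectors[a])
    g <- igraph::add_edges(g, sapply(edges, function(x)
      which(igraph::V(g)$name == x)))
    antennaClusters[[paste0("antenna", LETTERS[a])]] <- mem
  }
  names(connectors) <- names(antennaClusters)
  labels <- c(stats::setNames(rep("core", nCore), coreNames),
              stats::setNames(rep("antenna",
                                  nAntennas * antennaSize),
                              unlist(antennaClusters, use.names = FALSE)))
  checkNetwork(g, connected = TRUE)
  new("PlantedNetwork", network = g, coreNodes = coreNames,
      antennaClusters = antennaClusters, connectors = connectors,
      labels = labels,
      params = list(nCore = nCore, pCore = pCore, nAntennas = nAntennas,
                    antennaSize = antennaSize, seed = seed))
}

#' @describeIn makeCorePeriphery accessor for the generated network.
#' @param x a \code{PlantedNetwork}.
#' @export
plantedGraph <- function(x) {
  stopifnot(is(x, "PlantedNetwork"))
  x@network
}

#' @describeIn makeCorePeriphery accessor for ground-truth node roles.
#' @export
plantedLabels <- function(x) {
  stopifnot(is(x, "PlantedNetwork"))
  x@labels
}

setMethod("show", "PlantedNetwork", function(object) {
  cat("PlantedNetwork:", length(object@coreNodes), "core nodes +",
      length(object@antennaClusters), "antenna cliques of",
      object@params$antennaSize, "(seed", object@params$seed, ")\n")
})

#' Catalogue of small graphs with closed-form GNM expectations
#'
#' Analytic reference values for validating the covariance and PRS code:
#' \itemize{
#'   \item \code{path3}: 3-node path; covariance entries in ninths
#'     (e.g. \eqn{C_{11} = 5/9}), effective resistance across the path is 2,
#'     squared-convention PRS row 1 is (1, 0.04, 0.64).
#'   \item \code{k5}: complete graph on 5 nodes;
#'     \eqn{\Gamma^{+} = (1/n)(I - J/n)} so \eqn{C_{ii} = 4/25},
#'     \eqn{C_{ij} = -1/25}, and every node's effectiveness and sensitivity
#'     equal \eqn{1/(n-1) = 0.25}.
#'   \item \code{star10}: star with 10 leaves; all leaves share identical
#'     profiles by symmetry.
#'   \item \code{cycle6}: 6-cycle; vertex-transitive, so both profiles are
#'     constant.
#' }
#'
#' @return named list; each entry holds \code{graph} and an
#'   \code{expected} list of analytic values.
#' @export
makeClosedFormGraphs <- function() {
  path3 <- igraph::make_graph(~ n1 - n2, n2 - n3)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  star10 <- igraph::make_star(11, mode = "undirected", center = 1)
  igraph::V(star10)$name <- c("hub", paste0("leaf", 1:10))
  cycle6 <- igraph::make_ring(6)
  igraph::V(cycle6)$name <- paste0("c", 1:6)
  list(
    path3 = list(graph = path3, expected = list(
      C = matrix(c(5, -1, -4, -1, 2, -1, -4, -1, 5) / 9, 3,
                 dimnames = list(paste0("n", 1:3), paste0("n", 1:3))),
      resistance13 = 2,
      prsRow1 = c(n1 = 1, n2 = 0.04, n3 = 0.64),
      effectiveness = c(n1 = 0.56, n2 = 0.50, n3 = 0.56),
      sensitivity = c(n1 = 0.63, n2 = 0.36, n3 = 0.63))),
    k5 = list(graph = k5, expected = list(
      Cdiag = 4 / 25, Coff = -1 / 25, profile = 0.25)),
    star10 = list(graph = star10, expected = list(
      leafSymmetry = TRUE)),
    cycle6 = list(graph = cycle6, expected = list(
      constantProfiles = TRUE))
  )
}

#' Synthetic GO annotation fixture for a planted network
#'
#' Builds OBO/GAF-style annotation structures with known ground truth:
#' every antenna cluster receives one dedicated "signal" term annotating all
#' of its members (plus a small number of random background genes), and
#' \code{nBackgroundTerms} background terms annotate random population genes
#' at uniform rates. With \code{signal = FALSE}, only background terms are
#' generated — a pure-null configuration for FDR calibration. Optionally
#' writes the fixture to OBO and GAF files so the parsers can be exercised
#' round-trip.
#'
#' @param planted a [PlantedNetwork-class].
#' @param nBackgroundTerms number of non-signal terms (default 20).
#' @param backgroundRate per-gene annotation probability for background
#'   terms (default 0.1).
#' @param signal plant enriched terms on the antenna clusters
#'   (default \code{TRUE}).
#' @param leakage number of random non-cluster genes added to each signal
#'   term (default 2).
#' @param seed RNG seed.
#' @param oboPath,gafPath optional file paths to also write the fixture to.
#' @return list with \code{annotations} (an [AnnotationSet-class]),
#'   \code{signalTerms} (named by antenna cluster) and the file paths used.
#' @export
makeAnnotations <- function(planted, nBackgroundTerms = 20L,
                            backgroundRate = 0.1, signal = TRUE,
                            leakage = 2L, seed = 1L,
                            oboPath = NULL, gafPath = NULL) {
  stopifnot(is(planted, "PlantedNetwork"))
  set.seed(as.integer(seed))
  population <- igraph::V(plantedGraph(planted))$name
  terms <- data.frame(id = character(), name = character(),
                      namespace = character(), stringsAsFactors = FALSE)
  annot <- list()   # term -> genes
  signalTerms <- character()
  if (signal) {
    for (a in names(planted@antennaClusters)) {
      tid <- sprintf("GO:%07d", 1000000L + length(signalTerms) + 1L)
      genes <- planted@antennaClusters[[a]]
      if (leakage > 0L) {
        extra <- sample(setdiff(population, genes), leakage)
        genes <- c(genes, extra)
      }
      annot[[tid]] <- genes
      terms <- rbind(terms, data.frame(
        id = tid, name = paste0("signal process ", a),
        namespace = "biological_process"))
      signalTerms[a] <- tid
    }
  }
  for (b in seq_len(nBackgroundTerms)) {
    tid <- sprintf("GO:%07d", 2000000L + b)
    genes <- population[runif(length(population)) < backgroundRate]
    if (!length(genes)) genes <- sample(population, 1L)
    annot[[tid]] <- genes
    terms <- rbind(terms, data.frame(
      id = tid, name = paste0("background process ", b),
      namespace = "biological_process"))
  }
  geneTerms <- local({
    pairs <- data.frame(gene = unlist(annot, use.names = FALSE),
                        term = rep(names(annot), lengths(annot)))
    lapply(split(pairs$term, pairs$gene), unique)
  })
  ann <- new("AnnotationSet", terms = terms,
             parents = stats::setNames(vector("list", nrow(terms)),
                                       terms$id),
             geneTerms = geneTerms, population = population,
             excludedCodes = character())
  if (!is.null(oboPath)) {
    con <- file(oboPath, "w")
    writeLines("format-version: 1.2", con)
    for (i in seq_len(nrow(terms))) {
      writeLines(c("", "[Term]", paste0("id: ", terms$id[i]),
                   paste0("name: ", terms$name[i]),
                   paste0("namespace: ", terms$namespace[i])), con)
    }
    close(con)
  }
  if (!is.null(gafPath)) {
    rows <- character()
    for (tid in names(annot)) {
      for (g in annot[[tid]]) {
        rows <- c(rows, paste(c("SYN", g, g, "", tid, "SYN:1", "IDA", "",
                                "P", "", "", "gene", "taxon:0", "20260101",
                                "SYN", "", ""), collapse = "\t"))
      }
    }
    writeLines(c("!gaf-version: 2.2", rows), gafPath)
  }
  list(annotations = ann, signalTerms = signalTerms,
       oboPath = oboPath, gafPath = gafPath)
}
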