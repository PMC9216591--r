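test_that("selection size rounds half away from zero", {
  expect_equal(selectionSize(5183, 0.01), 52L)
  expect_equal(selectionSize(3238, 0.01), 32L)
  expect_equal(selectionSize(1145, 0.05), 57L)
  expect_equal(selectionSize(50, 0.01), 1L)   # 0.5 rounds up, not to even
})

test_that("top-percentile selection is deterministic and shift-invariant", {
  set.seed(4)
  v <- stats::setNames(runif(200), sprintf("g%03d", 1:200))
  cls <- selectTop(v, 0.05, "sensor")
  expect_length(classMembers(cls), 10)
  expect_setequal(classMembers(cls), names(sort(v, decreasing = TRUE))[1:10])
  ## invariant under constant shift
  cls2 <- selectTop(v + 100, 0.05, "sensor")
  expect_equal(classMembers(cls2), classMembers(cls))
  ## ties at the boundary break by ascending label
  vt <- stats::setNames(c(3, 2, 2, 2, 1), c("e", "c", "a", "d", "b"))
  expect_equal(classMembers(selectTop(vt, 0.4, "effector")), c("e", "a"))
  expect_error(selectTop(vt, 0.05), "empty")
})

test_that("class clusters are the induced components above the size floor", {
  ## two triangles plus an isolated member
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                          x - a, x - d, x - z, z - y, y - a)
  members <- c("a", "b", "c", "d", "e", "f", "z")
  res <- findClusters(members, g, minSize = 3)
  expect_length(res$clusters, 2)
  expect_equal(res$unclustered, "z")
  got <- lapply(res$clusters, clusterMembers)
  expect_setequal(got[[1]], c("a", "b", "c"))
  expect_setequal(got[[2]], c("d", "e", "f"))
  ## clusters plus unclustered partition the member set exactly
  expect_setequal(c(unlist(got), res$unclustered), members)
})

test_that("antenna motifs are clusters with exactly one outside connector", {
  ## sensor 3-chain hanging off a hub: antenna with the hub as connector
  g <- igraph::make_graph(~ hub - s1, s1 - s2, s2 - s3,
                          hub - o1, o1 - o2, o2 - hub)
  det <- detectAntenna(c("s1", "s2", "s3"), c("s1", "s2", "s3"), g)
  expect_true(det$isAntenna)
  expect_equal(det$connectors, "hub")

  ## touching two outside nodes: not an antenna
  g2 <- igraph::add_edges(g, c("s3", "o1"))
  det2 <- detectAntenna(c("s1", "s2", "s3"), c("s1", "s2", "s3"), g2)
  expect_false(det2$isAntenna)
  expect_setequal(det2$connectors, c("hub", "o1"))

  ## no exterior left: undefined
  g3 <- igraph::make_graph(~ a - b, b - c)
  expect_error(detectAntenna(c("a", "b", "c"), c("a", "b", "c"), g3),
               "whole network")
})

test_that("planted antennae are found and flagged from the PRS profile", {
  pn <- makeCorePeriphery(seed = 7)
  g <- plantedGraph(pn)
  prs <- computePRS(gnmCovariance(gnmModel(g)))
  sensors <- selectTop(sensitivity(prs), 0.25, "sensor")
  res <- findClusters(sensors, g, minSize = 3)
  expect_gte(length(res$clusters), 3)
  antennaFlags <- vapply(res$clusters, isAntenna, logical(1))
  ## every planted antenna clique appears as a flagged cluster
  for (ant in pn@antennaClusters) {
    hit <- vapply(res$clusters, function(cl)
      all(ant %in% clusterMembers(cl)), logical(1))
    expect_true(any(hit & antennaFlags))
  }
})

test_that("neighbour-degree comparison behaves on stars and fixtures", {
  star <- igraph::make_star(9, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:8))
  nds <- neighborDegreeStats(paste0("l", 1:8), star)
  ## every leaf's single neighbour is the hub
  expect_equal(unname(nds$avgNeighborDegree[paste0("l", 1:8)]), rep(8, 8))

  pn <- makeCorePeriphery(seed = 7)
  lab <- plantedLabels(pn)
  nds2 <- neighborDegreeStats(names(lab)[lab == "antenna"], plantedGraph(pn),
                              alternative = "less")
  expect_lt(nds2$classMean, nds2$restMean)
  expect_lt(nds2$p.value, 0.01)
})

test_that("permuted class labels give calibrated neighbour-degree p-values", {
  g <- randomConnectedGraph(40, 0.15, seed = 21)
  set.seed(77)
  ps <- replicate(200, {
    cls <- sample(igraph::V(g)$name, 10)
    neighborDegreeStats(cls, g)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)  # discrete p-values tie by construction
})

test_that("a planted clique is edge-enriched against degree-matched nulls", {
  ## sparse random graph + 5-clique on nodes whose degree is common
  set.seed(12)
  g <- randomConnectedGraph(120, 0.05, seed = 12)
  clique <- c("v01", "v02", "v03", "v04", "v05")
  for (i in 1:4) for (j in (i + 1):5) {
    if (!igraph::are_adjacent(g, clique[i], clique[j]))
      g <- igraph::add_edges(g, c(clique[i], clique[j]))
  }
  res <- edgeEnrichment(clique, g, nSamples = 999, seed = 5)
  expect_gt(res$fold, 3)
  expect_equal(res$p.value, 1 / 1000)

  ## uniformly random class: fold near 1
  set.seed(9)
  rnd <- sample(igraph::V(g)$name, 12)
  res2 <- edgeEnrichment(rnd, g, nSamples = 499, seed = 6)
  sdNull <- stats::sd(res2$nullPcts)
  expect_lt(abs(res2$observedPct - mean(res2$nullPcts)), 3 * sdNull + 1e-9)
})

test_that("degree-matched samples preserve the class degree multiset", {
  g <- randomConnectedGraph(80, 0.08, seed = 31)
  deg <- igraph::degree(g)
  cls <- sample(igraph::V(g)$name, 8)
  res <- edgeEnrichment(cls, g, nSamples = 25, seed = 2,
                        returnSamples = TRUE)
  for (s in res$samples) {
    expect_equal(sort(unname(deg[s])), sort(unname(deg[cls])))
    expect_equal(anyDuplicated(s), 0)
  }
})
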