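test_that("rewiring preserves the degree sequence and connectivity", {
  for (seed in 1:5) {
    g <- randomConnectedGraph(40, 0.12, seed = seed + 100)
    rg <- rewireNetwork(g, swapMultiplier = 10, seed = seed)
    expect_setequal(igraph::V(rg)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(rg), igraph::ecount(g))
    nodes <- igraph::V(g)$name
    expect_equal(igraph::degree(rg)[nodes], igraph::degree(g)[nodes])
    expect_true(igraph::is_connected(rg))
    expect_false(igraph::any_multiple(rg) || igraph::any_loop(rg))
  }
  ## rewiring actually changes the wiring
  g <- randomConnectedGraph(40, 0.12, seed = 1)
  rg <- rewireNetwork(g, seed = 42)
  common <- length(igraph::E(igraph::intersection(g, rg)))
  expect_lt(common, igraph::ecount(g))
})

test_that("degenerate graphs with no valid swap are returned unchanged", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_warning(rg <- rewireNetwork(k3, seed = 1), "no valid")
  expect_equal(igraph::ecount(rg), 3)
})

test_that("rewiring is reproducible per seed", {
  g <- randomConnectedGraph(30, 0.15, seed = 55)
  e1 <- igraph::as_edgelist(rewireNetwork(g, seed = 7))
  e2 <- igraph::as_edgelist(rewireNetwork(g, seed = 7))
  e3 <- igraph::as_edgelist(rewireNetwork(g, seed = 8))
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
})

test_that("empirical p-values follow (r+1)/(n+1) with conservative ties", {
  nulls <- 1:100
  expect_equal(empiricalPValue(101, nulls, "greater")$p, 1 / 101)
  expect_lt(empiricalPValue(101, nulls, "greater")$p, 0.01)
  expect_equal(empiricalPValue(0, nulls, "greater")$p, 1)
  expect_equal(empiricalPValue(0, nulls, "less")$p, 1 / 101)
  ## observed at the median of the nulls
  expect_equal(empiricalPValue(50.5, nulls, "greater")$p, 51 / 101)
  ## ties count as exceedances
  expect_equal(empiricalPValue(100, nulls, "greater")$p, 2 / 101)
  ## bounds: never 0, never above 1
  expect_gte(empiricalPValue(1e9, nulls, "greater")$p, 1 / 101)
  expect_lte(empiricalPValue(-1e9, nulls, "greater")$p, 1)
})

test_that("permutation test matches the formula in extreme cases", {
  v <- stats::setNames(c(10, 11, 12, 1, 2, 3), letters[1:6])
  res <- permutationTest(v, c("a", "b", "c"), nShuffles = 500, seed = 1,
                         direction = "greater")
  ## observed split is the unique maximum: only ties can match it
  expect_lte(res$p, (1 + sum(res$nullValues >= res$observed)) / 501)
  expect_gte(res$p, 1 / 501)

  ## identical values everywhere: every shuffle ties, p = 1
  vconst <- stats::setNames(rep(2, 8), letters[1:8])
  expect_equal(permutationTest(vconst, letters[1:3], nShuffles = 100,
                               seed = 1)$p, 1)
  expect_error(permutationTest(v, letters[1:6]), "proper subset")
})

test_that("permutation p-values are uniform under random group labels", {
  set.seed(31)
  v <- stats::setNames(rnorm(40), sprintf("n%02d", 1:40))
  ps <- vapply(1:200, function(i) {
    grp <- sample(names(v), 8)
    permutationTest(v, grp, nShuffles = 199, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)  # discrete p-values tie by construction
})

test_that("rewired ensembles summarise the pipeline reproducibly", {
  pn <- makeCorePeriphery(nCore = 25, pCore = 0.35, nAntennas = 2,
                          antennaSize = 4, seed = 3)
  g <- plantedGraph(pn)
  ens <- ensembleStats(g, nReplicates = 5, seed = 11,
                       sensorFraction = 0.25)
  tab <- ensembleSummaries(ens)
  expect_equal(nrow(tab), 5)
  expect_true(all(is.finite(tab$mean_effectiveness)))
  ## bit-identical rerun under the same master seed
  tab2 <- ensembleSummaries(ensembleStats(g, nReplicates = 5, seed = 11,
                                          sensorFraction = 0.25))
  expect_identical(tab, tab2)
  ## different seed gives different replicates
  tab3 <- ensembleSummaries(ensembleStats(g, nReplicates = 5, seed = 12,
                                          sensorFraction = 0.25))
  expect_false(identical(tab$degree_effectiveness_r,
                         tab3$degree_effectiveness_r))
})

test_that("the real planted network out-senses its rewired ensemble", {
  pn <- makeCorePeriphery(seed = 7)
  g <- plantedGraph(pn)
  prs <- computePRS(gnmCovariance(gnmModel(g)))
  realMeanSens <- mean(sensitivity(prs))
  ens <- ensembleStats(g, nReplicates = 10, seed = 19,
                       sensorFraction = 0.25)
  tab <- ensembleSummaries(ens)
  res <- empiricalPValue(realMeanSens, tab$mean_sensitivity, "greater")
  expect_equal(res$p, 1 / 11)
  ## rewired replicates lose the planted sensor clusters in most runs
  expect_gt(mean(tab$n_sensor_clusters < 3), 0.5)
})
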