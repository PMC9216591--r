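## small OBO/GAF fixtures written in code
writeToyOBO <- function(path) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: process one",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: process two",
    "namespace: biological_process", "is_a: GO:0000001 ! process one",
    "",
    "[Term]", "id: GO:0000003", "name: old process",
    "namespace: biological_process", "is_obsolete: true",
    "",
    "[Term]", "id: GO:0000004", "name: component",
    "namespace: cellular_component",
    "",
    "[Typedef]", "id: part_of", "name: part of"
  ), path)
  path
}

writeToyGAF <- function(path, rows) {
  gafRow <- function(gene, term, evidence, qualifier = "") {
    paste(c("DB", gene, gene, qualifier, term, "REF", evidence, "", "P",
            "", "", "gene", "taxon:1", "20260101", "DB", "", ""),
          collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               mapply(gafRow, rows$gene, rows$term, rows$evidence,
                      rows$qualifier)), path)
  path
}

test_that("OBO parsing keeps live terms with names and parents", {
  obo <- readOBO(writeToyOBO(withr::local_tempfile(fileext = ".obo")))
  expect_setequal(obo$terms$id, c("GO:0000001", "GO:0000002", "GO:0000004"))
  expect_equal(obo$terms$name[obo$terms$id == "GO:0000001"], "process one")
  expect_equal(obo$parents[["GO:0000002"]], "GO:0000001")
  expect_false("GO:0000003" %in% obo$terms$id)  # obsolete dropped
})

test_that("GAF parsing and evidence filtering follow the contract", {
  gaf <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g9"),
    term = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000001",
             "GO:0000001"),
    evidence = c("IDA", "IGI", "IMP", "IDA", "IDA"),
    qualifier = c("", "", "", "NOT", ""))
  path <- writeToyGAF(withr::local_tempfile(fileext = ".gaf"), gaf)
  raw <- readGAF(path)
  expect_equal(nrow(raw), 4)        # NOT-qualified row dropped at parse
  obo <- writeToyOBO(withr::local_tempfile(fileext = ".obo"))
  ## population excludes g9, evidence filter removes the IGI row
  ann <- loadAnnotations(obo, path, population = c("g1", "g2", "g3", "g5"))
  expect_setequal(names(ann@geneTerms), c("g1", "g3"))
  expect_equal(ann@geneTerms[["g3"]], "GO:0000002")
  ## filtering more codes never adds annotations
  ann2 <- loadAnnotations(obo, path, population = c("g1", "g2", "g3", "g5"),
                          excludedCodes = c("ND", "IGI", "HGI", "IMP"))
  expect_true(all(lengths(ann2@geneTerms) <=
                    lengths(ann@geneTerms[names(ann2@geneTerms)])))
})

test_that("annotation propagation climbs is_a edges when requested", {
  gaf <- data.frame(gene = "g1", term = "GO:0000002", evidence = "IDA",
                    qualifier = "")
  path <- writeToyGAF(withr::local_tempfile(fileext = ".gaf"), gaf)
  obo <- writeToyOBO(withr::local_tempfile(fileext = ".obo"))
  ann <- loadAnnotations(obo, path, population = "g1", propagate = TRUE)
  expect_setequal(ann@geneTerms[["g1"]], c("GO:0000002", "GO:0000001"))
})

test_that("enrichment p-values equal the hypergeometric tail oracle", {
  pn <- makeCorePeriphery(seed = 13)
  fx <- makeAnnotations(pn, seed = 13)
  ann <- fx$annotations
  study <- pn@antennaClusters[[1]]
  res <- enrichGO(study, ann, nResamples = 50, seed = 1)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_fisher[i],
                 hyperTailOracle(res$study_count[i], res$pop_count[i],
                                 res$pop_n[i], res$study_n[i]),
                 tolerance = 1e-10)
    ## cross-check against the exact-test route
    ct <- matrix(c(res$study_count[i],
                   res$study_n[i] - res$study_count[i],
                   res$pop_count[i] - res$study_count[i],
                   res$pop_n[i] - res$study_n[i] - res$pop_count[i] +
                     res$study_count[i]), 2)
    expect_equal(res$p_fisher[i],
                 stats::fisher.test(ct, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("planted signal terms reach significance, whole-population terms never", {
  pn <- makeCorePeriphery(seed = 13)
  fx <- makeAnnotations(pn, seed = 13)
  res <- enrichGO(pn@antennaClusters[[1]], fx$annotations,
                  nResamples = 499, seed = 2)
  sig <- fx$signalTerms[[1]]
  expect_true(sig %in% res$term)
  expect_lt(res$fdr[res$term == sig], 0.1)
  expect_true(res$significant[res$term == sig])
  ## FDR bounds
  expect_true(all(res$fdr >= 1 / 500 & res$fdr <= 1))

  ## a term annotating the whole population is never enriched
  ann <- fx$annotations
  pop <- ann@population
  ann@geneTerms <- lapply(ann@geneTerms, function(t) c(t, "GO:9999999"))
  extra <- setdiff(pop, names(ann@geneTerms))
  ann@geneTerms[extra] <- list("GO:9999999")
  ann@terms <- rbind(ann@terms, data.frame(
    id = "GO:9999999", name = "everything", namespace = "biological_process"))
  res2 <- enrichGO(pn@antennaClusters[[1]], ann, nResamples = 99, seed = 3)
  expect_equal(res2$p_fisher[res2$term == "GO:9999999"], 1)
  expect_false(res2$significant[res2$term == "GO:9999999"])
})

test_that("resampling FDR is calibrated on random study sets", {
  pn <- makeCorePeriphery(seed = 29)
  fx <- makeAnnotations(pn, nBackgroundTerms = 15, signal = FALSE, seed = 29)
  pop <- fx$annotations@population
  hits <- total <- 0
  set.seed(8)
  for (rep in 1:25) {
    study <- sample(pop, 6)
    res <- enrichGO(study, fx$annotations, nResamples = 199, seed = rep)
    hits <- hits + sum(res$significant)
    total <- total + nrow(res)
  }
  ## null study sets should rarely clear FDR < 0.1
  expect_lt(hits / total, 0.15)
})

test_that("synthetic annotation fixtures round-trip through OBO/GAF files", {
  pn <- makeCorePeriphery(seed = 3)
  obo <- withr::local_tempfile(fileext = ".obo")
  gaf <- withr::local_tempfile(fileext = ".gaf")
  fx <- makeAnnotations(pn, seed = 3, oboPath = obo, gafPath = gaf)
  ann <- loadAnnotations(obo, gaf,
                         population = igraph::V(plantedGraph(pn))$name)
  direct <- fx$annotations
  expect_setequal(names(ann@geneTerms), names(direct@geneTerms))
  for (g in names(direct@geneTerms))
    expect_setequal(ann@geneTerms[[g]], direct@geneTerms[[g]])
})
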