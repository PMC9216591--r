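#' Parse a Gene Ontology OBO file (minimal 1.2/1.4 reader)
#'
#' Extracts term id, name, namespace, obsolescence and the
#' \code{is_a}/\code{part_of} parent edges from \code{[Term]} stanzas.
#'
#' @param path path to an OBO file.
#' @return list with \code{terms} (data.frame id/name/namespace, obsolete
#'   terms removed) and \code{parents} (named list of parent term ids).
#' @export
readOBO <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found; not an OBO file?")
  bounds <- c(starts, length(lines) + 1L)
  ids <- names <- namespaces <- character(length(starts))
  obsolete <- logical(length(starts))
  parents <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]  # stop at next stanza header text
    getField <- function(tag) sub(paste0("^", tag, ": *"), "",
                                  grep(paste0("^", tag, ": "), block,
                                       value = TRUE))
    id <- getField("id")
    ids[k] <- if (length(id)) id[1L] else NA_character_
    nm <- getField("name")
    names[k] <- if (length(nm)) nm[1L] else NA_character_
    ns <- getField("namespace")
    namespaces[k] <- if (length(ns)) ns[1L] else NA_character_
    obsolete[k] <- any(grepl("^is_obsolete: true", block))
    isa <- sub(" !.*$", "", getField("is_a"))
    rel <- getField("relationship")
    partof <- sub(" !.*$", "", sub("^part_of +", "",
                                   rel[grepl("^part_of ", rel)]))
    parents[[k]] <- unique(c(isa, partof))
  }
  keep <- !obsolete & !is.na(ids)
  terms <- data.frame(id = ids[keep], name = names[keep],
                      namespace = namespaces[keep],
                      stringsAsFactors = FALSE)
  parents <- stats::setNames(parents[keep], ids[keep])
  list(terms = terms, parents = parents)
}

#' Parse a GAF 2.x annotation file (minimal reader)
#'
#' Reads the tab-delimited Gene Association File format, skipping \code{!}
#' comment lines and rows whose qualifier contains \code{NOT}.
#'
#' @param path path to a GAF file.
#' @param idColumn which gene identifier to use: \code{"symbol"} (column 3,
#'   default) or \code{"id"} (column 2).
#' @return data.frame with columns \code{gene}, \code{term},
#'   \code{evidence}, \code{aspect}.
#' @export
readGAF <- function(path, idColumn = c("symbol", "id")) {
  idColumn <- match.arg(idColumn)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "!",
                    stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 7L) stop("not a GAF file: fewer than 7 columns")
  gene <- as.character(if (idColumn == "symbol") tab[[3L]] else tab[[2L]])
  qualifier <- as.character(tab[[4L]])
  keep <- !grepl("NOT", qualifier, fixed = TRUE)
  data.frame(gene = gene[keep], term = as.character(tab[[5L]][keep]),
             evidence = as.character(tab[[7L]][keep]),
             aspect = if (ncol(tab) >= 9L) as.character(tab[[9L]][keep])
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Load GO annotations for a gene population
#'
#' Combines an OBO ontology with GAF annotations: annotations carrying
#' excluded evidence codes (by default ND, IGI and HGI — codes that would
#' leak genetic-interaction-derived information back into genetic-network
#' enrichment) are removed, annotations for genes outside the population or
#' for obsolete/unknown terms are dropped, and optionally the annotations
#' are propagated to ancestor terms along \code{is_a}/\code{part_of}.
#'
#' @param oboPath path to the ontology OBO file.
#' @param gafPath path to the GAF annotation file.
#' @param population character vector of background genes (all network
#'   nodes).
#' @param excludedCodes evidence codes to remove
#'   (default \code{c("ND", "IGI", "HGI")}).
#' @param namespace restrict to one namespace, e.g.
#'   \code{"biological_process"} (default); \code{NULL} keeps all.
#' @param propagate climb \code{is_a}/\code{part_of} edges so a gene
#'   annotated to a term is also annotated to its ancestors (default
#'   \code{FALSE}).
#' @param idColumn GAF gene identifier column (see [readGAF()]).
#' @return an [AnnotationSet-class].
#' @export
loadAnnotations <- function(oboPath, gafPath, population,
                            excludedCodes = c("ND", "IGI", "HGI"),
                            namespace = "biological_process",
                            propagate = FALSE,
                            idColumn = c("symbol", "id")) {
  obo <- readOBO(oboPath)
  gaf <- readGAF(gafPath, idColumn = idColumn)
  stopifnot(is.character(population), length(population) >= 1L)
  terms <- obo$terms
  if (!is.null(namespace))
    terms <- terms[terms$namespace %in% namespace, , drop = FALSE]
  gaf <- gaf[!gaf$evidence %in% excludedCodes, , drop = FALSE]
  gaf <- gaf[gaf$gene %in% population & gaf$term %in% terms$id, ,
             drop = FALSE]
  if (nrow(gaf) == 0L)
    stop("no annotations left after filtering; empty population overlap?")
  geneTerms <- lapply(split(gaf$term, gaf$gene), unique)
  if (propagate) {
    geneTerms <- lapply(geneTerms, function(ts) {
      seen <- character(0)
      queue <- ts
      while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        if (t %in% seen) next
        seen <- c(seen, t)
        queue <- c(queue, obo$parents[[t]])
      }
      intersect(seen, terms$id)
    })
  }
  new("AnnotationSet", terms = terms, parents = obo$parents,
      geneTerms = geneTerms, population = unique(population),
      excludedCodes = excludedCodes)
}

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@geneTerms), "annotated genes of",
      length(object@population), "population genes;",
      nrow(object@terms), "terms\n")
})

## term -> annotated population genes, as a named list
termGenes <- function(ann) {
  pairs <- data.frame(
    gene = rep(names(ann@geneTerms), lengths(ann@geneTerms)),
    term = unlist(ann@geneTerms, use.names = FALSE))
  lapply(split(pairs$gene, pairs$term), unique)
}

#' GO over-representation with resampling-based FDR
#'
#' For every term annotating at least one study gene, a one-sided exact test
#' of over-representation is computed from the 2x2 table of study/population
#' annotation counts (hypergeometric tail). Multiple testing is corrected by
#' a resampling-based false discovery estimate: \code{nResamples} random
#' gene sets of the study's size are drawn from the population, the same
#' per-term p-values computed, and each term's FDR is
#' \eqn{(r+1)/(n+1)} with \eqn{r} the number of resamples whose p-value for
#' that term is at most the observed one. The same resampled sets are reused
#' across terms. Terms with FDR below \code{fdrThreshold} (default 0.1) are
#' flagged significant.
#'
#' @param study character vector of study genes (subset of the population).
#' @param ann an [AnnotationSet-class].
#' @param nResamples number of random same-size gene sets (default 500).
#' @param seed RNG seed.
#' @param fdrThreshold significance threshold on the FDR (default 0.1).
#' @return data.frame: term, name, study_count, study_n, pop_count, pop_n,
#'   p_fisher, fdr, significant; ordered by p then term id.
#' @export
enrichGO <- function(study, ann, nResamples = 500L, seed = 1L,
                     fdrThreshold = 0.1) {
  stopifnot(is(ann, "AnnotationSet"), is.character(study),
            length(study) >= 1L)
  pop <- ann@population
  if (!all(study %in% pop)) stop("study genes must be in the population")
  study <- unique(study)
  tg <- termGenes(ann)
  popN <- length(pop)
  studyN <- length(study)
  popCount <- lengths(tg)
  studyCount <- vapply(tg, function(g) sum(study %in% g), integer(1L))
  keep <- studyCount > 0L
  if (!any(keep))
    return(data.frame(term = character(), name = character(),
                      study_count = integer(), study_n = integer(),
                      pop_count = integer(), pop_n = integer(),
                      p_fisher = numeric(), fdr = numeric(),
                      significant = logical()))
  tg <- tg[keep]; popCount <- popCount[keep]; studyCount <- studyCount[keep]
  pObs <- phyper(studyCount - 1L, popCount, popN - popCount, studyN,
                 lower.tail = FALSE)
  ## resampling null: same-size random study sets, same per-term test
  set.seed(as.integer(seed))
  exceed <- integer(length(tg))
  for (s in seq_len(nResamples)) {
    rnd <- pop[sample.int(popN, studyN)]
    rc <- vapply(tg, function(g) sum(rnd %in% g), integer(1L))
    pr <- phyper(rc - 1L, popCount, popN - popCount, studyN,
                 lower.tail = FALSE)
    exceed <- exceed + (pr <= pObs)
  }
  fdr <- (exceed + 1) / (nResamples + 1)
  nameOf <- stats::setNames(ann@terms$name, ann@terms$id)
  out <- data.frame(term = names(tg), name = unname(nameOf[names(tg)]),
                    study_count = unname(studyCount), study_n = studyN,
                    pop_count = unname(popCount), pop_n = popN,
                    p_fisher = unname(pObs), fdr = unname(fdr),
                    significant = unname(fdr < fdrThreshold),
                    stringsAsFactors = FALSE)
  out[order(out$p_fisher, out$term), , drop = FALSE]
}
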