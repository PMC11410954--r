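# fixtures are built in code; nothing is read from disk
suppressPackageStartupMessages(library(SummarizedExperiment))

# a path network GA - GB - GC - GD (plus optional extras)
linePPI <- function(genes = c("GA", "GB", "GC", "GD")) {
  newPPINetwork(cbind(genes[-length(genes)], genes[-1]))
}

# tiny linearly separable cohort on the line network: class 1 is shifted on
# GB and GC, so a sum-aggregating classifier can separate the classes
smallCohort <- function(nPerClass = 10L, shift = 3, seed = 1L,
                        genes = c("GA", "GB", "GC", "GD")) {
  set.seed(seed)
  m <- 2L * nPerClass
  labels <- rep(c(0L, 1L), each = nPerClass)
  vals <- matrix(rnorm(length(genes) * m), length(genes), m,
                 dimnames = list(genes, sprintf("P%03d", seq_len(m))))
  vals[c("GB", "GC"), labels == 1L] <- vals[c("GB", "GC"), labels == 1L] + shift
  makeExpressionSE(vals, labels)
}

smallGraphs <- function(nPerClass = 10L, shift = 3, seed = 1L) {
  buildPatientGraphs(smallCohort(nPerClass, shift, seed), linePPI())
}

# fast training configuration for protocol-level tests
fastConfig <- function(seed = 1L) {
  gnnConfig(hiddenDim = 8L, epochs = 8L, batchSize = 8L, seed = seed)
}

# independent weighted-vote oracle: explicit score accumulation
bruteVote <- function(votes, weights) {
  s0 <- 0
  s1 <- 0
  for (i in seq_along(weights)) {
    if (votes[i] == 1) s1 <- s1 + weights[i] else s0 <- s0 + weights[i]
  }
  if (s1 > s0) 1L else 0L
}

# greedy lexicographic growth from a start gene (test-side subgraph builder)
growFrom <- function(ppi, start, size) {
  e <- edgeMatrix(ppi)
  genes <- start
  while (length(genes) < size) {
    nb <- sort(setdiff(c(e[e[, 1] %in% genes, 2], e[e[, 2] %in% genes, 1]),
                       genes))
    if (length(nb) == 0) break
    genes <- c(genes, nb[1])
  }
  sub <- inducedNetwork(ppi, genes)
  new("SubgraphSpec", genes = nodeNames(sub), edges = edgeMatrix(sub))
}

# ---- cached study runs (shared by invariant and acceptance tests) -------

.studyCache <- new.env(parent = emptyenv())

# one full-pipeline run at the reference study conditions; the global
# federated ensemble of a single site is the concatenation of its members
recoveryRun <- function(seed) {
  key <- paste0("rec", seed)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  spec <- syntheticSpec(seed = seed)
  ds <- generateDataset(spec)
  graphs <- buildPatientGraphs(ds$expr, ds$ppi)
  pipe <- trainLocalEnsemble(graphs, gnnConfig(seed = seed), seed = seed)
  payload <- detachData(pipe$ensemble)
  global <- aggregateModels(list(site = payload))
  testReport <- evaluateEnsemble(global, graphs[, pipe$split$test],
                                 splitName = "test")
  sig <- nodeNames(ds$signal)
  nodeImp <- pipe$scores@nodeImportance
  pval <- stats::wilcox.test(nodeImp[sig],
                             nodeImp[setdiff(names(nodeImp), sig)],
                             alternative = "greater", exact = FALSE)$p.value
  overlap <- max(vapply(pipe$subgraphs, function(sg)
    mean(sig %in% nodeNames(sg)), numeric(1)))
  out <- list(balacc = unname(perfMetrics(testReport)["balanced_accuracy"]),
              pval = pval, signalOverlap = overlap)
  .studyCache[[key]] <- out
  out
}

# two clients, each holding half the cohort: federated global model vs the
# clients' own local ensembles
fedVsLocalRun <- function(seed) {
  key <- paste0("fed", seed)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  spec <- syntheticSpec(seed = seed)
  ds <- generateDataset(spec)
  graphs <- buildPatientGraphs(ds$expr, ds$ppi)
  lab <- graphLabels(graphs)
  i0 <- which(lab == 0L)
  i1 <- which(lab == 1L)
  halves <- list(
    a = graphs[, sort(c(i0[seq_len(50)], i1[seq_len(50)]))],
    b = graphs[, sort(c(i0[50 + seq_len(50)], i1[50 + seq_len(50)]))])
  res <- runFederation(halves, gnnConfig(seed = seed), seed = seed)
  bal <- function(r) unname(perfMetrics(r)["balanced_accuracy"])
  out <- list(
    globalTest = vapply(res@perClientReports, function(r)
      bal(r$global_test), numeric(1)),
    localTest = vapply(res@perClientReports, function(r)
      bal(r$local_test), numeric(1)),
    memberCounts = table(memberProvenance(res@globalModel)),
    result = res)
  .studyCache[[key]] <- out
  out
}
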