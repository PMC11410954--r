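#' @include AllClasses.R graphio.R
NULL

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Describes a scale-free PPI network and a balanced two-class expression
#' cohort with a class-conditional mean shift planted on a connected
#' subnetwork — the ground-truth recovery target for the whole pipeline.
#'
#' @slot nGenes number of genes (network nodes).
#' @slot attachmentEdges edges added per node during preferential-attachment
#'   growth.
#' @slot nPatientsPerClass patients per outcome class.
#' @slot signalSize genes carrying the planted signal.
#' @slot effectSize class-1 mean shift on signal genes, in units of the
#'   noise standard deviation.
#' @slot noiseSd standard deviation of the background expression noise.
#' @slot seed integer seed; generation is fully deterministic under it.
#'
#' @seealso [syntheticSpec()], [generatePPI()], [plantSignal()],
#'   [generateCohort()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nGenes = "integer", attachmentEdges = "integer",
                 nPatientsPerClass = "integer", signalSize = "integer",
                 effectSize = "numeric", noiseSd = "numeric",
                 seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (object@nGenes < 3L) msgs <- c(msgs, "nGenes must be >= 3")
  if (object@attachmentEdges < 1L) msgs <- c(msgs, "attachmentEdges must be >= 1")
  if (object@nPatientsPerClass < 2L)
    msgs <- c(msgs, "nPatientsPerClass must be >= 2")
  if (object@signalSize > object@nGenes)
    msgs <- c(msgs, "signalSize cannot exceed nGenes")
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d genes (PA m=%d), %d patients/class, signal %d genes at %+g sd, noise sd %g, seed %d\n",
    object@nGenes, object@attachmentEdges, object@nPatientsPerClass,
    object@signalSize, object@effectSize, object@noiseSd, object@seed))
})

#' Create a synthetic benchmark specification
#'
#' Defaults define the package's reference study conditions: a 100-gene
#' scale-free PPI (two attachment edges per node), 100 patients per class,
#' and a five-gene connected signal subnetwork whose class-1 expression is
#' shifted by two noise standard deviations.
#'
#' @param nGenes,attachmentEdges,nPatientsPerClass,signalSize,effectSize,noiseSd,seed
#'   see [SyntheticSpec-class].
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 100L, attachmentEdges = 2L,
                          nPatientsPerClass = 100L, signalSize = 5L,
                          effectSize = 2, noiseSd = 1, seed = 1L) {
  new("SyntheticSpec", nGenes = as.integer(nGenes),
      attachmentEdges = as.integer(attachmentEdges),
      nPatientsPerClass = as.integer(nPatientsPerClass),
      signalSize = as.integer(signalSize),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

geneSymbols <- function(n) {
  paste0("G", formatC(seq_len(n), width = max(4L, nchar(n)), flag = "0"))
}

#' Generate a scale-free PPI network
#'
#' Barabasi-Albert preferential attachment over `nGenes` gene symbols
#' (`G0001`, `G0002`, ...); the result is connected and deterministic under
#' the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [PPINetwork-class].
#' @export
generatePPI <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  g <- withSeed(spec@seed,
                igraph::sample_pa(spec@nGenes, power = 1,
                                  m = spec@attachmentEdges,
                                  directed = FALSE))
  symbols <- geneSymbols(spec@nGenes)
  e <- igraph::as_edgelist(g, names = FALSE)
  newPPINetwork(cbind(symbols[e[, 1]], symbols[e[, 2]]), nodes = symbols)
}

#' Plant a connected signal subnetwork
#'
#' Chooses a seeded random start gene and grows the signal set breadth-first
#' to `signalSize` genes, so the ground truth is a connected subnetwork tests
#' can compare recovered subgraphs against.
#'
#' @param ppi the [PPINetwork-class] to plant into.
#' @param spec a [SyntheticSpec-class] (`signalSize >= 2`).
#' @return a [SubgraphSpec-class] of the signal genes.
#' @export
plantSignal <- function(ppi, spec) {
  stopifnot(is(ppi, "PPINetwork"), is(spec, "SyntheticSpec"))
  if (spec@signalSize < 2L) stop("signalSize must be >= 2")
  if (spec@signalSize > numNodes(ppi))
    stop("signalSize exceeds the network's gene count")
  g <- igraph::graph_from_data_frame(
    as.data.frame(ppi@edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = ppi@nodes)
  start <- withSeed(spec@seed, sample(ppi@nodes, 1L))
  ord <- as.integer(igraph::bfs(g, root = start, order = TRUE)$order)
  genes <- igraph::V(g)$name[ord][seq_len(spec@signalSize)]
  sub <- inducedNetwork(ppi, genes)
  new("SubgraphSpec", genes = sub@nodes, edges = sub@edges)
}

#' Generate a balanced two-class expression cohort
#'
#' Background expression is i.i.d. `Normal(0, noiseSd^2)` for every gene and
#' patient; for class-1 patients the signal genes are shifted by
#' `effectSize * noiseSd`. Labels are balanced (`nPatientsPerClass` each of
#' class 0 and 1) and sample ids are `P0001`, `P0002`, ...
#'
#' @param ppi the [PPINetwork-class] supplying the gene set.
#' @param signal the planted [SubgraphSpec-class] (from [plantSignal()]).
#' @param spec a [SyntheticSpec-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] as from
#'   [readExpression()].
#' @export
generateCohort <- function(ppi, signal, spec) {
  stopifnot(is(ppi, "PPINetwork"), is(signal, "SubgraphSpec"),
            is(spec, "SyntheticSpec"))
  validObject(spec)
  genes <- ppi@nodes
  m <- 2L * spec@nPatientsPerClass
  labels <- rep(c(0L, 1L), each = spec@nPatientsPerClass)
  vals <- withSeed(spec@seed,
                   matrix(stats::rnorm(length(genes) * m, 0, spec@noiseSd),
                          length(genes), m))
  shiftRows <- match(signal@genes, genes)
  vals[shiftRows, labels == 1L] <-
    vals[shiftRows, labels == 1L] + spec@effectSize * spec@noiseSd
  ids <- paste0("P", formatC(seq_len(m), width = max(4L, nchar(m)),
                             flag = "0"))
  makeExpressionSE(vals, labels, sampleIds = ids, genes = genes)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: network, planted signal and cohort from one spec.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a list with elements `ppi`, `signal`, `expr`.
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  ppi <- generatePPI(spec)
  signal <- plantSignal(ppi, spec)
  list(ppi = ppi, signal = signal,
       expr = generateCohort(ppi, signal, spec))
}

#' Write the standard input files for a synthetic dataset
#'
#' Emits the same formats the readers expect — a two-column PPI edge list, a
#' samples x genes expression TSV with a `label` column — plus a
#' ground-truth file listing the planted signal genes.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths (`ppi`,
#'   `expression`, `signal`).
#' @export
writeSyntheticInputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generateDataset(spec)
  ppiPath <- file.path(dir, "ppi_edges.tsv")
  exprPath <- file.path(dir, "expression.tsv")
  signalPath <- file.path(dir, "signal_genes.txt")
  writePPI(ds$ppi, ppiPath)
  mat <- SummarizedExperiment::assay(ds$expr, "expr")
  tab <- data.frame(sample_id = colnames(mat), t(mat),
                    label = SummarizedExperiment::colData(ds$expr)$label,
                    check.names = FALSE)
  utils::write.table(tab, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(ds$signal@genes, signalPath)
  c(ppi = ppiPath, expression = exprPath, signal = signalPath)
}
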