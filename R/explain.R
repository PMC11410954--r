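#' @include AllClasses.R gnn.R
NULL

#' ImportanceScores: node and edge attribution for a trained model
#'
#' Edge importance is the averaged absolute gradient-based sensitivity of the
#' predicted-class logit to the edge's message contribution; node importance
#' is the maximum over incident edges. Both are rescaled to `[0, 1]` by the
#' maximum (left at 0 when every score is 0, e.g. for an all-zero model).
#'
#' @slot nodeImportance named numeric, one score per gene of the model's
#'   topology.
#' @slot edgeImportance named numeric, one score per undirected edge; names
#'   are `"<geneA>|<geneB>"` with endpoints in lexicographic order.
#'
#' @seealso [computeImportance()], [extractSubgraphs()],
#'   [writeImportanceTables()]
#' @exportClass ImportanceScores
setClass("ImportanceScores",
  representation(nodeImportance = "numeric", edgeImportance = "numeric")
)

setValidity("ImportanceScores", function(object) {
  msgs <- character(0)
  if (is.null(names(object@nodeImportance)))
    msgs <- c(msgs, "nodeImportance must be named")
  if (length(object@edgeImportance) && is.null(names(object@edgeImportance)))
    msgs <- c(msgs, "edgeImportance must be named")
  rng <- range(c(object@nodeImportance, object@edgeImportance, 0, 0))
  if (rng[1] < 0 || rng[2] > 1 + 1e-12)
    msgs <- c(msgs, "scores must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ImportanceScores", function(object) {
  top <- sort(object@nodeImportance, decreasing = TRUE)
  cat("ImportanceScores:", length(object@nodeImportance), "genes,",
      length(object@edgeImportance), "edges; top genes:",
      paste(utils::head(names(top), 5), collapse = ", "), "\n")
})

edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# gradient of the class-c logit of one graph wrt every entry of the
# adjacency-plus-self matrix S (the edge "message contributions")
logitAdjacencyGrad <- function(S, fw, params, classIdx) {
  n <- fw$n
  L <- fw$L
  h <- length(params$bout)
  dpool <- params$Wout[, classIdx]                       # h_L
  dH <- matrix(rep(dpool / n, each = n), n)              # n x h_L
  dS <- matrix(0, n, n)
  for (l in rev(seq_len(L))) {
    dP <- dH * fw$masks[[l]]
    G <- fw$Hs[[l]] %*% params[[paste0("W", l)]]         # n x h_l (m = 1)
    dS <- dS + dP %*% t(G)
    if (l > 1L)
      dH <- crossprod(S, dP) %*% t(params[[paste0("W", l)]])
  }
  dS
}

#' Score node and edge importance of a trained graph classifier
#'
#' For every graph the gradient of the predicted-class logit with respect to
#' each edge's message contribution (the corresponding adjacency entries, in
#' both directions) is computed by backpropagation; edge importance is the
#' mean absolute sensitivity across correctly-classified graphs, node
#' importance the maximum over incident edges, and both are rescaled to
#' `[0, 1]` by the maximum. When no graph is classified correctly the
#' average falls back to all graphs, with a warning.
#'
#' @param model a [TrainedGNN-class].
#' @param graphs a [PatientGraphSet-class] over the model's node set.
#' @return an [ImportanceScores-class] whose keys are exactly the topology's
#'   nodes and edges.
#' @export
computeImportance <- function(model, graphs) {
  stopifnot(is(model, "TrainedGNN"), is(graphs, "PatientGraphSet"))
  if (ncol(graphs) < 1L) stop("need at least one graph")
  pred <- predictGraphs(model, graphs)
  y <- unname(graphLabels(graphs))
  use <- which(pred$label == y)
  if (length(use) == 0L) {
    warning("no correctly-classified graph; averaging sensitivity over all graphs")
    use <- seq_len(ncol(graphs))
  }
  nodes <- model@nodeOrder
  edges <- edgeMatrix(graphs)
  X <- SummarizedExperiment::assay(graphs, "expr")[nodes, , drop = FALSE]
  S <- adjacencyWithSelf(nodes, edges)
  acc <- matrix(0, length(nodes), length(nodes))
  for (g in use) {
    fw <- gnnForward(S, X[, g, drop = FALSE], model@params, keepCache = TRUE)
    dS <- logitAdjacencyGrad(S, fw, model@params, pred$label[g] + 1L)
    acc <- acc + abs(dS + t(dS)) / 2
  }
  acc <- acc / length(use)
  if (nrow(edges) > 0) {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    edgeImp <- acc[cbind(i, j)] + acc[cbind(j, i)]
  } else {
    edgeImp <- numeric(0)
    i <- j <- integer(0)
  }
  nodeImp <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_along(edgeImp)) {
    nodeImp[i[k]] <- max(nodeImp[i[k]], edgeImp[k])
    nodeImp[j[k]] <- max(nodeImp[j[k]], edgeImp[k])
  }
  mx <- if (length(edgeImp)) max(edgeImp) else 0
  if (mx > 0) {
    edgeImp <- edgeImp / mx
    nodeImp <- nodeImp / mx
  }
  names(edgeImp) <- if (nrow(edges)) edgeKey(edges[, 1], edges[, 2]) else character(0)
  new("ImportanceScores", nodeImportance = nodeImp, edgeImportance = edgeImp)
}

#' Decompose a PPI network into high-importance connected subgraphs
#'
#' The `nMembers` highest-importance genes (ties broken lexicographically)
#' seed one subgraph each; every subgraph is grown greedily from its seed by
#' repeatedly adding the neighbouring gene with the highest importance
#' (again with lexicographic tie-break) until `memberSize` genes are reached
#' or the connected component is exhausted. Subgraphs may overlap. The
#' procedure is deterministic given `(ppi, scores)`.
#'
#' @param ppi a [PPINetwork-class].
#' @param scores an [ImportanceScores-class] over the same genes.
#' @param nMembers number of subgraphs to seed (<= gene count).
#' @param memberSize target genes per subgraph (>= 2).
#' @return a list of [SubgraphSpec-class], in seed order. A seed whose
#'   component is a single isolated gene cannot form a valid (>= 2 gene)
#'   subgraph and is dropped with a warning.
#' @export
extractSubgraphs <- function(ppi, scores, nMembers = 10L, memberSize = 5L) {
  stopifnot(is(ppi, "PPINetwork"), is(scores, "ImportanceScores"))
  nMembers <- as.integer(nMembers)
  memberSize <- as.integer(memberSize)
  if (nMembers < 1L) stop("nMembers must be >= 1")
  if (memberSize < 2L) stop("memberSize must be >= 2")
  if (numNodes(ppi) < memberSize)
    stop("memberSize exceeds the network's node count")
  if (nMembers > numNodes(ppi))
    stop("nMembers (", nMembers, ") exceeds the node count (", numNodes(ppi), ")")
  imp <- scores@nodeImportance[ppi@nodes]
  if (anyNA(imp)) stop("importance scores do not cover the network's genes")
  adj <- adjacencyList(ppi)
  seeds <- ppi@nodes[order(-imp, ppi@nodes)][seq_len(nMembers)]
  out <- list()
  for (seed in seeds) {
    genes <- seed
    repeat {
      if (length(genes) >= memberSize) break
      nb <- setdiff(unique(unlist(adj[genes], use.names = FALSE)), genes)
      if (length(nb) == 0L) break
      pick <- nb[order(-imp[nb], nb)][1L]
      genes <- c(genes, pick)
    }
    if (length(genes) < 2L) {
      warning("seed gene ", seed,
              " is isolated; its subgraph is dropped")
      next
    }
    sub <- inducedNetwork(ppi, genes)
    out[[length(out) + 1L]] <- new("SubgraphSpec", genes = sub@nodes,
                                   edges = sub@edges)
  }
  out
}

adjacencyList <- function(ppi) {
  adj <- stats::setNames(vector("list", length(ppi@nodes)), ppi@nodes)
  e <- ppi@edges
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  adj
}

#' Export importance scores as two TSV tables
#'
#' Writes `(gene, score)` and `(gene_a, gene_b, score)` tables, the tabular
#' counterpart of rendering importance as node size and edge thickness.
#'
#' @param scores an [ImportanceScores-class].
#' @param nodePath,edgePath output file paths.
#' @return invisibly, `c(nodePath, edgePath)`.
#' @export
writeImportanceTables <- function(scores, nodePath, edgePath) {
  nodeTab <- data.frame(gene = names(scores@nodeImportance),
                        score = unname(scores@nodeImportance))
  ek <- strsplit(names(scores@edgeImportance), "|", fixed = TRUE)
  edgeTab <- data.frame(
    gene_a = vapply(ek, `[[`, character(1), 1L),
    gene_b = vapply(ek, `[[`, character(1), 2L),
    score = unname(scores@edgeImportance))
  utils::write.table(nodeTab, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edgeTab, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodePath, edgePath))
}
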