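#' @import methods
NULL

#' PPINetwork: an undirected protein-protein interaction topology
#'
#' Holds the shared knowledge-graph topology over gene symbols. Edges are
#' undirected, stored once with endpoints in lexicographic order, self-loops
#' are not allowed, and the node order is deterministic (lexicographic).
#'
#' @slot nodes character vector of gene symbols, lexicographically sorted.
#' @slot edges two-column character matrix; each row one undirected edge with
#'   `edges[i, 1] < edges[i, 2]`, rows sorted and unique.
#'
#' @seealso [readPPI()], [writePPI()], [inducedNetwork()], [generatePPI()]
#' @exportClass PPINetwork
setClass("PPINetwork",
  representation(nodes = "character", edges = "matrix"),
  prototype(nodes = character(0),
            edges = matrix(character(0), ncol = 2L))
)

setValidity("PPINetwork", function(object) {
  msgs <- character(0)
  n <- object@nodes
  e <- object@edges
  if (!is.character(n)) msgs <- c(msgs, "nodes must be character")
  if (anyDuplicated(n)) msgs <- c(msgs, "duplicate node names")
  if (is.unsorted(n, strictly = TRUE) && length(n) > 1)
    msgs <- c(msgs, "nodes must be in lexicographic order")
  if (!is.character(e) || ncol(e) != 2L)
    msgs <- c(msgs, "edges must be a two-column character matrix")
  else if (nrow(e) > 0) {
    if (any(e[, 1] == e[, 2])) msgs <- c(msgs, "self-loops are not allowed")
    if (any(e[, 1] > e[, 2]))
      msgs <- c(msgs, "edge endpoints must be lexicographically ordered")
    if (!all(e %in% n)) msgs <- c(msgs, "edge endpoint not among nodes")
    key <- paste(e[, 1], e[, 2], sep = "\r")
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' PatientGraphSet: one attributed PPI graph per patient
#'
#' A [SummarizedExperiment::SummarizedExperiment] (assay `"expr"`,
#' genes x samples) paired with the [PPINetwork-class] topology all patients
#' share. Row order is identical to the network's node order, so column `j`
#' of the assay is the node-feature vector of patient `j`'s graph; the binary
#' outcome lives in `colData()$label`.
#'
#' @slot ppi the shared [PPINetwork-class] topology.
#'
#' @seealso [buildPatientGraphs()], [restrictToSubgraph()], [labels()]
#' @exportClass PatientGraphSet
setClass("PatientGraphSet",
  contains = "SummarizedExperiment",
  representation(ppi = "PPINetwork")
)

setValidity("PatientGraphSet", function(object) {
  msgs <- character(0)
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'expr' is required")
  rn <- rownames(object)
  if (is.null(rn)) rn <- character(0)
  if (!identical(rn, object@ppi@nodes))
    msgs <- c(msgs, "row order must equal the PPI node order")
  lab <- SummarizedExperiment::colData(object)$label
  if (is.null(lab)) msgs <- c(msgs, "colData must contain a 'label' column")
  else if (!all(lab %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0 or 1")
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "duplicate sample ids")
  if (length(msgs)) msgs else TRUE
})

#' GNNConfig: hyperparameters of the graph classifier
#'
#' @slot messagePassingLayers number of message-passing layers (sum
#'   aggregation over neighbours plus self, learned linear map, ReLU).
#' @slot hiddenDim width of each hidden layer.
#' @slot epochs training epochs.
#' @slot learningRate Adam step size.
#' @slot seed integer seed controlling initialization and batch order.
#' @slot batchSize mini-batch size (graphs per update).
#'
#' @seealso [gnnConfig()], [trainGNN()]
#' @exportClass GNNConfig
setClass("GNNConfig",
  representation(messagePassingLayers = "integer", hiddenDim = "integer",
                 epochs = "integer", learningRate = "numeric",
                 seed = "integer", batchSize = "integer")
)

setValidity("GNNConfig", function(object) {
  msgs <- character(0)
  for (s in c("messagePassingLayers", "hiddenDim", "epochs", "batchSize")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, paste(s, "must be a count >= 1"))
  }
  if (length(object@learningRate) != 1L || !is.finite(object@learningRate) ||
      object@learningRate <= 0)
    msgs <- c(msgs, "learningRate must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' TrainedGNN: a fitted graph classifier
#'
#' Parameters of the message-passing network together with the gene (node)
#' order the model expects and the per-epoch training loss. Predictions
#' depend only on (parameters, topology, features).
#'
#' @slot config the [GNNConfig-class] used for training.
#' @slot nodeOrder gene symbols, in the order features must be supplied.
#' @slot params list of weight matrices/bias vectors (`W1..WL`, `b1..bL`,
#'   `Wout`, `bout`).
#' @slot trainingLog mean cross-entropy per epoch.
#'
#' @seealso [trainGNN()], [predictGraphs()], [flattenParams()]
#' @exportClass TrainedGNN
setClass("TrainedGNN",
  representation(config = "GNNConfig", nodeOrder = "character",
                 params = "list", trainingLog = "numeric")
)

setValidity("TrainedGNN", function(object) {
  msgs <- character(0)
  if (length(object@nodeOrder) < 1L) msgs <- c(msgs, "nodeOrder is empty")
  if (!all(vapply(object@params, function(p) all(is.finite(p)), logical(1))))
    msgs <- c(msgs, "non-finite parameter")
  if (length(msgs)) msgs else TRUE
})

#' SubgraphSpec: a connected PPI subnetwork
#'
#' An ordered gene subset of a parent PPI network together with the induced
#' edge set. The induced subgraph must be connected and have at least two
#' nodes; these subnetworks seed ensemble members.
#'
#' @slot genes gene symbols in the parent network's (lexicographic) order.
#' @slot edges induced two-column character matrix (same conventions as
#'   [PPINetwork-class]).
#'
#' @seealso [extractSubgraphs()], [plantSignal()]
#' @exportClass SubgraphSpec
setClass("SubgraphSpec",
  representation(genes = "character", edges = "matrix")
)

setValidity("SubgraphSpec", function(object) {
  msgs <- character(0)
  g <- object@genes
  e <- object@edges
  if (length(g) < 2L) msgs <- c(msgs, "a subgraph needs >= 2 genes")
  if (anyDuplicated(g)) msgs <- c(msgs, "duplicate genes")
  if (!is.character(e) || ncol(e) != 2L)
    msgs <- c(msgs, "edges must be a two-column character matrix")
  else {
    if (nrow(e) > 0 && !all(e %in% g))
      msgs <- c(msgs, "edge endpoint outside the gene set")
    ig <- igraph::graph_from_data_frame(
      as.data.frame(e, stringsAsFactors = FALSE),
      directed = FALSE, vertices = g)
    if (!igraph::is_connected(ig)) msgs <- c(msgs, "subgraph is not connected")
  }
  if (length(msgs)) msgs else TRUE
})

#' PerformanceReport: confusion counts and derived metrics for one split
#'
#' Class 1 is the positive class. `accuracy = (tp+tn)/(tp+fp+tn+fn)`,
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`, and
#' `balanced_accuracy = (sensitivity+specificity)/2`; a metric whose
#' denominator is zero is `NA`.
#'
#' @slot splitName which split the counts come from ("train", "validation",
#'   "test", ...).
#' @slot counts named numeric vector `tp`, `fp`, `tn`, `fn`.
#' @slot metrics named numeric vector `accuracy`, `balanced_accuracy`,
#'   `sensitivity`, `specificity`.
#'
#' @seealso [performanceReport()], [evaluateEnsemble()]
#' @exportClass PerformanceReport
setClass("PerformanceReport",
  representation(splitName = "character", counts = "numeric",
                 metrics = "numeric")
)

setValidity("PerformanceReport", function(object) {
  msgs <- character(0)
  cn <- c("tp", "fp", "tn", "fn")
  if (!identical(names(object@counts), cn)) msgs <- c(msgs, "counts must be named tp, fp, tn, fn")
  else if (any(object@counts < 0)) msgs <- c(msgs, "negative confusion count")
  mn <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity")
  if (!identical(names(object@metrics), mn))
    msgs <- c(msgs, "metrics must be named accuracy, balanced_accuracy, sensitivity, specificity")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleMember: one subnetwork-restricted classifier
#'
#' @slot subgraph the [SubgraphSpec-class] the member is restricted to.
#' @slot model the [TrainedGNN-class] trained on that subnetwork's features;
#'   its `nodeOrder` equals the subgraph's genes.
#' @slot performance the member's own [PerformanceReport-class] on the
#'   validation split (or `NULL` before evaluation).
#'
#' @seealso [trainEnsemble()]
#' @exportClass EnsembleMember
setClass("EnsembleMember",
  representation(subgraph = "SubgraphSpec", model = "TrainedGNN",
                 performance = "ANY")
)

setValidity("EnsembleMember", function(object) {
  msgs <- character(0)
  if (!identical(object@model@nodeOrder, object@subgraph@genes))
    msgs <- c(msgs, "model nodeOrder must equal the subgraph genes")
  if (!is.null(object@performance) && !is(object@performance, "PerformanceReport"))
    msgs <- c(msgs, "performance must be NULL or a PerformanceReport")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleClassifier: an ordered collection of subnetwork classifiers
#'
#' Member order is stable: vote-weight indices refer to it, locally and after
#' federated concatenation. `provenance` records the originating participant
#' of each member ("local" before federation).
#'
#' @slot members list of [EnsembleMember-class].
#' @slot provenance character, one participant id per member.
#'
#' @seealso [trainEnsemble()], [weightedVote()], [aggregateModels()]
#' @exportClass EnsembleClassifier
setClass("EnsembleClassifier",
  representation(members = "list", provenance = "character")
)

setValidity("EnsembleClassifier", function(object) {
  msgs <- character(0)
  if (length(object@members) < 1L) msgs <- c(msgs, "an ensemble needs >= 1 member")
  if (!all(vapply(object@members, is, logical(1), "EnsembleMember")))
    msgs <- c(msgs, "members must all be EnsembleMember")
  if (length(object@provenance) != length(object@members))
    msgs <- c(msgs, "provenance length must equal member count")
  if (length(msgs)) msgs else TRUE
})

#' FederationResult: outcome of an in-process federated run
#'
#' @slot globalModel the concatenated [EnsembleClassifier-class] every client
#'   received.
#' @slot perClientReports named list (per client) of lists of
#'   [PerformanceReport-class] for the local and global model on the client's
#'   validation and test splits.
#' @slot aggregatedWeights numeric vector of federated vote weights from the
#'   last aggregation round, or `NULL` when no interactive round ran.
#' @slot transcript data.frame of state transitions
#'   (participant, from, to, event), one state machine per participant.
#' @slot messages list of every cross-participant message
#'   (sender, recipient, kind, payload) for audit.
#' @slot interactiveEvaluations list of re-scoring events performed after
#'   weight changes (client, round, weights, report).
#'
#' @seealso [runFederation()]
#' @exportClass FederationResult
setClass("FederationResult",
  representation(globalModel = "EnsembleClassifier",
                 perClientReports = "list",
                 aggregatedWeights = "ANY",
                 transcript = "data.frame",
                 messages = "list",
                 interactiveEvaluations = "list")
)
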