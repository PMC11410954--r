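#' @include AllClasses.R
NULL

#' Accessors for network topologies and ensembles
#'
#' `nodeNames()` returns the ordered node (gene) symbols of a topology;
#' `edgeMatrix()` its undirected edge set as a two-column character matrix;
#' `numNodes()`/`numEdges()` the corresponding counts. `members()` returns
#' the ordered member list of an ensemble, `memberCount()` its length, and
#' `memberProvenance()` the originating participant per member.
#'
#' @param x a [PPINetwork-class], [SubgraphSpec-class],
#'   [PatientGraphSet-class] or [EnsembleClassifier-class].
#' @return see the individual descriptions.
#' @name topology-accessors
#' @aliases nodeNames edgeMatrix numNodes numEdges
#'   nodeNames,PPINetwork-method nodeNames,SubgraphSpec-method
#'   nodeNames,PatientGraphSet-method edgeMatrix,PPINetwork-method
#'   edgeMatrix,SubgraphSpec-method edgeMatrix,PatientGraphSet-method
#'   numNodes,PPINetwork-method numNodes,SubgraphSpec-method
#'   numEdges,PPINetwork-method numEdges,SubgraphSpec-method
#'   members,EnsembleClassifier-method memberCount,EnsembleClassifier-method
#'   memberProvenance,EnsembleClassifier-method
NULL

#' @rdname topology-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname topology-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname topology-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname topology-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname topology-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname topology-accessors
#' @export
setGeneric("memberCount", function(x) standardGeneric("memberCount"))

#' @rdname topology-accessors
#' @export
setGeneric("memberProvenance", function(x) standardGeneric("memberProvenance"))

setMethod("nodeNames", "PPINetwork", function(x) x@nodes)
setMethod("nodeNames", "SubgraphSpec", function(x) x@genes)
setMethod("nodeNames", "PatientGraphSet", function(x) x@ppi@nodes)
setMethod("edgeMatrix", "PPINetwork", function(x) x@edges)
setMethod("edgeMatrix", "SubgraphSpec", function(x) x@edges)
setMethod("edgeMatrix", "PatientGraphSet", function(x) x@ppi@edges)
setMethod("numNodes", "PPINetwork", function(x) length(x@nodes))
setMethod("numNodes", "SubgraphSpec", function(x) length(x@genes))
setMethod("numEdges", "PPINetwork", function(x) nrow(x@edges))
setMethod("numEdges", "SubgraphSpec", function(x) nrow(x@edges))
setMethod("members", "EnsembleClassifier", function(x) x@members)
setMethod("memberCount", "EnsembleClassifier", function(x) length(x@members))
setMethod("memberProvenance", "EnsembleClassifier", function(x) x@provenance)

#' Topology and labels of a PatientGraphSet
#'
#' `ppiNetwork()` returns the shared [PPINetwork-class] topology;
#' `graphLabels()` the per-patient binary outcome as an integer vector named
#' by sample id.
#'
#' @param x a [PatientGraphSet-class].
#' @name patientgraph-accessors
#' @aliases ppiNetwork graphLabels ppiNetwork,PatientGraphSet-method
#'   graphLabels,PatientGraphSet-method
NULL

#' @rdname patientgraph-accessors
#' @export
setGeneric("ppiNetwork", function(x) standardGeneric("ppiNetwork"))

#' @rdname patientgraph-accessors
#' @export
setGeneric("graphLabels", function(x) standardGeneric("graphLabels"))

setMethod("ppiNetwork", "PatientGraphSet", function(x) x@ppi)
setMethod("graphLabels", "PatientGraphSet", function(x) {
  lab <- as.integer(SummarizedExperiment::colData(x)$label)
  names(lab) <- colnames(x)
  lab
})

#' Accessors for performance reports
#'
#' `splitName()` names the data split the report was computed on;
#' `confusionCounts()` returns the named `tp/fp/tn/fn` vector and
#' `perfMetrics()` the named metric vector (accuracy, balanced accuracy,
#' sensitivity, specificity).
#'
#' @param x a [PerformanceReport-class].
#' @name performance-accessors
#' @aliases splitName confusionCounts perfMetrics
#'   splitName,PerformanceReport-method
#'   confusionCounts,PerformanceReport-method
#'   perfMetrics,PerformanceReport-method
NULL

#' @rdname performance-accessors
#' @export
setGeneric("splitName", function(x) standardGeneric("splitName"))

#' @rdname performance-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname performance-accessors
#' @export
setGeneric("perfMetrics", function(x) standardGeneric("perfMetrics"))

setMethod("splitName", "PerformanceReport", function(x) x@splitName)
setMethod("confusionCounts", "PerformanceReport", function(x) x@counts)
setMethod("perfMetrics", "PerformanceReport", function(x) x@metrics)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", length(object@nodes), "genes,",
      nrow(object@edges), "undirected edges\n")
  if (length(object@nodes))
    cat("  genes:", paste(utils::head(object@nodes, 5), collapse = ", "),
        if (length(object@nodes) > 5) "..." else "", "\n")
})

setMethod("show", "PatientGraphSet", function(object) {
  callNextMethod()
  lab <- graphLabels(object)
  cat("shared PPI topology: ", numNodes(object@ppi), " genes, ",
      numEdges(object@ppi), " edges; labels: ",
      sum(lab == 0L), "x class 0, ", sum(lab == 1L), "x class 1\n", sep = "")
})

setMethod("show", "SubgraphSpec", function(object) {
  cat("SubgraphSpec:", length(object@genes), "genes,", nrow(object@edges),
      "edges |", paste(object@genes, collapse = ", "), "\n")
})

setMethod("show", "GNNConfig", function(object) {
  cat(sprintf(
    "GNNConfig: %d message-passing layer(s), hidden %d, %d epochs, lr %g, batch %d, seed %d\n",
    object@messagePassingLayers, object@hiddenDim, object@epochs,
    object@learningRate, object@batchSize, object@seed))
})

setMethod("show", "TrainedGNN", function(object) {
  cat("TrainedGNN over", length(object@nodeOrder), "genes;",
      length(object@trainingLog), "epochs, final loss",
      signif(utils::tail(object@trainingLog, 1), 4), "\n")
})

setMethod("show", "PerformanceReport", function(object) {
  m <- object@metrics
  cat(sprintf("PerformanceReport [%s]: acc %.3f, bal.acc %.3f, sens %.3f, spec %.3f (tp %.0f fp %.0f tn %.0f fn %.0f)\n",
              object@splitName, m["accuracy"], m["balanced_accuracy"],
              m["sensitivity"], m["specificity"],
              object@counts["tp"], object@counts["fp"],
              object@counts["tn"], object@counts["fn"]))
})

setMethod("show", "EnsembleClassifier", function(object) {
  cat("EnsembleClassifier with", length(object@members), "member(s)\n")
  sizes <- vapply(object@members, function(m) length(m@subgraph@genes), integer(1))
  cat("  member sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  provenance:", paste(unique(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "FederationResult", function(object) {
  cat("FederationResult:", memberCount(object@globalModel),
      "global members from", length(object@perClientReports), "client(s);",
      nrow(object@transcript), "transitions,", length(object@messages),
      "messages\n")
})
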