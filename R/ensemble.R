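#' @include AllClasses.R gnn.R explain.R
NULL

#' Restrict patient graphs to a subnetwork
#'
#' Keeps only the subgraph's genes (features and topology); the resulting
#' graphs share the subgraph's induced edge set.
#'
#' @param graphs a [PatientGraphSet-class].
#' @param subgraph a [SubgraphSpec-class] over genes present in `graphs`.
#' @return a [PatientGraphSet-class] over the subgraph's genes.
#' @export
restrictToSubgraph <- function(graphs, subgraph) {
  stopifnot(is(graphs, "PatientGraphSet"), is(subgraph, "SubgraphSpec"))
  if (!all(subgraph@genes %in% nodeNames(graphs)))
    stop("topology mismatch: subgraph gene(s) absent from the patient graphs: ",
         paste(utils::head(setdiff(subgraph@genes, nodeNames(graphs)), 5),
               collapse = ", "))
  net <- new("PPINetwork", nodes = subgraph@genes, edges = subgraph@edges)
  mat <- SummarizedExperiment::assay(graphs, "expr")[subgraph@genes, ,
                                                     drop = FALSE]
  se <- makeExpressionSE(mat, unname(graphLabels(graphs)))
  new("PatientGraphSet", se, ppi = net)
}

#' Build a confusion-count performance report
#'
#' Class 1 is the positive class. Metrics with a zero denominator are `NA`.
#'
#' @param truth integer vector of true labels in \{0, 1\}.
#' @param predicted integer vector of predicted labels, same length.
#' @param splitName name of the data split the labels come from.
#' @return a [PerformanceReport-class].
#' @export
performanceReport <- function(truth, predicted, splitName = "validation") {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  new("PerformanceReport", splitName = splitName,
      counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
      metrics = c(accuracy = (tp + tn) / (tp + fp + tn + fn),
                  balanced_accuracy = (sens + spec) / 2,
                  sensitivity = sens, specificity = spec))
}

#' Train one classifier per subnetwork
#'
#' Each subgraph yields one ensemble member: a graph classifier trained only
#' on that subnetwork's genes (features and induced topology), in subgraph
#' order. Member performance is scored on `evalGraphs` (the validation
#' split). A member whose training fails is dropped with a warning; at least
#' one member must survive.
#'
#' @param trainGraphs a [PatientGraphSet-class] with both classes present.
#' @param subgraphs list of [SubgraphSpec-class] from [extractSubgraphs()].
#' @param config a [GNNConfig-class] shared by all members.
#' @param evalGraphs a [PatientGraphSet-class] used for per-member
#'   performance (validation split).
#' @return an [EnsembleClassifier-class] with provenance `"local"`.
#' @export
trainEnsemble <- function(trainGraphs, subgraphs, config = gnnConfig(),
                          evalGraphs = NULL) {
  stopifnot(is(trainGraphs, "PatientGraphSet"), length(subgraphs) >= 1L)
  membersOut <- list()
  for (k in seq_along(subgraphs)) {
    sg <- subgraphs[[k]]
    member <- tryCatch({
      sub <- restrictToSubgraph(trainGraphs, sg)
      model <- trainGNN(sub, config)
      perf <- NULL
      if (!is.null(evalGraphs)) {
        evalSub <- restrictToSubgraph(evalGraphs, sg)
        pred <- predictGraphs(model, evalSub)
        perf <- performanceReport(unname(graphLabels(evalSub)), pred$label,
                                  "validation")
      }
      new("EnsembleMember", subgraph = sg, model = model, performance = perf)
    }, error = function(e) {
      warning("member ", k, " dropped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(member)) membersOut[[length(membersOut) + 1L]] <- member
  }
  if (length(membersOut) == 0L)
    stop("no ensemble member could be trained")
  new("EnsembleClassifier", members = membersOut,
      provenance = rep("local", length(membersOut)))
}

#' Default (neutral) vote weights for an ensemble
#'
#' Every member starts with weight 1.
#'
#' @param ensemble an [EnsembleClassifier-class].
#' @return numeric vector of ones, one per member.
#' @export
defaultWeights <- function(ensemble) {
  rep(1, memberCount(ensemble))
}

checkWeights <- function(weights, nMembers) {
  if (length(weights) != nMembers)
    stop("weight configuration has length ", length(weights),
         " but the ensemble has ", nMembers, " member(s)")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("vote weights must be finite and >= 0")
  invisible(as.numeric(weights))
}

#' Hard-label votes of every ensemble member
#'
#' @param ensemble an [EnsembleClassifier-class].
#' @param graphs a [PatientGraphSet-class] covering every member's genes.
#' @return integer matrix, members x patients, entries in \{0, 1\}.
#' @export
memberVotes <- function(ensemble, graphs) {
  votes <- vapply(members(ensemble), function(m) {
    sub <- restrictToSubgraph(graphs, m@subgraph)
    predictGraphs(m@model, sub)$label
  }, integer(ncol(graphs)))
  t(matrix(votes, ncol = memberCount(ensemble)))
}

#' Combine member votes by weighted majority
#'
#' The score of class `c` is the sum of the weights of the members voting
#' for `c`; the returned label is the class with the larger score, with
#' exact ties going to class 0.
#'
#' @param votes integer matrix (members x patients) of hard labels in
#'   \{0, 1\}.
#' @param weights non-negative numeric vector, one weight per member.
#' @return integer vector of combined labels, one per patient.
#' @export
tallyVotes <- function(votes, weights) {
  if (is.matrix(votes)) {
    votes <- matrix(as.numeric(votes), nrow = nrow(votes))
  } else {
    votes <- matrix(as.numeric(votes), nrow = length(votes))
  }
  weights <- checkWeights(weights, nrow(votes))
  score1 <- as.vector(weights %*% votes)
  score0 <- as.vector(weights %*% (1 - votes))
  as.integer(score1 > score0)
}

#' Weighted majority vote of an ensemble on patient graphs
#'
#' Each member predicts a hard label on its own subnetwork view of the
#' graph; labels are combined by [tallyVotes()] under the given weights
#' (default: all 1, the neutral configuration).
#'
#' @param ensemble an [EnsembleClassifier-class].
#' @param graphs a [PatientGraphSet-class].
#' @param weights numeric vote weights, one per member (>= 0).
#' @return integer vector of predicted labels, one per patient.
#' @export
weightedVote <- function(ensemble, graphs, weights = defaultWeights(ensemble)) {
  checkWeights(weights, memberCount(ensemble))
  tallyVotes(memberVotes(ensemble, graphs), weights)
}

#' Evaluate an ensemble on a labelled split
#'
#' @param ensemble an [EnsembleClassifier-class].
#' @param graphs a non-empty labelled [PatientGraphSet-class].
#' @param weights vote weights (default all 1).
#' @param splitName name recorded in the report.
#' @return a [PerformanceReport-class].
#' @export
evaluateEnsemble <- function(ensemble, graphs,
                             weights = defaultWeights(ensemble),
                             splitName = "validation") {
  if (ncol(graphs) < 1L) stop("cannot evaluate on an empty split")
  predicted <- weightedVote(ensemble, graphs, weights)
  performanceReport(unname(graphLabels(graphs)), predicted, splitName)
}

# ---- detachment & serialization ---------------------------------------

# all numerics in a payload are rendered in fixed-width scientific notation
# so the serialized byte size depends only on the architecture and member
# count, never on the cohort the models were trained on
fmtNum <- function(x) formatC(as.numeric(x), format = "e", digits = 10,
                              width = 18)

parseNum <- function(s) as.numeric(trimws(s))

configAsList <- function(config) {
  list(messagePassingLayers = config@messagePassingLayers,
       hiddenDim = config@hiddenDim, epochs = config@epochs,
       learningRate = fmtNum(config@learningRate),
       seed = config@seed, batchSize = config@batchSize)
}

configFromList <- function(x) {
  gnnConfig(messagePassingLayers = x$messagePassingLayers,
            hiddenDim = x$hiddenDim, epochs = x$epochs,
            learningRate = parseNum(x$learningRate), seed = x$seed,
            batchSize = x$batchSize)
}

#' Detach an ensemble from its training data for sharing
#'
#' Produces the shareable payload: per member the subnetwork topology, gene
#' names, model architecture and flat parameter vector, and the member's
#' performance summary. The payload contains no sample ids, no expression
#' values and no labels, and its serialized size is independent of the
#' number of patients the ensemble was trained on.
#'
#' @param ensemble a trained [EnsembleClassifier-class].
#' @return a plain list (`version`, `members`, `provenance`) ready for
#'   [payloadText()] / [writeEnsemblePayload()] and [attachEnsemble()].
#' @export
detachData <- function(ensemble) {
  stopifnot(is(ensemble, "EnsembleClassifier"))
  mem <- lapply(members(ensemble), function(m) {
    perf <- m@performance
    list(genes = m@subgraph@genes,
         edge_a = m@subgraph@edges[, 1],
         edge_b = m@subgraph@edges[, 2],
         config = configAsList(m@model@config),
         parameters = fmtNum(flattenParams(m@model)),
         performance = if (is.null(perf)) NULL else
           list(split = perf@splitName,
                counts = as.list(stats::setNames(fmtNum(perf@counts),
                                                 names(perf@counts))),
                metrics = as.list(stats::setNames(fmtNum(perf@metrics),
                                                  names(perf@metrics)))))
  })
  list(version = "fedgnn-ensemble-1", members = mem,
       provenance = memberProvenance(ensemble))
}

#' Canonical text form of a detached payload
#'
#' Versioned JSON with all numbers in fixed-width scientific notation; the
#' representation exchanged between federation participants.
#'
#' @param payload a list from [detachData()].
#' @return a single JSON string.
#' @export
payloadText <- function(payload) {
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null"))
}

#' Write / read a detached ensemble payload
#'
#' @param payload a list from [detachData()].
#' @param path file path.
#' @return `writeEnsemblePayload()` returns `path` invisibly;
#'   `readEnsemblePayload()` returns the payload list.
#' @export
writeEnsemblePayload <- function(payload, path) {
  writeLines(payloadText(payload), path)
  invisible(path)
}

#' @rdname writeEnsemblePayload
#' @export
readEnsemblePayload <- function(path) {
  jsonlite::fromJSON(readLines(path, warn = FALSE),
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Rebuild an ensemble classifier from a detached payload
#'
#' Inverse of [detachData()]: the restored ensemble produces identical
#' predictions (up to the payload's 10-digit parameter precision).
#'
#' @param payload a payload list, possibly re-read from disk.
#' @return an [EnsembleClassifier-class].
#' @export
attachEnsemble <- function(payload) {
  if (!identical(payload$version, "fedgnn-ensemble-1"))
    stop("unsupported payload version: ", payload$version)
  mem <- lapply(payload$members, function(m) {
    genes <- as.character(unlist(m$genes))
    ea <- as.character(unlist(m$edge_a))
    eb <- as.character(unlist(m$edge_b))
    sg <- new("SubgraphSpec", genes = genes, edges = cbind(ea, eb))
    config <- configFromList(m$config)
    model <- restoreModel(parseNum(unlist(m$parameters)), config, genes)
    perf <- NULL
    if (!is.null(m$performance))
      perf <- new("PerformanceReport", splitName = m$performance$split,
                  counts = stats::setNames(parseNum(unlist(m$performance$counts)),
                                           c("tp", "fp", "tn", "fn")),
                  metrics = stats::setNames(parseNum(unlist(m$performance$metrics)),
                                            c("accuracy", "balanced_accuracy",
                                              "sensitivity", "specificity")))
    new("EnsembleMember", subgraph = sg, model = model, performance = perf)
  })
  new("EnsembleClassifier", members = mem,
      provenance = as.character(unlist(payload$provenance)))
}

#' Write performance reports as a structured text file
#'
#' One record per (model, split): TSV with columns model, split, the four
#' confusion counts and the four metrics.
#'
#' @param reports named list of [PerformanceReport-class] (names identify
#'   the model, e.g. `"local"` / `"global"`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePerformanceReports <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cbind(data.frame(model = nm, split = r@splitName),
          as.data.frame(as.list(r@counts)),
          as.data.frame(as.list(r@metrics)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
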