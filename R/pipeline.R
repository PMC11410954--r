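#' @include federation.R synthdata.R
NULL

#' Run the full local analysis of one data holder
#'
#' The single-client pipeline: train a GNN on the full PPI using the
#' training split, score node/edge importance, extract connected
#' high-importance subgraphs, train one ensemble member per subgraph, and
#' report local ensemble performance on the validation and test splits.
#'
#' @param graphs a [PatientGraphSet-class] (all patients of this client).
#' @param config a [GNNConfig-class].
#' @param nMembers,memberSize subgraph extraction parameters; both are
#'   capped at the network's node count.
#' @param fractions train/validation/test fractions.
#' @param seed seed for the split (the GNN seed comes from `config`).
#' @return a list: `split`, `fullModel`, `scores`, `subgraphs`, `ensemble`,
#'   and `reports` (named [PerformanceReport-class] list:
#'   `local_validation`, `local_test`).
#' @export
trainLocalEnsemble <- function(graphs, config = gnnConfig(), nMembers = 10L,
                               memberSize = 5L,
                               fractions = c(train = 0.6, validation = 0.2,
                                             test = 0.2),
                               seed = config@seed) {
  stopifnot(is(graphs, "PatientGraphSet"))
  split <- splitDataset(unname(graphLabels(graphs)), fractions, seed = seed)
  trainG <- graphs[, split$train]
  valG <- graphs[, split$validation]
  testG <- graphs[, split$test]
  fullModel <- trainGNN(trainG, config)
  scores <- computeImportance(fullModel, trainG)
  net <- ppiNetwork(graphs)
  subgraphs <- extractSubgraphs(net, scores,
                                nMembers = min(as.integer(nMembers),
                                               numNodes(net)),
                                memberSize = min(as.integer(memberSize),
                                                 numNodes(net)))
  ensemble <- trainEnsemble(trainG, subgraphs, config, evalGraphs = valG)
  reports <- list(
    local_validation = evaluateEnsemble(ensemble, valG,
                                        splitName = "validation"),
    local_test = evaluateEnsemble(ensemble, testG, splitName = "test"))
  list(split = split, fullModel = fullModel, scores = scores,
       subgraphs = subgraphs, ensemble = ensemble, reports = reports)
}

#' Run a federated simulation from a YAML run configuration
#'
#' Mirrors the `fedgnn simulate` command line. The YAML file holds the
#' shared run options and one entry per client:
#' ```
#' interactive: false
#' n_members: 10
#' member_size: 5
#' seed: 1
#' fractions: [0.6, 0.2, 0.2]
#' gnn: {message_passing_layers: 2, hidden_dim: 32, epochs: 50,
#'       learning_rate: 0.01, batch_size: 16}
#' clients:
#'   - id: site_a
#'     ppi_path: ppi_edges.tsv
#'     expression_path: expression.tsv
#'     label_column: label
#'     actions:
#'       - {type: weights, weights: [1, 1, 2]}
#'       - {type: terminate}
#' ```
#' Writes per-client performance TSVs, the global model payload, the
#' transcript log and (when an aggregation round ran) the aggregated
#' weights into `outputDir`.
#'
#' @param configPath path to the YAML run configuration.
#' @param outputDir output directory (created if needed).
#' @return the [FederationResult-class], invisibly.
#' @export
runFederationFromConfig <- function(configPath, outputDir = ".") {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations")
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$clients) || length(cfg$clients) < 1L)
    stop("run configuration lists no clients")
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  graphs <- list()
  actions <- list()
  for (cl in cfg$clients) {
    id <- cl$id
    if (is.null(id)) stop("every client needs an 'id'")
    ppi <- readPPI(resolve(cl$ppi_path))
    expr <- readExpression(resolve(cl$expression_path),
                           labelColumn = cl$label_column %||% "label")
    graphs[[id]] <- buildPatientGraphs(expr, ppi)
    if (!is.null(cl$actions)) actions[[id]] <- cl$actions
  }
  g <- cfg$gnn %||% list()
  config <- gnnConfig(
    messagePassingLayers = g$message_passing_layers %||% 2L,
    hiddenDim = g$hidden_dim %||% 32L, epochs = g$epochs %||% 50L,
    learningRate = g$learning_rate %||% 1e-2,
    seed = cfg$seed %||% 1L, batchSize = g$batch_size %||% 16L)
  fractions <- cfg$fractions %||% c(0.6, 0.2, 0.2)
  res <- runFederation(graphs, config = config,
                       nMembers = cfg$n_members %||% 10L,
                       memberSize = cfg$member_size %||% 5L,
                       fractions = as.numeric(fractions),
                       interactive = isTRUE(cfg$interactive),
                       scriptedActions = if (length(actions)) actions else NULL,
                       seed = cfg$seed %||% 1L)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  for (cid in names(res@perClientReports))
    writePerformanceReports(res@perClientReports[[cid]],
                            file.path(outputDir,
                                      paste0("client_", cid,
                                             "_performance.tsv")))
  writeEnsemblePayload(detachData(res@globalModel),
                       file.path(outputDir, "global_model.json"))
  utils::write.table(res@transcript, file.path(outputDir, "transcript.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res@aggregatedWeights))
    writeLines(format(res@aggregatedWeights, digits = 15),
               file.path(outputDir, "aggregated_weights.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
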