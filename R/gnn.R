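#' @include AllClasses.R graphio.R
NULL

#' Create a GNN hyperparameter configuration
#'
#' Defaults give the smallest standard graph classifier that recovers a
#' planted expression signal: two sum-aggregation message-passing layers with
#' learned linear maps and ReLU, global mean pooling, and a two-logit linear
#' output head trained with cross-entropy and Adam.
#'
#' @param messagePassingLayers number of message-passing layers (>= 1).
#' @param hiddenDim hidden width.
#' @param epochs training epochs.
#' @param learningRate Adam step size.
#' @param seed integer seed for initialization and batch shuffling.
#' @param batchSize graphs per parameter update.
#' @return a [GNNConfig-class].
#' @export
gnnConfig <- function(messagePassingLayers = 2L, hiddenDim = 32L,
                      epochs = 50L, learningRate = 1e-2, seed = 1L,
                      batchSize = 16L) {
  new("GNNConfig",
      messagePassingLayers = as.integer(messagePassingLayers),
      hiddenDim = as.integer(hiddenDim), epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate), seed = as.integer(seed),
      batchSize = as.integer(batchSize))
}

# dense adjacency-plus-self matrix in a given node order: message passing
# sums over neighbours and the node itself
adjacencyWithSelf <- function(nodes, edges) {
  n <- length(nodes)
  S <- diag(1, n)
  dimnames(S) <- list(nodes, nodes)
  if (nrow(edges) > 0) {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    S[cbind(i, j)] <- 1
    S[cbind(j, i)] <- 1
  }
  S
}

paramShapes <- function(config) {
  h <- config@hiddenDim
  L <- config@messagePassingLayers
  shapes <- list()
  din <- 1L
  for (l in seq_len(L)) {
    shapes[[paste0("W", l)]] <- c(din, h)
    shapes[[paste0("b", l)]] <- h
    din <- h
  }
  shapes$Wout <- c(h, 2L)
  shapes$bout <- 2L
  shapes
}

# Glorot-uniform weights, zero biases; draws come from the active RNG stream
initParams <- function(config) {
  shapes <- paramShapes(config)
  params <- list()
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    if (length(s) == 2L) {
      lim <- sqrt(6 / (s[1] + s[2]))
      params[[nm]] <- matrix(stats::runif(prod(s), -lim, lim), s[1], s[2])
    } else {
      params[[nm]] <- numeric(s)
    }
  }
  params
}

#' Flatten model parameters to a single numeric vector
#'
#' Concatenates all weight matrices and bias vectors in layer order
#' (`W1, b1, ..., WL, bL, Wout, bout`), the serializable form used in
#' detached payloads. [restoreModel()] is the inverse.
#'
#' @param model a [TrainedGNN-class].
#' @return numeric vector of all parameters.
#' @export
flattenParams <- function(model) {
  stopifnot(is(model, "TrainedGNN"))
  unlist(lapply(model@params, as.vector), use.names = FALSE)
}

#' Rebuild a trained model from its flat parameter vector
#'
#' @param flat numeric vector as produced by [flattenParams()].
#' @param config the [GNNConfig-class] defining the architecture.
#' @param nodeOrder gene symbols the model expects, in order.
#' @param trainingLog optional per-epoch loss to carry along.
#' @return a [TrainedGNN-class] producing identical predictions to the model
#'   the vector came from.
#' @export
restoreModel <- function(flat, config, nodeOrder, trainingLog = numeric(0)) {
  shapes <- paramShapes(config)
  sizes <- vapply(shapes, prod, numeric(1))
  if (length(flat) != sum(sizes))
    stop("parameter vector has length ", length(flat), ", expected ", sum(sizes))
  params <- list()
  at <- 0L
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    vals <- flat[at + seq_len(prod(s))]
    at <- at + prod(s)
    params[[nm]] <- if (length(s) == 2L) matrix(vals, s[1], s[2]) else vals
  }
  new("TrainedGNN", config = config, nodeOrder = as.character(nodeOrder),
      params = params, trainingLog = as.numeric(trainingLog))
}

# Batched forward pass. S: n x n adjacency-plus-self; X: n x m node features
# (one column per graph). Layer l computes relu(S H W_l + b_l) for every
# graph at once via the (n*m) x h <-> n x (m*h) reshape (column-major order
# (i, g, k) is shared by both layouts, so matrix() is a free reinterpret).
# Returns logits plus the caches backward needs.
gnnForward <- function(S, X, params, keepCache = FALSE) {
  n <- nrow(S)
  m <- ncol(X)
  L <- (length(params) - 2L) / 2L
  Hs <- vector("list", L + 1L)
  masks <- vector("list", L)
  Hs[[1]] <- matrix(as.vector(X), ncol = 1L)        # (n*m) x 1
  Hwide <- NULL
  for (l in seq_len(L)) {
    A <- Hs[[l]] %*% params[[paste0("W", l)]]        # (n*m) x h
    h <- ncol(A)
    P <- S %*% matrix(A, n, m * h)                   # n x (m*h)
    P <- P + matrix(rep(params[[paste0("b", l)]], each = m),
                    n, m * h, byrow = TRUE)
    mask <- P > 0
    P <- P * mask
    masks[[l]] <- mask
    Hwide <- P
    Hs[[l + 1L]] <- matrix(as.vector(P), n * m, h)
  }
  h <- ncol(Hs[[L + 1L]])
  pool <- matrix(colMeans(Hwide), m, h)              # global mean pooling
  logits <- pool %*% params$Wout +
    matrix(params$bout, m, 2L, byrow = TRUE)
  out <- list(logits = logits, n = n, m = m, L = L)
  if (keepCache) {
    out$Hs <- Hs
    out$masks <- masks
    out$pool <- pool
  }
  out
}

softmaxRows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

# gradient of the mean cross-entropy wrt all parameters, given a cached
# forward pass and integer labels y in {0,1}
gnnBackward <- function(S, fw, params, y) {
  n <- fw$n; m <- fw$m; L <- fw$L
  probs <- softmaxRows(fw$logits)
  Y <- cbind(1 - y, y)
  dlogits <- (probs - Y) / m                          # m x 2
  grads <- list()
  grads$Wout <- crossprod(fw$pool, dlogits)
  grads$bout <- colSums(dlogits)
  dpool <- dlogits %*% t(params$Wout)                 # m x h
  dH <- matrix(rep(as.vector(dpool) / n, each = n), n, m * ncol(dpool))
  for (l in rev(seq_len(L))) {
    dP <- dH * fw$masks[[l]]                          # n x (m*h_l)
    h <- ncol(fw$Hs[[l + 1L]])
    cs <- colSums(dP)
    grads[[paste0("b", l)]] <- colSums(matrix(cs, m, h))
    dA <- matrix(as.vector(crossprod(S, dP)), n * m, h)
    grads[[paste0("W", l)]] <- crossprod(fw$Hs[[l]], dA)
    if (l > 1L) {
      dHprev <- dA %*% t(params[[paste0("W", l)]])    # (n*m) x h_{l-1}
      dH <- matrix(as.vector(dHprev), n, m * ncol(dHprev))
    }
  }
  grads[names(params)]
}

meanCrossEntropy <- function(logits, y) {
  probs <- softmaxRows(logits)
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a graph classifier on attributed patient graphs
#'
#' All graphs share one topology; features are the per-patient expression
#' values on the nodes. Training is full mini-batch gradient descent with
#' Adam on the mean cross-entropy, deterministic under the config seed
#' (initialization and batch order are the only random draws, and the
#' caller's RNG state is left untouched).
#'
#' @param graphs a [PatientGraphSet-class]; at least two graphs with both
#'   classes present.
#' @param config a [GNNConfig-class].
#' @return a [TrainedGNN-class] with the per-epoch mean training loss in its
#'   `trainingLog`.
#' @export
trainGNN <- function(graphs, config = gnnConfig()) {
  stopifnot(is(graphs, "PatientGraphSet"), is(config, "GNNConfig"))
  validObject(config)
  nodes <- nodeNames(graphs)
  if (length(nodes) == 0L) stop("empty topology: no nodes to train on")
  m <- ncol(graphs)
  if (m < 2L) stop("need at least 2 graphs to train")
  y <- unname(graphLabels(graphs))
  if (length(unique(y)) < 2L)
    stop("degenerate data: training set contains a single class")
  X <- SummarizedExperiment::assay(graphs, "expr")
  S <- adjacencyWithSelf(nodes, edgeMatrix(graphs))
  batch <- min(config@batchSize, m)
  lossLog <- numeric(config@epochs)
  params <- NULL
  withSeed(config@seed, {
    params <- initParams(config)
    opt <- adamInit(params, config@learningRate)
    for (epoch in seq_len(config@epochs)) {
      perm <- sample.int(m)
      starts <- seq(1L, m, by = batch)
      epochLoss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + batch - 1L, m)]
        fw <- gnnForward(S, X[, idx, drop = FALSE], params, keepCache = TRUE)
        epochLoss <- epochLoss + meanCrossEntropy(fw$logits, y[idx]) * length(idx)
        grads <- gnnBackward(S, fw, params, y[idx])
        upd <- adamStep(opt, params, grads)
        params <- upd$params
        opt <- upd$opt
      }
      lossLog[epoch] <- epochLoss / m
    }
  })
  new("TrainedGNN", config = config, nodeOrder = nodes, params = params,
      trainingLog = lossLog)
}

adamInit <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

adamStep <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(params = params, opt = opt)
}

#' Predict class labels and probabilities for patient graphs
#'
#' The graphs' node set must equal the model's `nodeOrder` (the node-set
#' match is checked; features and adjacency are aligned to the model's
#' order, so a consistently relabelled graph scores identically). Class
#' probabilities are the softmax of the two logits; the label is the argmax
#' with ties going to class 0.
#'
#' @param model a [TrainedGNN-class].
#' @param graphs a [PatientGraphSet-class] over the same node set.
#' @return a data.frame with one row per patient: `sample_id`, `label`
#'   (predicted), `p0`, `p1`.
#' @export
predictGraphs <- function(model, graphs) {
  stopifnot(is(model, "TrainedGNN"), is(graphs, "PatientGraphSet"))
  nodes <- nodeNames(graphs)
  if (!setequal(nodes, model@nodeOrder) ||
      length(nodes) != length(model@nodeOrder))
    stop("topology mismatch: graph node set differs from the model's node order")
  X <- SummarizedExperiment::assay(graphs, "expr")[model@nodeOrder, ,
                                                   drop = FALSE]
  S <- adjacencyWithSelf(model@nodeOrder, edgeMatrix(graphs))
  fw <- gnnForward(S, X, model@params)
  probs <- softmaxRows(fw$logits)
  data.frame(sample_id = colnames(graphs),
             label = as.integer(probs[, 2] > probs[, 1]),
             p0 = probs[, 1], p1 = probs[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
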