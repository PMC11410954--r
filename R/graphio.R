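#' @include AllClasses.R
NULL

# canonicalize an edge matrix: endpoints sorted within each pair, self-loops
# removed, duplicate pairs collapsed, rows in lexicographic order
canonicalEdges <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi
  lo <- lo[keep]
  hi <- hi[keep]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]
  hi <- hi[!dup]
  o <- order(lo, hi)
  cbind(lo[o], hi[o])
}

#' Construct a PPI network from an edge list
#'
#' Endpoints are sorted within each pair, duplicate pairs collapse to one
#' undirected edge, self-loops are dropped (with a warning when `quiet =
#' FALSE`), and nodes end up in lexicographic order.
#'
#' @param edges two-column character matrix (or data.frame) of gene pairs.
#' @param nodes optional extra gene symbols to keep as isolated nodes.
#' @param quiet suppress the self-loop warning.
#' @return a [PPINetwork-class].
#' @export
newPPINetwork <- function(edges, nodes = character(0), quiet = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edges must have two columns")
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  nLoop <- sum(a == b)
  if (nLoop > 0 && !quiet)
    warning(nLoop, " self-loop(s) dropped from the PPI edge list")
  e <- canonicalEdges(a, b)
  allNodes <- sort(unique(c(e[, 1], e[, 2], as.character(nodes))))
  new("PPINetwork", nodes = allNodes, edges = e)
}

#' Read a PPI network from a two-column edge-list file
#'
#' Plain text, whitespace/tab separated, two gene symbols per line; a third
#' numeric column (e.g. a STRING-style confidence score) is accepted and
#' ignored, as are blank lines and lines starting with `#`. Self-loop lines
#' are dropped with a warning; duplicate and reversed pairs collapse to a
#' single undirected edge.
#'
#' @param path path to the edge-list file.
#' @return a [PPINetwork-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("GENE1 GENE2", "GENE2 GENE3", "GENE2 GENE1"), tf)
#' readPPI(tf)
#' @export
readPPI <- function(path) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  ok <- lengths(fields) >= 2L
  if (any(!ok))
    stop("malformed PPI line(s) with fewer than two fields: ",
         paste(utils::head(which(!ok), 3), collapse = ", "))
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  net <- newPPINetwork(cbind(a, b))
  if (nrow(net@edges) == 0L)
    stop("empty network: no valid (non-self-loop) edges in ", path)
  net
}

#' Write a PPI network as a two-column edge list
#'
#' Inverse of [readPPI()]: re-reading the written file reproduces the same
#' node and edge set.
#'
#' @param ppi a [PPINetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePPI <- function(ppi, path) {
  stopifnot(is(ppi, "PPINetwork"))
  writeLines(paste(ppi@edges[, 1], ppi@edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a gene-expression table with a binary outcome column
#'
#' Expects a tab-separated table: first column sample id, one numeric column
#' per gene, plus the outcome column named by `labelColumn`. Outcomes may be
#' 0/1 already or any two distinct values; non-numeric outcome pairs are
#' mapped deterministically (lexicographically smaller value becomes class 0)
#' and the mapping is reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param labelColumn name of the outcome column.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `"expr"`
#'   (genes x samples) and `colData()$label` in \{0, 1\}.
#' @export
readExpression <- function(path, labelColumn = "label") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expression table needs a sample-id column, >= 1 gene column and the label column")
  sampleIds <- as.character(df[[1]])
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  if (!labelColumn %in% colnames(df)[-1])
    stop("label column '", labelColumn, "' not found")
  labRaw <- df[[labelColumn]]
  geneCols <- setdiff(colnames(df)[-1], labelColumn)
  if (anyDuplicated(geneCols))
    stop("duplicate gene columns: ",
         paste(unique(geneCols[duplicated(geneCols)]), collapse = ", "))
  mat <- as.matrix(df[, geneCols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- geneCols[!vapply(df[, geneCols, drop = FALSE], is.numeric, logical(1))]
    stop("non-numeric expression values in column(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  makeExpressionSE(t(mat), coerceLabels(labRaw), sampleIds = sampleIds,
                   genes = geneCols)
}

# map any two-valued outcome vector onto {0,1}; lexicographically smaller
# value -> 0 for non-numeric labels (deterministic, reported)
coerceLabels <- function(lab) {
  uniq <- sort(unique(as.character(lab)))
  if (length(uniq) > 2L)
    stop("outcome must be binary; found ", length(uniq), " distinct values")
  if (length(uniq) == 0L) stop("no outcome values")
  if (all(uniq %in% c("0", "1"))) return(as.integer(as.character(lab)))
  message("outcome mapping: '", uniq[1], "' -> 0",
          if (length(uniq) == 2L) paste0(", '", uniq[2], "' -> 1") else "")
  as.integer(match(as.character(lab), uniq) - 1L)
}

#' Assemble an expression SummarizedExperiment in memory
#'
#' @param values genes x samples numeric matrix.
#' @param labels integer vector in \{0, 1\}, one per sample.
#' @param sampleIds,genes dimension names (defaults taken from `values`).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `"expr"`.
#' @export
makeExpressionSE <- function(values, labels, sampleIds = colnames(values),
                             genes = rownames(values)) {
  values <- as.matrix(values)
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  dimnames(values) <- list(genes, sampleIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = sampleIds))
}

#' Restrict a PPI network to a gene subset
#'
#' @param ppi a [PPINetwork-class].
#' @param genes gene symbols to keep.
#' @return the induced [PPINetwork-class] (kept genes stay even if isolated).
#' @export
inducedNetwork <- function(ppi, genes) {
  stopifnot(is(ppi, "PPINetwork"))
  genes <- intersect(ppi@nodes, genes)
  e <- ppi@edges
  keep <- e[, 1] %in% genes & e[, 2] %in% genes
  new("PPINetwork", nodes = sort(genes),
      edges = e[keep, , drop = FALSE])
}

#' Build one attributed patient graph per sample
#'
#' Intersects the expression genes with the PPI nodes, induces the network on
#' the intersection and attaches each patient's expression values as node
#' features. Genes present in only one input are dropped and counted in a
#' `message()`. All patients share the identical topology and node order.
#'
#' @param expr expression data as returned by [readExpression()] or
#'   [makeExpressionSE()].
#' @param ppi a [PPINetwork-class].
#' @param zscore if `TRUE`, z-score each gene across samples before attaching
#'   features (off by default; the generator already emits standardized
#'   values).
#' @return a [PatientGraphSet-class].
#' @export
buildPatientGraphs <- function(expr, ppi, zscore = FALSE) {
  stopifnot(is(expr, "SummarizedExperiment"), is(ppi, "PPINetwork"))
  common <- intersect(rownames(expr), ppi@nodes)
  if (length(common) < 2L)
    stop("incompatible inputs: fewer than 2 genes shared between expression table and PPI network")
  dropExpr <- length(setdiff(rownames(expr), common))
  dropPPI <- length(setdiff(ppi@nodes, common))
  if (dropExpr + dropPPI > 0)
    message("gene intersection: ", length(common), " kept; dropped ",
            dropExpr, " expression-only and ", dropPPI, " PPI-only gene(s)")
  net <- inducedNetwork(ppi, common)
  mat <- SummarizedExperiment::assay(expr, "expr")[net@nodes, , drop = FALSE]
  if (zscore) {
    mu <- rowMeans(mat)
    sdev <- apply(mat, 1, stats::sd)
    sdev[sdev == 0] <- 1
    mat <- (mat - mu) / sdev
  }
  lab <- SummarizedExperiment::colData(expr)$label
  se <- makeExpressionSE(mat, lab)
  new("PatientGraphSet", se, ppi = net)
}

#' Stratified train/validation/test split
#'
#' Allocates split sizes per class by largest-remainder rounding (so the
#' sizes are the rounded allocations and always sum to `n`), shuffles within
#' class under the seed, and returns disjoint 1-based patient indices
#' covering `1..n`.
#'
#' @param labels integer vector in \{0, 1\}, one per patient (its length is
#'   the patient count `n`).
#' @param fractions three positive fractions for train, validation and test;
#'   must sum to 1 (tolerance 1e-9).
#' @param seed integer seed; identical seeds give identical splits.
#' @return a list with integer index vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(labels, fractions = c(train = 0.6, validation = 0.2,
                                               test = 0.2), seed = 1L) {
  n <- length(labels)
  if (n < 3L) stop("need at least 3 patients to split")
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be three positive values")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  splits <- list(train = integer(0), validation = integer(0),
                 test = integer(0))
  withSeed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      sizes <- largestRemainder(length(idx), fractions)
      splits$train <- c(splits$train, idx[seq_len(sizes[1])])
      splits$validation <- c(splits$validation,
                             idx[seq_len(sizes[2]) + sizes[1]])
      splits$test <- c(splits$test, idx[seq_len(sizes[3]) + sizes[1] + sizes[2]])
    }
  })
  lapply(splits, sort)
}

# integer allocation of n into round(n * fractions) summing exactly to n
largestRemainder <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Export a dataset split for audit
#'
#' Writes a two-column TSV of (sample_id, split).
#'
#' @param graphs a [PatientGraphSet-class].
#' @param split the list returned by [splitDataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSplits <- function(graphs, split, path) {
  ids <- colnames(graphs)
  rows <- do.call(rbind, lapply(names(split), function(s)
    data.frame(sample_id = ids[split[[s]]], split = s)))
  utils::write.table(rows[order(match(rows$sample_id, ids)), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
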