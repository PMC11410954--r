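test_that("one member is trained per subgraph, restricted to its genes", {
  graphs <- smallGraphs(shift = 3)
  ppi <- ppiNetwork(graphs)
  subs <- list(growFrom(ppi, "GA", 2), growFrom(ppi, "GB", 3),
               growFrom(ppi, "GC", 2))
  ens <- trainEnsemble(graphs, subs, fastConfig(), evalGraphs = graphs)
  expect_identical(memberCount(ens), 3L)
  for (k in 1:3) {
    m <- members(ens)[[k]]
    expect_identical(m@model@nodeOrder, nodeNames(subs[[k]]))
    expect_identical(nodeNames(m@subgraph), nodeNames(subs[[k]]))
    expect_s4_class(m@performance, "PerformanceReport")
    expect_identical(splitName(m@performance), "validation")
  }
})

test_that("the member holding the signal subnetwork scores best most of the time", {
  wins <- 0L
  for (seed in 1:8) {
    spec <- syntheticSpec(nGenes = 30L, nPatientsPerClass = 30L,
                          signalSize = 4L, seed = seed)
    ds <- generateDataset(spec)
    graphs <- buildPatientGraphs(ds$expr, ds$ppi)
    split <- splitDataset(unname(graphLabels(graphs)), seed = seed)
    background <- setdiff(nodeNames(ds$ppi), nodeNames(ds$signal))
    subs <- c(list(ds$signal),
              lapply(tail(background, 3), function(g)
                growFrom(ds$ppi, g, 4)))
    ens <- trainEnsemble(graphs[, split$train], subs,
                         gnnConfig(hiddenDim = 16L, epochs = 30L,
                                   seed = seed),
                         evalGraphs = graphs[, split$validation])
    bal <- vapply(members(ens), function(m)
      unname(perfMetrics(m@performance)["balanced_accuracy"]), numeric(1))
    if (which.max(bal) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("vote tallying follows the stated weighted-majority rule", {
  expect_identical(tallyVotes(c(1L, 1L, 0L), c(1, 1, 1)), 1L)
  expect_identical(tallyVotes(c(1L, 1L, 0L), c(0, 0, 5)), 0L)
  expect_identical(tallyVotes(c(1L, 0L), c(1, 1)), 0L)  # exact tie -> 0
  expect_error(tallyVotes(c(1L, 0L), c(1, 1, 1)), "length")
  expect_error(tallyVotes(c(1L, 0L), c(1, -1)), ">= 0")
})

test_that("vote tallying matches brute-force enumeration and its invariances", {
  set.seed(7)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (r in 1:40) {
    w <- round(runif(4, 0, 5), 2)
    for (p in seq_len(nrow(patterns))) {
      v <- patterns[p, ]
      got <- tallyVotes(v, w)
      expect_identical(got, bruteVote(v, w))
      # positive rescaling never changes the prediction
      expect_identical(tallyVotes(v, w * runif(1, 0.1, 9)), got)
    }
  }
  # all-equal positive weights reproduce the unweighted majority
  for (r in 1:50) {
    v <- sample(0:1, 5, replace = TRUE)
    c0 <- runif(1, 0.1, 10)
    maj <- if (sum(v) > 2.5) 1L else 0L
    expect_identical(tallyVotes(v, rep(c0, 5)), maj)
  }
  # raising a member's weight never flips the outcome away from its vote
  for (r in 1:50) {
    v <- sample(0:1, 4, replace = TRUE)
    w <- runif(4, 0, 3)
    i <- sample(4, 1)
    before <- tallyVotes(v, w)
    w2 <- w
    w2[i] <- w[i] + runif(1, 0, 5)
    after <- tallyVotes(v, w2)
    if (after != before) expect_identical(after, as.integer(v[i]))
  }
})

test_that("evaluation reports satisfy the confusion-count identities", {
  truth <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  pred <- c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L)  # tp 3, fn 1, fp 2, tn 2
  rep_ <- performanceReport(truth, pred, "test")
  m <- perfMetrics(rep_)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 0.5)
  expect_equal(unname(m["balanced_accuracy"]), 0.625)
  expect_equal(unname(m["accuracy"]), 5 / 8)
  cc <- confusionCounts(rep_)
  expect_equal(unname(m["accuracy"]),
               unname((cc["tp"] + cc["tn"]) / sum(cc)))
})

test_that("weighting down wrong members can only help on a fixed vote table", {
  # 2 faithful members, 2 inverted ones
  truth <- rep(c(0L, 1L), each = 10)
  votes <- rbind(truth, truth, 1L - truth, 1L - truth)
  acc <- function(w) mean(tallyVotes(votes, w) == truth)
  expect_gte(acc(c(1, 1, 0, 0)), acc(c(1, 1, 1, 1)))
  expect_equal(acc(c(1, 1, 0, 0)), 1)
})

test_that("a strong ensemble under neutral weights is perfect on its input", {
  graphs <- smallGraphs(shift = 5, nPerClass = 8L)
  ppi <- ppiNetwork(graphs)
  subs <- list(growFrom(ppi, "GB", 3), growFrom(ppi, "GC", 3))
  ens <- trainEnsemble(graphs, subs,
                       gnnConfig(hiddenDim = 16L, epochs = 60L, seed = 3L),
                       evalGraphs = graphs)
  rep_ <- evaluateEnsemble(ens, graphs, splitName = "train")
  expect_equal(unname(perfMetrics(rep_)["accuracy"]), 1)
  expect_error(evaluateEnsemble(ens, graphs[, integer(0)]), "empty")
})

test_that("detached payloads drop patient data and round-trip exactly", {
  graphs <- smallGraphs(shift = 3)
  ppi <- ppiNetwork(graphs)
  subs <- list(growFrom(ppi, "GB", 3), growFrom(ppi, "GD", 2))
  ens <- trainEnsemble(graphs, subs, fastConfig(), evalGraphs = graphs)
  payload <- detachData(ens)
  txt <- payloadText(payload)

  # no sample identifier, expression value or label vector in the payload
  for (sid in colnames(graphs)) expect_false(grepl(sid, txt, fixed = TRUE))
  vals <- as.vector(assay(graphs, "expr"))[1:20]
  for (v in vals) {
    expect_false(grepl(format(v, digits = 10), txt, fixed = TRUE))
  }
  expect_false(grepl("label", txt, fixed = TRUE))

  # detach -> serialize -> re-read -> attach reproduces the predictions
  tf <- withr::local_tempfile()
  writeEnsemblePayload(payload, tf)
  back <- attachEnsemble(readEnsemblePayload(tf))
  expect_identical(weightedVote(back, graphs), weightedVote(ens, graphs))
  expect_identical(memberProvenance(back), memberProvenance(ens))
  perf <- members(back)[[1]]@performance
  expect_equal(perfMetrics(perf), perfMetrics(members(ens)[[1]]@performance))
})

test_that("payload size does not depend on the cohort size", {
  ppi <- generatePPI(syntheticSpec(nGenes = 15L, seed = 2L))
  mkPayload <- function(nPerClass) {
    spec <- syntheticSpec(nGenes = 15L, nPatientsPerClass = nPerClass,
                          signalSize = 3L, seed = 2L)
    sig <- plantSignal(ppi, spec)
    graphs <- buildPatientGraphs(generateCohort(ppi, sig, spec), ppi)
    subs <- list(growFrom(ppi, nodeNames(ppi)[1], 3),
                 growFrom(ppi, nodeNames(ppi)[5], 3))
    ens <- trainEnsemble(graphs, subs, fastConfig(), evalGraphs = graphs)
    payloadText(detachData(ens))
  }
  expect_identical(nchar(mkPayload(10L)), nchar(mkPayload(100L)))
})
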