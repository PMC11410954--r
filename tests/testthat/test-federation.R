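test_that("the protocol enumerates its states with the documented role map", {
  states <- federationStates()
  expect_length(states, 10L)
  expect_identical(sort(states), sort(c(
    "INITIAL", "LOCAL_TRAINING", "GLOBAL_MODEL_AGGREGATION",
    "WAITING_FOR_GLOBAL_MODEL", "WEB_CONTROLLED", "DISTRIBUTE_WEIGHTS",
    "WAITING_FOR_CLIENTS_TO_FINISH", "GLOBAL_WEIGHT_AGGREGATION",
    "WAITING_FOR_GLOBAL_WEIGHTS", "TERMINAL")))
  # shared, coordinator-only and client-only states partition the machine
  expect_identical(intersect(roleStates("coordinator"), roleStates("client")),
                   c("INITIAL", "TERMINAL"))
  expect_setequal(union(roleStates("coordinator"), roleStates("client")),
                  states)
  expect_setequal(setdiff(states, roleStates("client")),
                  c("GLOBAL_MODEL_AGGREGATION", "WAITING_FOR_CLIENTS_TO_FINISH",
                    "GLOBAL_WEIGHT_AGGREGATION"))
})

test_that("single transitions follow the workflow diagram", {
  expect_identical(federationStep("INITIAL", "coordinator", "start"),
                   "GLOBAL_MODEL_AGGREGATION")
  expect_identical(federationStep("INITIAL", "client", "start"),
                   "LOCAL_TRAINING")
  expect_identical(federationStep("LOCAL_TRAINING", "client", "payload_sent"),
                   "WAITING_FOR_GLOBAL_MODEL")
  # without the UI-mode flag the workflow is complete on model receipt
  expect_identical(federationStep("WAITING_FOR_GLOBAL_MODEL", "client",
                                  "model_received", interactive = FALSE),
                   "TERMINAL")
  expect_identical(federationStep("WAITING_FOR_GLOBAL_MODEL", "client",
                                  "model_received", interactive = TRUE),
                   "WEB_CONTROLLED")
  expect_identical(federationStep("WAITING_FOR_GLOBAL_WEIGHTS", "client",
                                  "weights_received"),
                   "WEB_CONTROLLED")
  expect_identical(federationStep("WEB_CONTROLLED", "client", "terminate"),
                   "TERMINAL")
  expect_identical(federationStep("WAITING_FOR_CLIENTS_TO_FINISH",
                                  "coordinator", "all_clients_terminated"),
                   "TERMINAL")

  # roles may not occupy each other's states
  expect_error(federationStep("LOCAL_TRAINING", "coordinator", "start"),
               "may not occupy")
  expect_error(federationStep("GLOBAL_WEIGHT_AGGREGATION", "client",
                              "weights_broadcast"), "may not occupy")
  # one-shot rule: no second submission while one is in flight
  expect_error(federationStep("WAITING_FOR_GLOBAL_WEIGHTS", "client",
                              "submit_weights"), "illegal transition")
  expect_error(federationStep("WEB_CONTROLLED", "client", "start"),
               "illegal transition")
  expect_error(federationStep("NOT_A_STATE", "client", "start"),
               "unknown state")
})

test_that("random-walk fuzzing stays inside legal (state, role) territory", {
  legal <- list(
    coordinator = list(
      INITIAL = "start",
      GLOBAL_MODEL_AGGREGATION = "model_broadcast",
      WAITING_FOR_CLIENTS_TO_FINISH = c("weights_received",
                                        "all_clients_terminated"),
      GLOBAL_WEIGHT_AGGREGATION = "weights_broadcast"),
    client = list(
      INITIAL = "start",
      LOCAL_TRAINING = "payload_sent",
      WAITING_FOR_GLOBAL_MODEL = "model_received",
      WEB_CONTROLLED = c("submit_weights", "terminate"),
      DISTRIBUTE_WEIGHTS = "weights_sent",
      WAITING_FOR_GLOBAL_WEIGHTS = "weights_received"))
  allEvents <- unique(unlist(legal))
  set.seed(20)
  for (role in c("coordinator", "client")) {
    for (walk in 1:30) {
      state <- "INITIAL"
      while (state != "TERMINAL") {
        expect_true(state %in% roleStates(role))
        ev <- sample(legal[[role]][[state]], 1)
        state <- federationStep(state, role, ev,
                                interactive = sample(c(TRUE, FALSE), 1))
      }
      expect_identical(state, "TERMINAL")
    }
    # anything off the table raises
    for (i in 1:60) {
      state <- sample(roleStates(role), 1)
      ev <- sample(allEvents, 1)
      ok <- state != "TERMINAL" && ev %in% legal[[role]][[state]]
      if (!ok) expect_error(federationStep(state, role, ev))
    }
  }
})

test_that("weight aggregation pads with 1 and averages elementwise", {
  expect_identical(aggregateWeights(list(c(2, 0, 1), c(0, 0, 1)), 3),
                   c(1, 0, 1))
  expect_identical(aggregateWeights(list(2, c(0, 4)), 2), c(1, 2.5))
  expect_identical(aggregateWeights(list(c(3, 3)), 2), c(3, 3))

  # aggregating k identical lists returns the list
  set.seed(4)
  for (r in 1:20) {
    w <- runif(sample(1:6, 1), 0, 4)
    k <- sample(1:5, 1)
    expect_equal(aggregateWeights(rep(list(w), k), length(w)), w)
  }

  expect_error(aggregateWeights(list(), 3), "protocol error")
  expect_error(aggregateWeights(list(c(1, -2)), 2), ">= 0")
  expect_error(aggregateWeights(list(c(1, 1, 1)), 2), "longer")
})

test_that("model aggregation concatenates members in client order", {
  graphs <- smallGraphs(shift = 3)
  ppi <- ppiNetwork(graphs)
  subs <- list(growFrom(ppi, "GA", 2), growFrom(ppi, "GB", 3),
               growFrom(ppi, "GC", 2))
  ens <- trainEnsemble(graphs, subs, fastConfig(), evalGraphs = graphs)
  p <- detachData(ens)

  global <- aggregateModels(list(A = p, B = p))
  expect_identical(memberCount(global), 6L)
  expect_identical(memberProvenance(global), rep(c("A", "B"), each = 3))

  # one client: the global model is that client's ensemble
  solo <- aggregateModels(list(A = p))
  expect_identical(weightedVote(solo, graphs), weightedVote(ens, graphs))

  # order matters for indices, not for the member multiset
  ba <- aggregateModels(list(A = p, B = p), clientOrder = c("B", "A"))
  expect_identical(memberProvenance(ba), rep(c("B", "A"), each = 3))
  expect_setequal(vapply(members(ba), function(m)
    paste(nodeNames(m@subgraph), collapse = ","), character(1)),
    vapply(members(global), function(m)
      paste(nodeNames(m@subgraph), collapse = ","), character(1)))

  expect_error(aggregateModels(list(A = p), clientOrder = c("A", "B")),
               "protocol error")
})

# a small two-client dataset for protocol-level simulations
protoClients <- function(seed = 21L, nGenes = 16L, nPerClass = 12L) {
  spec <- syntheticSpec(nGenes = nGenes, nPatientsPerClass = nPerClass,
                        signalSize = 3L, effectSize = 3, seed = seed)
  ds <- generateDataset(spec)
  graphs <- buildPatientGraphs(ds$expr, ds$ppi)
  lab <- graphLabels(graphs)
  i0 <- which(lab == 0L)
  i1 <- which(lab == 1L)
  h <- nPerClass %/% 2L
  list(graphs = graphs,
       clients = list(
         siteA = graphs[, sort(c(i0[1:h], i1[1:h]))],
         siteB = graphs[, sort(c(i0[(h + 1):nPerClass],
                                 i1[(h + 1):nPerClass]))]))
}

test_that("a batch run concatenates, broadcasts and terminates cleanly", {
  pc <- protoClients()
  res <- runFederation(pc$clients, fastConfig(), nMembers = 3L,
                       memberSize = 3L, seed = 8L)

  # member-count conservation and provenance
  expect_identical(memberCount(res@globalModel), 6L)
  expect_identical(unique(memberProvenance(res@globalModel)),
                   c("siteA", "siteB"))

  # every client holds local and global reports on its own two eval splits
  for (cid in c("siteA", "siteB")) {
    r <- res@perClientReports[[cid]]
    expect_named(r, c("local_validation", "local_test",
                      "global_validation", "global_test"))
    expect_identical(splitName(r$global_validation), "validation")
    expect_identical(splitName(r$global_test), "test")
  }

  # an identical global model copy went to every client
  gm <- Filter(function(m) m$kind == "global_model", res@messages)
  expect_length(gm, 2L)
  expect_identical(gm[[1]]$payload, gm[[2]]$payload)

  # transcripts start at INITIAL and end at TERMINAL for all participants
  for (p in unique(res@transcript$participant)) {
    tr <- res@transcript[res@transcript$participant == p, ]
    expect_identical(tr$from[1], "INITIAL")
    expect_identical(tail(tr$to, 1), "TERMINAL")
  }

  # message directions: payloads up, broadcasts down
  for (m in res@messages) {
    if (m$kind %in% c("ensemble_payload", "weight_vector", "terminate"))
      expect_identical(m$recipient, "coordinator")
    if (m$kind %in% c("global_model", "global_weights"))
      expect_identical(m$sender, "coordinator")
  }
})

test_that("interactive rounds aggregate weights and re-score on validation", {
  pc <- protoClients(seed = 22L)
  res <- runFederation(pc$clients, fastConfig(), nMembers = 3L,
                       memberSize = 3L, interactive = TRUE,
                       scriptedActions = list(
                         siteA = list(list(type = "weights",
                                           weights = c(2, 0, 1)),
                                      list(type = "terminate")),
                         siteB = list(list(type = "weights",
                                           weights = c(0, 0, 1, 1)),
                                      list(type = "terminate"))),
                       seed = 9L)
  # pad to 6 with ones, then elementwise mean
  expect_equal(res@aggregatedWeights, c(1, 0, 1, 1, 1, 1))
  expect_length(res@interactiveEvaluations, 2L)
  for (ev in res@interactiveEvaluations)
    expect_identical(splitName(ev$report), "validation")
  # all-ones submissions broadcast all ones
  res1 <- runFederation(pc$clients, fastConfig(), nMembers = 3L,
                        memberSize = 3L, interactive = TRUE,
                        scriptedActions = list(
                          siteA = list(list(type = "weights",
                                            weights = rep(1, 6)),
                                       list(type = "terminate")),
                          siteB = list(list(type = "weights",
                                            weights = rep(1, 6)),
                                       list(type = "terminate"))),
                        seed = 9L)
  expect_identical(res1@aggregatedWeights, rep(1, 6))
})

test_that("an immediate scripted terminate shuts the coordinator down", {
  pc <- protoClients(seed = 23L)
  res <- runFederation(pc$clients["siteA"], fastConfig(), nMembers = 2L,
                       memberSize = 3L, interactive = TRUE,
                       scriptedActions = list(
                         siteA = list(list(type = "terminate"))),
                       seed = 10L)
  coordTr <- res@transcript[res@transcript$participant == "coordinator", ]
  expect_identical(tail(coordTr$to, 1), "TERMINAL")
  expect_null(res@aggregatedWeights)
})

test_that("scripting errors are caught: deadlock and mid-round terminate", {
  pc <- protoClients(seed = 24L)
  # siteB runs out of actions while siteA keeps submitting
  err <- tryCatch(
    runFederation(pc$clients, fastConfig(), nMembers = 2L, memberSize = 3L,
                  interactive = TRUE,
                  scriptedActions = list(
                    siteA = list(list(type = "weights", weights = c(1, 1)),
                                 list(type = "terminate")),
                    siteB = list()),
                  seed = 11L),
    fedgnnDeadlock = identity)
  expect_s3_class(err, "fedgnnDeadlock")
  expect_true(is.data.frame(err$transcript))

  # terminating while a weight round is in flight is rejected
  expect_error(
    runFederation(pc$clients, fastConfig(), nMembers = 2L, memberSize = 3L,
                  interactive = TRUE,
                  scriptedActions = list(
                    siteA = list(list(type = "weights", weights = c(1, 1)),
                                 list(type = "terminate")),
                    siteB = list(list(type = "terminate"))),
                  seed = 11L),
    class = "fedgnnDeadlock")
})

test_that("no federation message ever carries patient-level data", {
  pc <- protoClients(seed = 25L)
  res <- runFederation(pc$clients, fastConfig(), nMembers = 3L,
                       memberSize = 3L, interactive = TRUE,
                       scriptedActions = list(
                         siteA = list(list(type = "weights",
                                           weights = c(5, 0, 1)),
                                      list(type = "terminate")),
                         siteB = list(list(type = "weights",
                                           weights = c(1, 1, 1)),
                                      list(type = "terminate"))),
                       seed = 12L)
  blob <- paste(messagePayloadStrings(res), collapse = "\n")
  for (sid in colnames(pc$graphs))
    expect_false(grepl(sid, blob, fixed = TRUE))
  expect_false(grepl("label", blob, fixed = TRUE))
  vals <- as.vector(assay(pc$graphs, "expr"))
  for (v in vals[seq(1, length(vals), by = 17)])
    expect_false(grepl(format(v, digits = 10), blob, fixed = TRUE))
})

test_that("the federated global model is no worse than local models alone", {
  drops <- numeric(0)
  for (seed in 1:10) {
    run <- fedVsLocalRun(seed)
    drops <- c(drops, mean(run$globalTest) - run$localTest)
  }
  expect_true(all(drops >= -0.05))
})
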