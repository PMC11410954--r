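#' @include AllClasses.R ensemble.R
NULL

# state names of the coordinator/client protocol
.FED_STATES <- c("INITIAL", "LOCAL_TRAINING", "GLOBAL_MODEL_AGGREGATION",
                 "WAITING_FOR_GLOBAL_MODEL", "WEB_CONTROLLED",
                 "DISTRIBUTE_WEIGHTS", "WAITING_FOR_CLIENTS_TO_FINISH",
                 "GLOBAL_WEIGHT_AGGREGATION", "WAITING_FOR_GLOBAL_WEIGHTS",
                 "TERMINAL")

.COORDINATOR_STATES <- c("INITIAL", "GLOBAL_MODEL_AGGREGATION",
                         "WAITING_FOR_CLIENTS_TO_FINISH",
                         "GLOBAL_WEIGHT_AGGREGATION", "TERMINAL")

.CLIENT_STATES <- c("INITIAL", "LOCAL_TRAINING", "WAITING_FOR_GLOBAL_MODEL",
                    "WEB_CONTROLLED", "DISTRIBUTE_WEIGHTS",
                    "WAITING_FOR_GLOBAL_WEIGHTS", "TERMINAL")

#' Protocol states of the federated workflow
#'
#' The coordinator/client workflow is a state machine; `federationStates()`
#' enumerates every state and `roleStates()` the subset a role may occupy
#' (initial and terminal states are shared; the model/weight aggregation and
#' client-waiting states are coordinator-only; training, waiting-for-model,
#' web-controlled, distribute-weights and waiting-for-weights are
#' client-only).
#'
#' @param role `"coordinator"` or `"client"`.
#' @return character vector of state names.
#' @export
federationStates <- function() .FED_STATES

#' @rdname federationStates
#' @export
roleStates <- function(role = c("coordinator", "client")) {
  role <- match.arg(role)
  if (role == "coordinator") .COORDINATOR_STATES else .CLIENT_STATES
}

illegalTransition <- function(current, role, event) {
  stop("illegal transition: no event '", event, "' for role '", role,
       "' in state '", current, "'")
}

#' Advance the protocol state machine by one event
#'
#' Pure transition function of the coordinator/client workflow. Coordinator
#' path: INITIAL -> GLOBAL_MODEL_AGGREGATION (start) ->
#' WAITING_FOR_CLIENTS_TO_FINISH (model_broadcast), then either
#' GLOBAL_WEIGHT_AGGREGATION (weights_received) ->
#' WAITING_FOR_CLIENTS_TO_FINISH (weights_broadcast) cycles, or TERMINAL
#' once the active-client count reaches zero (all_clients_terminated).
#' Client path: INITIAL -> LOCAL_TRAINING (start) ->
#' WAITING_FOR_GLOBAL_MODEL (payload_sent); on model_received the client
#' terminates when the interactive (UI-mode) flag is unset, otherwise enters
#' WEB_CONTROLLED, from which submit_weights leads through
#' DISTRIBUTE_WEIGHTS (weights_sent) to WAITING_FOR_GLOBAL_WEIGHTS and, on
#' weights_received, back to WEB_CONTROLLED; terminate ends the client.
#' Any other (state, role, event) combination is an error, including a
#' second weight submission while one is already in flight.
#'
#' @param current a state name from [federationStates()].
#' @param role `"coordinator"` or `"client"`.
#' @param event a protocol event name (see Details above).
#' @param interactive UI-mode flag consulted for `model_received`.
#' @return the next state name.
#' @export
federationStep <- function(current, role = c("coordinator", "client"),
                           event, interactive = FALSE) {
  role <- match.arg(role)
  if (!current %in% .FED_STATES) stop("unknown state: ", current)
  if (!current %in% roleStates(role))
    stop("role '", role, "' may not occupy state '", current, "'")
  if (role == "coordinator") {
    if (current == "INITIAL" && event == "start")
      return("GLOBAL_MODEL_AGGREGATION")
    if (current == "GLOBAL_MODEL_AGGREGATION" && event == "model_broadcast")
      return("WAITING_FOR_CLIENTS_TO_FINISH")
    if (current == "WAITING_FOR_CLIENTS_TO_FINISH") {
      if (event == "weights_received") return("GLOBAL_WEIGHT_AGGREGATION")
      if (event == "all_clients_terminated") return("TERMINAL")
    }
    if (current == "GLOBAL_WEIGHT_AGGREGATION" && event == "weights_broadcast")
      return("WAITING_FOR_CLIENTS_TO_FINISH")
  } else {
    if (current == "INITIAL" && event == "start") return("LOCAL_TRAINING")
    if (current == "LOCAL_TRAINING" && event == "payload_sent")
      return("WAITING_FOR_GLOBAL_MODEL")
    if (current == "WAITING_FOR_GLOBAL_MODEL" && event == "model_received")
      return(if (interactive) "WEB_CONTROLLED" else "TERMINAL")
    if (current == "WEB_CONTROLLED") {
      if (event == "submit_weights") return("DISTRIBUTE_WEIGHTS")
      if (event == "terminate") return("TERMINAL")
    }
    if (current == "DISTRIBUTE_WEIGHTS" && event == "weights_sent")
      return("WAITING_FOR_GLOBAL_WEIGHTS")
    if (current == "WAITING_FOR_GLOBAL_WEIGHTS" && event == "weights_received")
      return("WEB_CONTROLLED")
  }
  illegalTransition(current, role, event)
}

#' Concatenate detached client ensembles into the global model
#'
#' Members are appended in client order, preserving each client's internal
#' member order, so a weight index refers to the same member everywhere.
#' Provenance records the source client of every member.
#'
#' @param payloads named list of detached payloads ([detachData()]), one per
#'   client.
#' @param clientOrder character vector of client ids in registration order;
#'   a registered client without a payload is a protocol error (aggregation
#'   is never silently partial).
#' @return the global [EnsembleClassifier-class].
#' @export
aggregateModels <- function(payloads, clientOrder = names(payloads)) {
  if (length(payloads) < 1L) stop("protocol error: no client payloads")
  missing <- setdiff(clientOrder, names(payloads))
  if (length(missing))
    stop("protocol error: missing payload from client(s): ",
         paste(missing, collapse = ", "))
  mem <- list()
  prov <- character(0)
  for (cid in clientOrder) {
    ens <- attachEnsemble(payloads[[cid]])
    mem <- c(mem, members(ens))
    prov <- c(prov, rep(cid, memberCount(ens)))
  }
  new("EnsembleClassifier", members = mem, provenance = prov)
}

#' Average per-client vote-weight lists elementwise
#'
#' A list with missing values (shorter than the global member count) is
#' padded with the neutral weight 1; the aggregate at index `j` is the
#' arithmetic mean of all clients' values at `j`. A list longer than the
#' global member count is a validation error, as is any negative weight.
#'
#' @param weightLists list of numeric vectors, one per contributing client.
#' @param targetLength the global model's member count.
#' @return numeric vector of length `targetLength`.
#' @examples
#' aggregateWeights(list(c(2, 0, 1), c(0, 0, 1)), 3)  # 1 0 1
#' aggregateWeights(list(2, c(0, 4)), 2)              # 1 2.5
#' @export
aggregateWeights <- function(weightLists, targetLength) {
  if (length(weightLists) < 1L)
    stop("protocol error: no weight configurations to aggregate")
  targetLength <- as.integer(targetLength)
  padded <- lapply(weightLists, function(w) {
    w <- as.numeric(w)
    if (any(!is.finite(w)) || any(w < 0))
      stop("vote weights must be finite and >= 0")
    if (length(w) > targetLength)
      stop("weight configuration longer (", length(w),
           ") than the global member count (", targetLength, ")")
    c(w, rep(1, targetLength - length(w)))
  })
  rowMeans(do.call(cbind, padded))
}

# condition signalled when a scripted interactive run cannot proceed; the
# protocol transcript so far is attached for debugging
deadlockError <- function(message, transcript) {
  stop(structure(class = c("fedgnnDeadlock", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      transcript = transcript)))
}

#' Simulate the full federated workflow in-process
#'
#' Runs the coordinator and all clients of the protocol in one R process:
#' each client splits its data, trains a local GNN, extracts
#' importance-based subgraphs, trains its local ensemble, detaches it from
#' the patient data and sends the payload to the coordinator; the
#' coordinator concatenates all local ensembles into the global model and
#' broadcasts an identical copy to every client, which scores it on its own
#' validation and test splits. With `interactive = TRUE` the run continues
#' with scripted expert actions: in each round every active client either
#' submits a vote-weight list (aggregated elementwise by the coordinator,
#' broadcast back, and re-scored on the client's validation split only) or
#' terminates; a terminate while an aggregation round is in flight is
#' rejected, and an active client left without a next scripted action
#' raises a deadlock error with the transcript attached. The coordinator
#' holds no dataset and does no local training.
#'
#' @param clientGraphs named list of [PatientGraphSet-class], one per client
#'   (names are the client ids, in registration order).
#' @param config a [GNNConfig-class]; each client trains with a
#'   client-specific seed derived from `seed`.
#' @param nMembers,memberSize subgraph extraction parameters (capped at the
#'   node count).
#' @param fractions train/validation/test fractions for [splitDataset()].
#' @param interactive the UI-mode flag: `FALSE` runs fully batch.
#' @param scriptedActions named list (per client) of ordered actions, each
#'   `list(type = "weights", weights = <numeric>)` or
#'   `list(type = "terminate")`. Required when `interactive = TRUE`.
#' @param seed master seed for splits and training.
#' @return a [FederationResult-class].
#' @export
runFederation <- function(clientGraphs, config = gnnConfig(),
                          nMembers = 10L, memberSize = 5L,
                          fractions = c(train = 0.6, validation = 0.2,
                                        test = 0.2),
                          interactive = FALSE, scriptedActions = NULL,
                          seed = 1L) {
  if (length(clientGraphs) < 1L) stop("need at least one client")
  if (is.null(names(clientGraphs)) || anyDuplicated(names(clientGraphs)))
    stop("clientGraphs must be a uniquely named list")
  clients <- names(clientGraphs)
  rec <- new.env(parent = emptyenv())
  rec$transcript <- list()
  rec$messages <- list()
  rec$interactive <- list()
  state <- new.env(parent = emptyenv())
  logStep <- function(participant, role, event, flag = FALSE) {
    from <- state[[participant]]
    to <- federationStep(from, role, event, interactive = flag)
    rec$transcript[[length(rec$transcript) + 1L]] <-
      data.frame(participant = participant, from = from, to = to,
                 event = event, stringsAsFactors = FALSE)
    state[[participant]] <- to
    to
  }
  send <- function(sender, recipient, kind, payload) {
    rec$messages[[length(rec$messages) + 1L]] <-
      list(sender = sender, recipient = recipient, kind = kind,
           payload = payload)
  }
  transcriptDF <- function() do.call(rbind, rec$transcript)

  # State 1: coordinator stores the client count and starts aggregating
  state[["coordinator"]] <- "INITIAL"
  activeClients <- clients
  logStep("coordinator", "coordinator", "start")

  # State 2: local training per client, then detachment and upload
  payloads <- list()
  reports <- stats::setNames(vector("list", length(clients)), clients)
  splits <- list()
  graphsets <- clientGraphs
  for (k in seq_along(clients)) {
    cid <- clients[k]
    state[[cid]] <- "INITIAL"
    logStep(cid, "client", "start")
    pgs <- graphsets[[cid]]
    clientSeed <- as.integer(seed) + k
    cfg <- config
    cfg@seed <- clientSeed
    pipe <- trainLocalEnsemble(pgs, cfg, nMembers = nMembers,
                               memberSize = memberSize,
                               fractions = fractions, seed = clientSeed)
    splits[[cid]] <- pipe$split
    local <- pipe$ensemble
    local@provenance <- rep(cid, memberCount(local))
    reports[[cid]] <- pipe$reports
    payload <- detachData(local)
    payloads[[cid]] <- payload
    send(cid, "coordinator", "ensemble_payload", payloadText(payload))
    logStep(cid, "client", "payload_sent")
  }

  # State 3: concatenation and broadcast of the global model
  globalModel <- aggregateModels(payloads, clientOrder = clients)
  globalPayload <- detachData(globalModel)
  globalText <- payloadText(globalPayload)
  for (cid in clients) send("coordinator", cid, "global_model", globalText)
  logStep("coordinator", "coordinator", "model_broadcast")

  # State 4: every client scores its copy of the global model locally
  received <- list()
  for (cid in clients) {
    gm <- attachEnsemble(readPayloadString(globalText))
    received[[cid]] <- gm
    split <- splits[[cid]]
    pgs <- graphsets[[cid]]
    reports[[cid]]$global_validation <-
      evaluateEnsemble(gm, pgs[, split$validation], splitName = "validation")
    reports[[cid]]$global_test <-
      evaluateEnsemble(gm, pgs[, split$test], splitName = "test")
    logStep(cid, "client", "model_received", flag = interactive)
    if (!interactive) {
      send(cid, "coordinator", "terminate", NULL)
      activeClients <- setdiff(activeClients, cid)
    }
  }

  # States 5-9: scripted expert interaction rounds
  aggregated <- NULL
  if (interactive) {
    queues <- lapply(stats::setNames(clients, clients), function(cid) {
      q <- scriptedActions[[cid]]
      if (is.null(q)) list() else q
    })
    cursor <- stats::setNames(rep(1L, length(clients)), clients)
    round <- 0L
    while (length(activeClients) > 0L) {
      round <- round + 1L
      roundOpen <- FALSE
      submitted <- list()
      for (cid in intersect(clients, activeClients)) {
        q <- queues[[cid]]
        if (cursor[cid] > length(q))
          deadlockError(paste0("deadlock: active client '", cid,
                               "' has no next scripted action"),
                        transcriptDF())
        action <- q[[cursor[cid]]]
        cursor[cid] <- cursor[cid] + 1L
        if (identical(action$type, "weights")) {
          roundOpen <- TRUE
          logStep(cid, "client", "submit_weights")
          w <- as.numeric(action$weights)
          if (any(!is.finite(w)) || any(w < 0))
            stop("vote weights must be finite and >= 0")
          if (length(w) > memberCount(globalModel))
            stop("weight configuration longer (", length(w),
                 ") than the global member count (",
                 memberCount(globalModel), ")")
          send(cid, "coordinator", "weight_vector", w)
          logStep(cid, "client", "weights_sent")
          submitted[[cid]] <- w
        } else if (identical(action$type, "terminate")) {
          if (roundOpen)
            deadlockError(paste0("client '", cid, "' scripted a terminate ",
                                 "while a weight-aggregation round is in ",
                                 "flight; rejected"),
                          transcriptDF())
          logStep(cid, "client", "terminate")
          send(cid, "coordinator", "terminate", NULL)
          activeClients <- setdiff(activeClients, cid)
        } else {
          stop("unknown scripted action type: ", action$type)
        }
      }
      if (roundOpen) {
        # States 7/8: coordinator collects, pads, averages and broadcasts
        logStep("coordinator", "coordinator", "weights_received")
        aggregated <- aggregateWeights(unname(submitted),
                                       memberCount(globalModel))
        for (cid in intersect(clients, activeClients))
          send("coordinator", cid, "global_weights", aggregated)
        logStep("coordinator", "coordinator", "weights_broadcast")
        # State 9 then back to 5: re-score on the validation split only
        for (cid in intersect(clients, activeClients)) {
          logStep(cid, "client", "weights_received")
          split <- splits[[cid]]
          rep_ <- evaluateEnsemble(received[[cid]],
                                   graphsets[[cid]][, split$validation],
                                   weights = aggregated,
                                   splitName = "validation")
          rec$interactive[[length(rec$interactive) + 1L]] <-
            list(client = cid, round = round, weights = aggregated,
                 report = rep_)
        }
      }
    }
  }

  # State 7 end: no clients active any more, the coordinator terminates
  logStep("coordinator", "coordinator", "all_clients_terminated")

  new("FederationResult", globalModel = globalModel,
      perClientReports = reports, aggregatedWeights = aggregated,
      transcript = transcriptDF(), messages = rec$messages,
      interactiveEvaluations = rec$interactive)
}

# parse a payload back from its canonical JSON text
readPayloadString <- function(txt) {
  jsonlite::fromJSON(txt, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Serialized form of every cross-participant message payload
#'
#' Used to audit data locality: scan the returned strings for sample ids,
#' labels or expression values — none may ever appear in federation traffic.
#'
#' @param result a [FederationResult-class].
#' @return character vector, one serialized payload per message (empty
#'   string for payload-free messages such as terminate notifications).
#' @export
messagePayloadStrings <- function(result) {
  vapply(result@messages, function(m) {
    p <- m$payload
    if (is.null(p)) "" else if (is.character(p)) paste(p, collapse = "\n")
    else paste(deparse(p), collapse = "\n")
  }, character(1))
}
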