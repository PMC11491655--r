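#' Training protocol
#'
#' Shared hyperparameters of the three training engines. Defaults follow
#' the simulated study: at most 200 rounds (federated), cycles (traveling
#' model) or epochs (centralized) with early stopping after 10 without
#' validation improvement; 32 clients sampled per federated round; one
#' local Adam step on the client's two-record batch per visit; centralized
#' minibatches of 64; Adam with learning rate 5e-3 and weight decay 1e-4.
#'
#' @param max_rounds maximum rounds/cycles/epochs.
#' @param patience early-stopping patience in rounds/cycles/epochs.
#' @param fl_clients_per_round clients sampled per federated round.
#' @param local_epochs Adam steps a client performs per visit.
#' @param batch_size centralized minibatch size.
#' @param lr,weight_decay Adam hyperparameters (see [adam_init()]).
#' @param carry_state if `TRUE` the traveling model carries its Adam
#'   moments from client to client; by default every visit starts from a
#'   fresh state, matching a network that transfers model parameters only.
#' @param seed integer seed for client sampling, visiting order and
#'   minibatch shuffling.
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(max_rounds = 200, patience = 10,
                              fl_clients_per_round = 32, local_epochs = 1,
                              batch_size = 64, lr = 5e-3,
                              weight_decay = 1e-4, carry_state = FALSE,
                              seed = 1) {
  check_scalar(max_rounds, "max_rounds", min = 1, integer = TRUE)
  check_scalar(patience, "patience", min = 1, integer = TRUE)
  check_scalar(fl_clients_per_round, "fl_clients_per_round", min = 1,
               integer = TRUE)
  check_scalar(local_epochs, "local_epochs", min = 1, integer = TRUE)
  check_scalar(batch_size, "batch_size", min = 1, integer = TRUE)
  check_scalar(lr, "lr", min = 0)
  check_scalar(weight_decay, "weight_decay", min = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(max_rounds = as.integer(max_rounds),
                 patience = as.integer(patience),
                 fl_clients_per_round = as.integer(fl_clients_per_round),
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 carry_state = isTRUE(carry_state),
                 seed = as.integer(seed)),
            class = "training_protocol")
}

#' Mean absolute error of a head
#'
#' Pooled over all records: both eyes of a subject count separately.
#'
#' @param head a [head_model()].
#' @param x record matrix with one feature vector per row, or a
#'   `fedgap_network` — in which case `y` is interpreted as a vector of
#'   subject ids whose pooled records are evaluated.
#' @param y chronological ages (or subject ids, see `x`).
#' @return MAE in years.
#' @export
evaluate_mae <- function(head, x, y) {
  if (inherits(x, "fedgap_network")) {
    pooled <- pool_records(x, y) # y carries subject ids in this form
    x <- pooled$X
    y <- pooled$y
  }
  if (length(y) == 0L) stop_param("cannot evaluate on an empty record set")
  mean(abs(predict_head(head, x) - y))
}

#' One local client update
#'
#' Runs `local_epochs` Adam steps on the client's two records as one batch,
#' starting (by default) from a fresh optimizer state, and reports the
#' FLOPs spent as `local_epochs * head_flops(head, "train_step")` -- the
#' documented per-update accounting unit.
#'
#' @param head current global head.
#' @param client list with `X` (record matrix), `y` (ages) and optionally
#'   `role`; a non-`"train"` role is an error.
#' @param protocol a [training_protocol()].
#' @param state optional `adam_state` to continue from.
#' @return list with `head`, `state` and `flops`.
#' @export
local_update <- function(head, client, protocol, state = NULL) {
  if (!is.null(client$role) && !identical(client$role, "train")) {
    stop_param("local updates are only run on 'train' clients (got '%s')",
               client$role)
  }
  if (is.null(state)) {
    state <- adam_init(head, lr = protocol$lr,
                       weight_decay = protocol$weight_decay)
  }
  for (e in seq_len(protocol$local_epochs)) {
    g <- l2_loss_and_grad(head, client$X, client$y)
    res <- adam_step(head, g, state)
    head <- res$head
    state <- res$state
  }
  list(head = head, state = state,
       flops = protocol$local_epochs * head_flops(head, "train_step"))
}

#' Federated averaging of parameter vectors
#'
#' Unweighted elementwise arithmetic mean; all simulated clients hold the
#' same number of records, so uniform weights are exact FedAvg.
#'
#' @param param_sets list of numeric vectors of identical length.
#' @return numeric vector, the elementwise mean.
#' @export
fedavg <- function(param_sets) {
  if (length(param_sets) == 0L) stop_param("no parameter sets to average")
  len <- length(param_sets[[1L]])
  for (p in param_sets) {
    if (length(p) != len) stop_param("parameter sets differ in shape")
  }
  Reduce(`+`, param_sets) / length(param_sets)
}

# internal: shared bookkeeping across the three engines.
# updates_per_round = optimizer steps performed in one round/cycle/epoch
# (local visits x local_epochs); transfers_per_round = model transfers
# (send + return per visited client); bytes are 4 bytes per 32-bit
# parameter per transfer.
run_engine <- function(strategy, head, protocol, n_rounds_cap,
                       do_round, val_X, val_y,
                       updates_per_round, transfers_per_round,
                       n_val_clients) {
  pc <- head_param_count(head)
  payload <- 4 * pc
  step_flops <- head_flops(head, "train_step")
  best_mae <- Inf
  best_head <- head
  best_round <- 0L
  hist <- vector("list", n_rounds_cap)
  for (round in seq_len(n_rounds_cap)) {
    head <- do_round(head, round)
    mae <- evaluate_mae(head, val_X, val_y)
    hist[[round]] <- data.frame(
      round = round, val_mae = mae,
      cum_updates = round * updates_per_round,
      cum_flops = round * updates_per_round * step_flops,
      cum_transfers = round * transfers_per_round,
      cum_bytes = round * transfers_per_round * payload,
      cum_val_broadcasts = round * n_val_clients)
    if (mae < best_mae) {
      best_mae <- mae
      best_head <- head
      best_round <- round
    }
    if (round - best_round >= protocol$patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  last <- history[nrow(history), ]
  structure(list(
    strategy = strategy,
    head = best_head,
    best_round = best_round,
    best_val_mae = best_mae,
    history = history,
    ledger = list(train_flops = last$cum_flops,
                  transfers = last$cum_transfers,
                  bytes = last$cum_bytes,
                  val_broadcasts = last$cum_val_broadcasts,
                  payload_bytes = payload,
                  param_count = pc),
    updates_at_best = best_round * updates_per_round,
    rounds_run = nrow(history)),
    class = "fedgap_train_result")
}

#' @export
print.fedgap_train_result <- function(x, ...) {
  cat(sprintf(
    "%s training: best val MAE %.3f y at round %d of %d run\n",
    x$strategy, x$best_val_mae, x$best_round, x$rounds_run))
  cat(sprintf("  ledger: %.3g train FLOPs, %d transfers (%.2f MB)\n",
              x$ledger$train_flops, x$ledger$transfers,
              x$ledger$bytes / 1e6))
  invisible(x)
}

# internal: per-client record extraction for a split
client_data <- function(network, ids) {
  keep <- match(ids, network$subjects$subject_id)
  lapply(keep, function(k) {
    rows <- network$rows[k, ]
    list(X = network$cohort$features[rows, , drop = FALSE],
         y = network$cohort$meta$age[rows], role = "train")
  })
}

#' Federated (FedAvg) training
#'
#' Each round, `fl_clients_per_round` training clients are sampled without
#' replacement (fresh draws every round); each runs [local_update()] from
#' the current global head; the returned parameter vectors are averaged
#' with [fedavg()]. Validation MAE is evaluated on the pooled validation
#' records after every round; training stops at `max_rounds` or when the
#' validation MAE has not improved for `patience` rounds, returning the
#' best-round snapshot. The ledger counts two model transfers (send and
#' return) per participating client per round; validation broadcasts are
#' tracked separately and excluded from the transfer totals.
#'
#' @param network a [build_network()] result.
#' @param split a [monte_carlo_split()] role assignment.
#' @param protocol a [training_protocol()].
#' @param head optional initial head; defaults to a zero-initialized linear
#'   head of the cohort's feature dimension.
#' @return a `fedgap_train_result`.
#' @export
train_federated <- function(network, split, protocol, head = NULL) {
  stopifnot(inherits(network, "fedgap_network"),
            inherits(protocol, "training_protocol"))
  n_train <- length(split$train)
  if (protocol$fl_clients_per_round > n_train) {
    stop_param("fl_clients_per_round (%d) exceeds the %d training clients",
               protocol$fl_clients_per_round, n_train)
  }
  if (length(split$val) < 1L) stop_param("no validation clients")
  clients <- client_data(network, split$train)
  val <- pool_records(network, split$val)
  if (is.null(head)) {
    head <- head_model("linear", input_dim = ncol(network$cohort$features))
  }
  k <- protocol$fl_clients_per_round
  with_seed(derive_seed(protocol$seed, "train/fl"), {
    do_round <- function(head, round) {
      picked <- sample.int(n_train, k)
      params <- lapply(picked, function(i) {
        head_params(local_update(head, clients[[i]], protocol)$head)
      })
      set_head_params(head, fedavg(params))
    }
    run_engine("fl", head, protocol, protocol$max_rounds, do_round,
               val$X, val$y,
               updates_per_round = k * protocol$local_epochs,
               transfers_per_round = 2L * k,
               n_val_clients = length(split$val))
  })
}

#' Traveling-model training
#'
#' Each cycle visits every training client once in a freshly randomized
#' order, chaining the head from client to client via [local_update()].
#' Validation, early stopping and the ledger follow the same rules as
#' [train_federated()]; each visit costs two transfers (arrival and
#' departure of the model).
#'
#' @inheritParams train_federated
#' @return a `fedgap_train_result`.
#' @export
train_traveling <- function(network, split, protocol, head = NULL) {
  stopifnot(inherits(network, "fedgap_network"),
            inherits(protocol, "training_protocol"))
  n_train <- length(split$train)
  if (n_train < 1L) stop_param("no training clients")
  if (length(split$val) < 1L) stop_param("no validation clients")
  clients <- client_data(network, split$train)
  val <- pool_records(network, split$val)
  if (is.null(head)) {
    head <- head_model("linear", input_dim = ncol(network$cohort$features))
  }
  with_seed(derive_seed(protocol$seed, "train/tm"), {
    state <- NULL
    do_round <- function(head, round) {
      order <- sample.int(n_train, n_train)
      for (i in order) {
        res <- local_update(head, clients[[i]], protocol,
                            state = if (protocol$carry_state) state else NULL)
        head <- res$head
        if (protocol$carry_state) state <<- res$state
      }
      head
    }
    run_engine("tm", head, protocol, protocol$max_rounds, do_round,
               val$X, val$y,
               updates_per_round = n_train * protocol$local_epochs,
               transfers_per_round = 2L * n_train,
               n_val_clients = length(split$val))
  })
}

#' Centralized training
#'
#' Pools the training clients' records and runs minibatch Adam (persistent
#' optimizer state, batches of `batch_size`, reshuffled every epoch) on the
#' mean squared loss, with the same early-stopping rule as the distributed
#' engines. No model transfers are ledgered.
#'
#' @inheritParams train_federated
#' @return a `fedgap_train_result`.
#' @export
train_centralized <- function(network, split, protocol, head = NULL) {
  stopifnot(inherits(network, "fedgap_network"),
            inherits(protocol, "training_protocol"))
  if (length(split$train) < 1L) stop_param("no training records to pool")
  if (length(split$val) < 1L) stop_param("no validation clients")
  pool <- pool_records(network, split$train)
  val <- pool_records(network, split$val)
  if (is.null(head)) {
    head <- head_model("linear", input_dim = ncol(network$cohort$features))
  }
  n <- nrow(pool$X)
  bs <- min(protocol$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  state <- adam_init(head, lr = protocol$lr,
                     weight_decay = protocol$weight_decay)
  with_seed(derive_seed(protocol$seed, "train/central"), {
    do_round <- function(head, round) {
      perm <- sample.int(n, n)
      for (s in seq_len(steps_per_epoch)) {
        idx <- perm[((s - 1L) * bs + 1L):min(s * bs, n)]
        g <- l2_loss_and_grad(head, pool$X[idx, , drop = FALSE], pool$y[idx])
        res <- adam_step(head, g, state)
        head <- res$head
        state <<- res$state
      }
      head
    }
    run_engine("central", head, protocol, protocol$max_rounds, do_round,
               val$X, val$y,
               updates_per_round = steps_per_epoch,
               transfers_per_round = 0L,
               n_val_clients = length(split$val))
  })
}
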