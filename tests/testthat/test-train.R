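# small full-pipeline cohort used across engine tests
train_fixture <- function(n = 120, D = 48, seed = 6, ...) {
  co <- generate_cohort(tiny_spec(n_subjects = n, feature_dim = D,
                                  n_centers = 8, seed = seed, ...))
  net <- build_network(co)
  plan <- split_plan(n_train = 40, n_val = 15, mc_iterations = 2, seed = 3)
  list(net = net, split = monte_carlo_split(net, plan, 1))
}

test_that("MAE evaluation is the pooled per-record mean absolute error", {
  h <- head_model("linear", 2)
  h$W[[1]][] <- c(1, 0)
  X <- matrix(c(50, 0, 60, 0), 2, byrow = TRUE)
  expect_identical(evaluate_mae(h, X, c(52, 57)), 2.5)

  set.seed(8)
  hr <- head_model("linear", 6, init = "he")
  Xr <- matrix(rnorm(60), 10)
  yr <- rnorm(10, 50)
  manual <- 0
  for (i in 1:10) manual <- manual + abs(predict_head(hr, Xr[i, ]) - yr[i])
  expect_equal(evaluate_mae(hr, Xr, yr), manual / 10, tolerance = 1e-12)
  expect_error(evaluate_mae(hr, Xr[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("federated averaging is the elementwise mean", {
  expect_identical(fedavg(list(c(0), c(2))), 1)
  expect_identical(fedavg(list(1:3, 1:3, 1:3) |> lapply(as.numeric)),
                   c(1, 2, 3))
  set.seed(2)
  sets <- lapply(1:7, function(i) rnorm(11))
  manual <- numeric(11)
  for (s in sets) manual <- manual + s
  expect_equal(fedavg(sets), manual / 7, tolerance = 1e-15)
  expect_error(fedavg(list(1:2, 1:3)), "shape")
  expect_error(fedavg(list()), "no parameter sets")
})

test_that("a local update is the composition of loss, gradient and Adam", {
  fx <- train_fixture()
  cl <- fedgap:::client_data(fx$net, fx$split$train[1])[[1]]
  proto <- training_protocol(seed = 1)
  h0 <- head_model("linear", 48)

  res <- local_update(h0, cl, proto)
  manual <- adam_step(h0, l2_loss_and_grad(h0, cl$X, cl$y),
                      adam_init(h0, lr = proto$lr,
                                weight_decay = proto$weight_decay))
  expect_identical(head_params(res$head), head_params(manual$head))
  expect_identical(res$flops, head_flops(h0, "train_step"))

  # two local epochs = two chained steps with persistent state
  proto2 <- training_protocol(local_epochs = 2, seed = 1)
  res2 <- local_update(h0, cl, proto2)
  step2 <- adam_step(manual$head,
                     l2_loss_and_grad(manual$head, cl$X, cl$y),
                     manual$state)
  expect_identical(head_params(res2$head), head_params(step2$head))

  cl_bad <- cl
  cl_bad$role <- "validation"
  expect_error(local_update(h0, cl_bad, proto), "train")
})

test_that("centralized training is reproducible and composes full-batch Adam", {
  fx <- train_fixture()
  proto <- training_protocol(max_rounds = 10, patience = 10, seed = 12)
  r1 <- train_centralized(fx$net, fx$split, proto)
  r2 <- train_centralized(fx$net, fx$split, proto)
  expect_identical(r1$history, r2$history)
  expect_identical(head_params(r1$head), head_params(r2$head))

  # with batch covering the pool, each epoch is one full-batch Adam step
  pool <- fedgap:::pool_records(fx$net, fx$split$train)
  protob <- training_protocol(max_rounds = 3, patience = 10,
                              batch_size = nrow(pool$X), seed = 12)
  rb <- train_centralized(fx$net, fx$split, protob)
  h <- head_model("linear", 48)
  st <- adam_init(h, lr = protob$lr, weight_decay = protob$weight_decay)
  for (e in 1:3) {
    g <- l2_loss_and_grad(h, pool$X, pool$y)
    res <- adam_step(h, g, st)
    h <- res$head
    st <- res$state
  }
  val <- fedgap:::pool_records(fx$net, fx$split$val)
  expect_equal(rb$history$val_mae[3], evaluate_mae(h, val$X, val$y),
               tolerance = 1e-12)
})

test_that("training a linear head on the noiseless cohort recovers ages", {
  co <- generate_cohort(noiseless_spec(n_subjects = 320, feature_dim = 256))
  net <- build_network(co)
  plan <- split_plan(n_train = 250, n_val = 60, seed = 2)
  split <- monte_carlo_split(net, plan, 1)
  proto <- training_protocol(max_rounds = 200, patience = 200, seed = 5)
  fit <- train_centralized(net, split, proto)
  tr <- fedgap:::pool_records(net, split$train)
  expect_lt(evaluate_mae(fit$head, tr$X, tr$y), 0.1)
})

test_that("federated training degenerates to sequential training on one client", {
  co <- generate_cohort(tiny_spec(n_subjects = 40, feature_dim = 24,
                                  n_centers = 8, seed = 9))
  net <- build_network(co)
  # hand-build a split with a single training client
  plan <- split_plan(n_train = 1, n_val = 10, seed = 31)
  split <- monte_carlo_split(net, plan, 1)
  proto <- training_protocol(max_rounds = 15, patience = 100,
                             fl_clients_per_round = 1, seed = 21)
  rf <- train_federated(net, split, proto)
  rt <- train_traveling(net, split,
                        training_protocol(max_rounds = 15, patience = 100,
                                          seed = 21))

  cl <- fedgap:::client_data(net, split$train)[[1]]
  h <- head_model("linear", 24)
  manual <- numeric(15)
  val <- fedgap:::pool_records(net, split$val)
  for (r in 1:15) {
    h <- local_update(h, cl, proto)$head
    manual[r] <- evaluate_mae(h, val$X, val$y)
  }
  expect_equal(rf$history$val_mae, manual, tolerance = 1e-12)
  expect_equal(rt$history$val_mae, manual, tolerance = 1e-12)
})

test_that("federated training converges on the noiseless cohort and is deterministic", {
  co <- generate_cohort(noiseless_spec(n_subjects = 400, feature_dim = 1024,
                                       seed = 13))
  net <- build_network(co)
  plan <- split_plan(n_train = 300, n_val = 100, seed = 17)
  split <- monte_carlo_split(net, plan, 1)
  proto <- training_protocol(local_epochs = 2, seed = 23)
  rf <- train_federated(net, split, proto)
  expect_lt(rf$best_val_mae, 0.5)

  rf2 <- train_federated(net, split, proto)
  expect_identical(rf$history, rf2$history)
  expect_identical(rf$ledger, rf2$ledger)

  # ledger conservation: bytes = 4 * params * transfers, exactly
  expect_equal(rf$ledger$bytes, 4 * 1025 * rf$ledger$transfers)
  expect_equal(rf$ledger$transfers, rf$rounds_run * 2 * 32)
  expect_equal(rf$ledger$train_flops,
               rf$rounds_run * 32 * 2 * head_flops(rf$head, "train_step"))
  # early stopping returns the argmin-validation snapshot
  expect_identical(rf$best_val_mae, min(rf$history$val_mae))
  val <- fedgap:::pool_records(net, split$val)
  expect_equal(evaluate_mae(rf$head, val$X, val$y), rf$best_val_mae,
               tolerance = 1e-12)

  expect_error(
    train_federated(net, split,
                    training_protocol(fl_clients_per_round = 500)),
    "exceeds")
})

test_that("traveling-model cycles reshuffle clients but replay identically", {
  fx <- train_fixture(seed = 11)
  proto <- training_protocol(max_rounds = 6, patience = 100,
                             carry_state = TRUE, seed = 41)
  r1 <- train_traveling(fx$net, fx$split, proto)
  r2 <- train_traveling(fx$net, fx$split, proto)
  expect_identical(r1$history, r2$history)
  expect_identical(head_params(r1$head), head_params(r2$head))
  # consecutive cycles traverse different permutations, so the model moves
  # differently cycle to cycle
  expect_gt(length(unique(round(r1$history$val_mae, 10))), 1L)
  expect_equal(r1$ledger$transfers, 6 * 2 * 40)
  expect_equal(r1$ledger$bytes, 4 * 49 * r1$ledger$transfers)
})
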