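test_that("head construction and parameter counts match enumeration", {
  lin <- head_model("linear", 1024)
  expect_identical(head_param_count(lin), 1025)
  expect_identical(lin$layer_sizes, c(1024L, 1L))

  # n-layer MLP with 100 hidden units: enumerate weights + biases by hand
  for (n_layers in 2:4) {
    h <- head_model("mlp", 1024, n_layers = n_layers, hidden = 100)
    sizes <- c(1024, rep(100, n_layers - 1), 1)
    manual <- 0
    for (l in seq_len(n_layers)) {
      manual <- manual + sizes[l] * sizes[l + 1] + sizes[l + 1]
    }
    expect_identical(head_param_count(h), manual)
    expect_identical(sum(vapply(h$W, length, numeric(1))) +
                       sum(lengths(h$b)), manual)
  }
  expect_identical(head_param_count(head_model("mlp", 1024, 2)), 102601)
  expect_identical(head_param_count(head_model("mlp", 1024, 3)), 112701)
  expect_identical(head_param_count(head_model("mlp", 1024, 4)), 122801)
})

test_that("prediction is the documented affine / ReLU composition", {
  h <- head_model("linear", 5)
  h$b[[1]] <- 52
  expect_identical(predict_head(h, rnorm(5)), 52)

  h$b[[1]] <- 0
  h$W[[1]][] <- c(1, 0, 0, 0, 0)
  expect_identical(predict_head(h, c(40, 1, 2, 3, 4)), 40)
  expect_error(predict_head(h, rnorm(4)), "features")

  # MLP with known weights: single hidden unit ReLU
  m <- head_model("mlp", 2, n_layers = 2, hidden = 1)
  m$W[[1]][] <- c(1, -1)
  m$b[[1]] <- 0
  m$W[[2]][] <- 2
  m$b[[2]] <- 1
  expect_identical(predict_head(m, c(3, 1)), 2 * max(3 - 1, 0) + 1)
  expect_identical(predict_head(m, c(1, 3)), 1) # ReLU clips negative
})

test_that("loss and analytic gradients match finite differences", {
  # trivial cases
  h <- head_model("linear", 3)
  h$W[[1]][] <- c(1, 1, 1)
  g <- l2_loss_and_grad(h, matrix(c(1, 2, 3), 1), 6)
  expect_identical(g$loss, 0)
  expect_true(all(abs(flat_gradient(g)) == 0))

  # single sample with residual 2: d/db (pred - y)^2 = 2 * resid = 4
  g2 <- l2_loss_and_grad(h, matrix(c(1, 2, 3), 1), 4)
  expect_identical(g2$loss, 4)
  expect_identical(as.numeric(g2$gb[[1]]), 4)
  expect_error(l2_loss_and_grad(h, matrix(numeric(0), 0, 3), numeric(0)),
               "empty")

  # property: finite differences across head kinds and seeds
  set.seed(99)
  cases <- list(
    list(kind = "linear", dim = 20, n_layers = 2),
    list(kind = "mlp", dim = 13, n_layers = 2),
    list(kind = "mlp", dim = 11, n_layers = 3))
  for (cs in cases) {
    for (rep in 1:3) {
      h <- head_model(cs$kind, cs$dim, n_layers = cs$n_layers, hidden = 7,
                      init = "he", seed = rep * 17)
      X <- matrix(rnorm(5 * cs$dim), 5)
      y <- rnorm(5, mean = 50, sd = 8)
      ana <- flat_gradient(l2_loss_and_grad(h, X, y))
      num <- fd_gradient(h, X, y)
      rel <- abs(ana - num) / pmax(abs(ana), abs(num), 1e-6)
      expect_lt(max(rel), 1e-4)
    }
  }
})

test_that("Adam follows the update formula and an independent reference", {
  # hand-computed first step: w=1, g=2, lr=0.1, wd=0 -> w' ~ 0.9
  h <- head_model("linear", 1)
  h$W[[1]][] <- 1
  st <- adam_init(h, lr = 0.1, weight_decay = 0)
  g <- list(gW = list(matrix(2)), gb = list(0))
  r <- adam_step(h, g, st)
  expect_equal(r$head$W[[1]][1], 1 - 0.1 * 2 / (2 + 1e-8), tolerance = 1e-12)
  expect_identical(r$state$step, 1L)
  expect_equal(r$state$m$W[[1]][1], 0.2, tolerance = 1e-12)
  expect_equal(r$state$v$W[[1]][1], 0.004, tolerance = 1e-12)

  # zero gradient, zero decay: fixed point
  g0 <- list(gW = list(matrix(0)), gb = list(0))
  r0 <- adam_step(h, g0, adam_init(h, weight_decay = 0))
  expect_identical(r0$head$W[[1]][1], 1)

  # lr = 0 leaves parameters fixed even with gradients
  rl <- adam_step(h, g, adam_init(h, lr = 0))
  expect_identical(rl$head$W[[1]][1], 1)

  # weight decay with zero gradient strictly shrinks parameter norms
  hh <- head_model("linear", 4)
  hh$W[[1]][] <- c(1, -2, 3, -4)
  gz <- list(gW = list(matrix(0, 4, 1)), gb = list(0))
  ss <- adam_init(hh, weight_decay = 1e-2)
  for (i in 1:5) {
    prev <- sum(head_params(hh)^2)
    rr <- adam_step(hh, gz, ss)
    hh <- rr$head
    ss <- rr$state
    expect_lt(sum(hh$W[[1]]^2), prev)
  }

  # 1000-step trajectory against the independent scalar reference
  set.seed(3)
  P <- 5
  grads <- lapply(1:1000, function(i) rnorm(P))
  ref <- reference_adam(rep(1, P), grads, lr = 5e-3, wd = 1e-4)
  h <- head_model("linear", P - 1)
  h$W[[1]][] <- 1
  h$b[[1]] <- 1
  st <- adam_init(h)
  for (t in 1:1000) {
    g <- list(gW = list(matrix(grads[[t]][1:(P - 1)], ncol = 1)),
              gb = list(grads[[t]][P]))
    r <- adam_step(h, g, st)
    h <- r$head
    st <- r$state
    expect_lt(max(abs(head_params(h) - ref[t, ])), 1e-10)
  }
})

test_that("head FLOP accounting reproduces the documented figures", {
  lin <- head_model("linear", 1024)
  expect_identical(head_flops(lin, "inference"), 2049)
  expect_identical(head_flops(lin, "train_step"), 2049 + 4098 + 9 * 1025)
  expect_equal(head_flops(lin, "inference") / 1000, 2.0, tolerance = 0.05)
  expect_equal(head_flops(lin, "train_step") / 1000, 15.3, tolerance = 0.01)

  # MLP inference FLOPs: independent shape loop (2 FLOPs/MAC + bias adds)
  for (n_layers in 2:4) {
    h <- head_model("mlp", 1024, n_layers = n_layers, hidden = 100)
    sizes <- c(1024, rep(100, n_layers - 1), 1)
    manual <- 0
    for (l in seq_len(n_layers)) {
      manual <- manual + 2 * sizes[l] * sizes[l + 1] + sizes[l + 1]
    }
    expect_identical(head_flops(h, "inference"), manual)
  }
  # the 2-layer figure corresponds to 615.3 kFLOPs under a x3 multiplier
  expect_equal(3 * head_flops(head_model("mlp", 1024, 2), "inference") / 1e3,
               615.3, tolerance = 1e-4)
})

test_that("parameter flattening and JSON checkpoints round trip exactly", {
  h <- head_model("mlp", 9, n_layers = 3, hidden = 4, init = "he", seed = 5)
  p <- head_params(h)
  expect_length(p, head_param_count(h))
  h2 <- set_head_params(head_model("mlp", 9, n_layers = 3, hidden = 4), p)
  expect_identical(h2$W, h$W)
  expect_identical(h2$b, h$b)
  expect_error(set_head_params(h, p[-1]), "length")

  path <- withr::local_tempfile(fileext = ".json")
  write_head(h, path)
  back <- read_head(path)
  expect_identical(back$kind, h$kind)
  expect_identical(back$layer_sizes, h$layer_sizes)
  expect_identical(head_params(back), head_params(h))
})
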