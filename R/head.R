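#' Construct a regression head
#'
#' Heads map a feature vector to a scalar age estimate. The linear head is
#' a single affine map with `input_dim + 1` trainable parameters (1025 for
#' 1024-dimensional embeddings). An n-layer MLP head has n weight matrices
#' (`input_dim -> hidden -> ... -> hidden -> 1`) with ReLU between hidden
#' layers and a linear output.
#'
#' @param kind `"linear"` or `"mlp"`.
#' @param input_dim input feature dimension.
#' @param n_layers number of weight matrices for MLP heads (2, 3 or 4 in
#'   the shipped experiments); ignored for linear heads.
#' @param hidden hidden width of MLP layers (default 100).
#' @param init `"zero"` or `"he"` (seeded He-normal weights, zero biases).
#' @param seed seed used when `init = "he"`.
#' @return an object of class `fedgap_head` with fields `kind`,
#'   `layer_sizes`, `W` (list of fan_in x fan_out matrices) and `b`
#'   (list of bias vectors).
#' @export
head_model <- function(kind = c("linear", "mlp"), input_dim = 1024,
                       n_layers = 2, hidden = 100,
                       init = c("zero", "he"), seed = 1) {
  kind <- match.arg(kind)
  init <- match.arg(init)
  check_scalar(input_dim, "input_dim", min = 1, integer = TRUE)
  sizes <- if (kind == "linear") {
    c(input_dim, 1L)
  } else {
    check_scalar(n_layers, "n_layers", min = 1, integer = TRUE)
    check_scalar(hidden, "hidden", min = 1, integer = TRUE)
    c(input_dim, rep(hidden, n_layers - 1L), 1L)
  }
  L <- length(sizes) - 1L
  make_layer <- function(l) {
    if (init == "zero") {
      matrix(0, sizes[l], sizes[l + 1L])
    } else {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                          sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L])
    }
  }
  W <- with_seed(derive_seed(seed, paste0("head/", kind)),
                 lapply(seq_len(L), make_layer))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  structure(list(kind = kind, layer_sizes = as.integer(sizes),
                 W = W, b = b),
            class = "fedgap_head")
}

#' @export
print.fedgap_head <- function(x, ...) {
  cat(sprintf("%s regression head: %s (%d parameters)\n", x$kind,
              paste(x$layer_sizes, collapse = " -> "),
              head_param_count(x)))
  invisible(x)
}

#' Predict ages with a head
#'
#' @param head a [head_model()].
#' @param x numeric vector of length `input_dim` or matrix with one record
#'   per row.
#' @return numeric vector of predicted ages in years.
#' @export
predict_head <- function(head, x) {
  stopifnot(inherits(head, "fedgap_head"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != head$layer_sizes[1L]) {
    stop_param("input has %d features; head expects %d",
               ncol(x), head$layer_sizes[1L])
  }
  A <- x
  L <- length(head$W)
  for (l in seq_len(L)) {
    A <- A %*% head$W[[l]]
    A <- sweep(A, 2L, head$b[[l]], "+")
    if (l < L) A[A < 0] <- 0
  }
  as.numeric(A)
}

#' Mean squared loss and analytic gradients
#'
#' Loss is the batch mean of `(prediction - age)^2`; gradients are the
#' exact analytic derivatives of that mean with respect to every weight and
#' bias, computed by hand-written backpropagation (ReLU subgradient 0 at 0).
#'
#' @param head a [head_model()].
#' @param x matrix of records (rows) or a single feature vector.
#' @param y numeric vector of chronological ages.
#' @return list with `loss` (years^2), `gW` and `gb` (lists shaped like
#'   `head$W` / `head$b`).
#' @export
l2_loss_and_grad <- function(head, x, y) {
  stopifnot(inherits(head, "fedgap_head"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- nrow(x)
  if (n == 0L) stop_param("empty batch")
  if (length(y) != n) stop_param("batch has %d rows but %d ages", n, length(y))
  if (ncol(x) != head$layer_sizes[1L]) {
    stop_param("input has %d features; head expects %d",
               ncol(x), head$layer_sizes[1L])
  }
  L <- length(head$W)
  acts <- vector("list", L + 1L) # post-activation outputs, acts[[1]] = input
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    A <- acts[[l]] %*% head$W[[l]]
    A <- sweep(A, 2L, head$b[[l]], "+")
    if (l < L) A[A < 0] <- 0
    acts[[l + 1L]] <- A
  }
  resid <- as.numeric(acts[[L + 1L]]) - y
  loss <- mean(resid^2)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(2 * resid / n, ncol = 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, head$W[[l]])
      delta[acts[[l]] <= 0] <- 0
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Initialize Adam optimizer state for a head
#'
#' Hyperparameter defaults follow the training protocol of the simulated
#' experiments: learning rate 5e-3 and weight decay 1e-4, with the de-facto
#' standard betas (0.9, 0.999) and eps 1e-8. Weight decay is coupled
#' (added to the gradient before the moment updates).
#'
#' @param head a [head_model()].
#' @param lr learning rate.
#' @param weight_decay coupled L2 decay rate.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return an object of class `adam_state`.
#' @export
adam_init <- function(head, lr = 5e-3, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(inherits(head, "fedgap_head"))
  zeros <- function(p) {
    list(W = lapply(head$W, function(w) array(0, dim(w))),
         b = lapply(head$b, function(v) numeric(length(v))))
  }
  structure(list(step = 0L, m = zeros(), v = zeros(),
                 lr = lr, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update
#'
#' For each parameter: `g <- grad + weight_decay * param`;
#' `m <- beta1 m + (1 - beta1) g`; `v <- beta2 v + (1 - beta2) g^2`;
#' bias-corrected `m_hat`, `v_hat` at `step + 1`; finally
#' `param <- param - lr * m_hat / (sqrt(v_hat) + eps)`.
#'
#' @param head a [head_model()].
#' @param grads gradients as returned by [l2_loss_and_grad()].
#' @param state an [adam_init()] state.
#' @return list with the updated `head` and `state`.
#' @export
adam_step <- function(head, grads, state) {
  stopifnot(inherits(head, "fedgap_head"), inherits(state, "adam_state"))
  t <- state$step + 1L
  bc1 <- 1 - state$beta1^t
  bc2 <- 1 - state$beta2^t
  upd <- function(param, grad, m, v) {
    if (!identical(dim(param), dim(grad)) &&
        !(is.null(dim(param)) && length(param) == length(grad))) {
      stop_param("gradient shape does not match parameter shape")
    }
    g <- grad + state$weight_decay * param
    m <- state$beta1 * m + (1 - state$beta1) * g
    v <- state$beta2 * v + (1 - state$beta2) * g * g
    param <- param - state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
    list(param = param, m = m, v = v)
  }
  for (l in seq_along(head$W)) {
    r <- upd(head$W[[l]], grads$gW[[l]], state$m$W[[l]], state$v$W[[l]])
    head$W[[l]] <- r$param
    state$m$W[[l]] <- r$m
    state$v$W[[l]] <- r$v
    r <- upd(head$b[[l]], as.numeric(grads$gb[[l]]),
             state$m$b[[l]], state$v$b[[l]])
    head$b[[l]] <- r$param
    state$m$b[[l]] <- r$m
    state$v$b[[l]] <- r$v
  }
  state$step <- t
  list(head = head, state = state)
}

#' Trainable parameter count of a head
#'
#' @param head a [head_model()].
#' @return integer-valued count.
#' @examples
#' head_param_count(head_model("linear", 1024)) # 1025
#' @export
head_param_count <- function(head) {
  stopifnot(inherits(head, "fedgap_head"))
  sum(vapply(head$W, length, numeric(1))) +
    sum(vapply(head$b, length, numeric(1)))
}

#' FLOP accounting for a head
#'
#' Inference FLOPs are `flops_per_mac` times the total matrix-product MACs,
#' plus one FLOP per bias element when bias adds are counted (the head
#' convention defaults to 2 FLOPs/MAC with bias adds on, under which the
#' 1024-input linear head costs 2049 FLOPs per record). A training update
#' is accounted as forward + backward (costed at twice the forward pass) +
#' optimizer, with Adam fixed at 9 FLOPs per parameter; for the linear head
#' this totals 2049 + 4098 + 9225 = 15372 FLOPs.
#'
#' @param head a [head_model()].
#' @param phase `"inference"` or `"train_step"`.
#' @param conv a [flop_convention()]; default 2 FLOPs/MAC with bias adds.
#' @return FLOP count (double).
#' @export
head_flops <- function(head, phase = c("inference", "train_step"),
                       conv = flop_convention(count_bias_adds = TRUE)) {
  stopifnot(inherits(head, "fedgap_head"), inherits(conv, "flop_convention"))
  phase <- match.arg(phase)
  sizes <- head$layer_sizes
  macs <- sum(sizes[-length(sizes)] * sizes[-1L])
  fwd <- conv$flops_per_mac * macs
  if (conv$count_bias_adds) fwd <- fwd + sum(sizes[-1L])
  if (conv$count_norms_activations && length(sizes) > 2L) {
    fwd <- fwd + sum(sizes[-c(1L, length(sizes))]) # one ReLU op per hidden unit
  }
  if (phase == "inference") {
    fwd
  } else {
    fwd + 2 * fwd + 9 * head_param_count(head)
  }
}

# ---- flat parameter vector helpers (used by FedAvg and transfers) ----

#' Flatten head parameters to a numeric vector
#'
#' Layout: for each layer, the weight matrix column-major, then the bias.
#' `set_head_params()` is the inverse.
#'
#' @param head a [head_model()].
#' @return numeric vector of length `head_param_count(head)`.
#' @export
head_params <- function(head) {
  stopifnot(inherits(head, "fedgap_head"))
  unlist(lapply(seq_along(head$W), function(l) {
    c(as.numeric(head$W[[l]]), head$b[[l]])
  }), use.names = FALSE)
}

#' @rdname head_params
#' @param params numeric vector as produced by `head_params()`.
#' @export
set_head_params <- function(head, params) {
  stopifnot(inherits(head, "fedgap_head"))
  if (length(params) != head_param_count(head)) {
    stop_param("parameter vector has length %d; head needs %d",
               length(params), head_param_count(head))
  }
  off <- 0L
  for (l in seq_along(head$W)) {
    nw <- length(head$W[[l]])
    head$W[[l]][] <- params[off + seq_len(nw)]
    off <- off + nw
    nb <- length(head$b[[l]])
    head$b[[l]] <- params[off + seq_len(nb)]
    off <- off + nb
  }
  head
}

#' Save / load a head checkpoint as JSON
#'
#' Weights are serialized at full double precision (no digit rounding) so a
#' round trip reproduces the head exactly.
#'
#' @param head a [head_model()].
#' @param path JSON file path.
#' @return `write_head()` returns `path` invisibly; `read_head()` returns
#'   the head.
#' @export
write_head <- function(head, path) {
  stopifnot(inherits(head, "fedgap_head"))
  obj <- list(kind = head$kind,
              layer_sizes = head$layer_sizes,
              # 17 significant digits: every double round-trips exactly
              params = format_full(head_params(head)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_head
#' @export
read_head <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$layer_sizes)
  head <- if (obj$kind == "linear") {
    head_model("linear", input_dim = sizes[1L])
  } else {
    head_model("mlp", input_dim = sizes[1L],
               n_layers = length(sizes) - 1L, hidden = sizes[2L])
  }
  set_head_params(head, as.numeric(obj$params))
}
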