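# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# small, fast cohort spec for structural tests
tiny_spec <- function(n_subjects = 30, feature_dim = 16, seed = 1,
                      n_centers = 4, ...) {
  args <- utils::modifyList(
    list(n_subjects = n_subjects, feature_dim = feature_dim,
         age_mean = 52.32, age_sd = 7.98, age_min = 40, age_max = 74,
         n_centers = n_centers, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# completely noiseless linear cohort: features lie on an affine line in
# feature space and age is exactly recoverable
noiseless_spec <- function(n_subjects = 60, feature_dim = 32, seed = 2,
                           ...) {
  tiny_spec(n_subjects = n_subjects, feature_dim = feature_dim, seed = seed,
            nonlinearity_coef = 0, bio_age_sd = 0, eye_age_sd = 0,
            site_sd = 0, eye_sd = 0, noise_sd = 0, ...)
}

# closed-form ridge oracle, independent of the package's training engines:
# centered ridge solve, returns a prediction function
ridge_oracle <- function(X, y, lambda_scale = 1e-3) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  yb <- mean(y)
  lam <- lambda_scale * nrow(X)
  w <- solve(crossprod(Xc) + diag(lam, ncol(Xc)), crossprod(Xc, y - yb))
  function(Xnew) as.numeric(sweep(Xnew, 2L, mu) %*% w) + yb
}

# independent scalar-loop Adam reference (coupled weight decay, bias
# correction), written without reference to the package implementation
reference_adam <- function(theta0, grads_list, lr, wd,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  theta <- theta0
  m <- numeric(length(theta0))
  v <- numeric(length(theta0))
  out <- matrix(NA_real_, length(grads_list), length(theta0))
  for (t in seq_along(grads_list)) {
    g <- grads_list[[t]] + wd * theta
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    out[t, ] <- theta
  }
  out
}

# central finite-difference gradient of the batch L2 loss wrt all params
fd_gradient <- function(head, X, y, h = 1e-5) {
  p0 <- head_params(head)
  f <- function(p) {
    l2_loss_and_grad(set_head_params(head, p), X, y)$loss
  }
  vapply(seq_along(p0), function(i) {
    up <- p0
    dn <- p0
    up[i] <- up[i] + h
    dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# analytic gradient flattened in the head_params() layout
flat_gradient <- function(g) {
  unlist(lapply(seq_along(g$gW), function(l) {
    c(as.numeric(g$gW[[l]]), as.numeric(g$gb[[l]]))
  }), use.names = FALSE)
}
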