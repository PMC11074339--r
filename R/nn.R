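# Minimal neural-network kernel used by the SMILES variational autoencoder:
# GRU layers with full backpropagation through time, an embedding table,
# linear heads, masked softmax cross-entropy, and Adam with global-norm
# gradient clipping. Written against base R matrix ops; gradients are
# verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(1 / nr)
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

gru_init <- function(in_dim, h_dim) {
  s <- sqrt(1 / h_dim)
  list(Wi = nn_mat(in_dim, 3L * h_dim, s),
       Wh = nn_mat(h_dim, 3L * h_dim, s),
       bi = stats::runif(3L * h_dim, -s, s),
       bh = stats::runif(3L * h_dim, -s, s))
}

linear_init <- function(in_dim, out_dim) {
  s <- sqrt(1 / in_dim)
  list(W = nn_mat(in_dim, out_dim, s),
       b = stats::runif(out_dim, -s, s))
}

linear_fwd <- function(X, p) sweep(X %*% p$W, 2L, p$b, "+")

# GRU forward over T steps.
# X: list of B x in matrices; h0: B x h; mask: list of length-B 0/1 vectors
# (1 = position is real content; masked steps copy the previous hidden state).
gru_fwd <- function(X, h0, p, mask = NULL) {
  Tn <- length(X)
  h_dim <- ncol(h0)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  h <- h0
  i1 <- seq_len(h_dim); i2 <- i1 + h_dim; i3 <- i2 + h_dim
  for (t in seq_len(Tn)) {
    x <- X[[t]]
    pi <- sweep(x %*% p$Wi, 2L, p$bi, "+")
    ph <- sweep(h %*% p$Wh, 2L, p$bh, "+")
    r <- sigmoid(pi[, i1, drop = FALSE] + ph[, i1, drop = FALSE])
    u <- sigmoid(pi[, i2, drop = FALSE] + ph[, i2, drop = FALSE])
    phn <- ph[, i3, drop = FALSE]
    nn <- tanh(pi[, i3, drop = FALSE] + r * phn)
    h_new <- (1 - u) * nn + u * h
    if (!is.null(mask)) {
      m <- mask[[t]]
      h_new <- h_new * m + h * (1 - m)
    }
    cache[[t]] <- list(x = x, h_prev = h, r = r, u = u, nn = nn, phn = phn)
    h <- h_new
    hs[[t]] <- h
  }
  list(hs = hs, h_last = h, cache = cache)
}

# GRU backward. dh_steps: optional list of B x h gradients injected at each
# step's output; dh_last: gradient on the final hidden state. Returns
# gradients for parameters and inputs plus dh0.
gru_bwd <- function(fwd, p, X, mask = NULL, dh_steps = NULL, dh_last = NULL) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  h_dim <- ncol(fwd$h_last)
  i1 <- seq_len(h_dim); i2 <- i1 + h_dim; i3 <- i2 + h_dim
  gWi <- matrix(0, nrow(p$Wi), ncol(p$Wi))
  gWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  gbi <- numeric(3L * h_dim); gbh <- numeric(3L * h_dim)
  dX <- vector("list", Tn)
  dh <- if (is.null(dh_last)) matrix(0, B, h_dim) else dh_last
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dh_steps) && !is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    cc <- fwd$cache[[t]]
    if (!is.null(mask)) {
      m <- mask[[t]]
      dh_thru <- dh * (1 - m)   # copied part flows straight to h_{t-1}
      dh <- dh * m
    } else {
      dh_thru <- 0
    }
    du <- dh * (cc$h_prev - cc$nn)
    dnn <- dh * (1 - cc$u)
    dh_prev <- dh * cc$u + dh_thru
    dnn_pre <- dnn * (1 - cc$nn^2)
    dr <- dnn_pre * cc$phn
    dphn <- dnn_pre * cc$r
    dr_pre <- dr * cc$r * (1 - cc$r)
    du_pre <- du * cc$u * (1 - cc$u)
    dPi <- cbind(dr_pre, du_pre, dnn_pre)
    dPh <- cbind(dr_pre, du_pre, dphn)
    gWi <- gWi + crossprod(cc$x, dPi)
    gWh <- gWh + crossprod(cc$h_prev, dPh)
    gbi <- gbi + colSums(dPi)
    gbh <- gbh + colSums(dPh)
    dX[[t]] <- dPi %*% t(p$Wi)
    dh_prev <- dh_prev + dPh %*% t(p$Wh)
    dh <- dh_prev
  }
  list(grads = list(Wi = gWi, Wh = gWh, bi = gbi, bh = gbh),
       dX = dX, dh0 = dh)
}

# Softmax rows of a matrix, numerically stabilized.
softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# Masked cross-entropy. logits: B x V; target: integer B; mask: 0/1 B.
# Returns summed loss and dlogits.
ce_loss <- function(logits, target, mask) {
  P <- softmax_rows(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), target)
  loss <- -sum(log(pmax(P[idx], 1e-12)) * mask)
  dL <- P
  dL[idx] <- dL[idx] - 1
  dL <- dL * mask
  list(loss = loss, dlogits = dL)
}

# --- parameter-tree utilities -------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros <- function(p) tree_map(function(x) x * 0, p)

tree_gather <- function(p) {
  if (is.list(p)) unlist(lapply(p, tree_gather), use.names = FALSE)
  else as.numeric(p)
}

tree_global_norm <- function(g) sqrt(sum(tree_gather(g)^2))

tree_scale <- function(g, s) tree_map(function(x) x * s, g)

tree_add <- function(a, b) tree_map(`+`, a, b)

# Adam optimizer state and update. Operates on whole parameter trees.
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = Inf) {
  if (is.finite(clip)) {
    gn <- tree_global_norm(grads)
    if (gn > clip) grads <- tree_scale(grads, clip / (gn + 1e-12))
  }
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
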