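# The analytic gradients of the full VAE objective (embedding, stacked GRU
# encoder with pad masking, reparameterization, stacked GRU decoder with
# per-step losses, KL term) are checked against central finite differences.

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  vocab <- build_vocabulary(c("CCO", "CCN", "CCOC", "CC(C)O"))
  cfg <- vae_config(char_embed_dim = 5L, encoder_hidden = 7L,
                    encoder_layers = 2L, latent_dim = 4L,
                    decoder_hidden = 6L, decoder_layers = 2L, max_len = 12L)
  params <- polygen:::vae_init_params(vocab$size, cfg)
  ids <- polygen:::encode_corpus(c("CCO", "CC(C)O", "CCN"), vocab, 12L)
  eps <- matrix(rnorm(3L * 4L), 3L, 4L)
  lg <- polygen:::vae_loss_and_grads(ids, params, cfg, vocab, eps, kl_w = 0.7)

  get_p <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_p <- function(p, path, val) {
    if (length(path) == 1L) { p[[path[[1]]]] <- val; return(p) }
    p[[path[[1]]]] <- set_p(p[[path[[1]]]], path[-1], val)
    p
  }
  paths <- list(list("E"), list("out", "W"), list("dec_lat", "W"),
                list("mu_head", "W"), list("lv_head", "b"),
                list("enc", 1L, "Wi"), list("enc", 2L, "Wh"),
                list("dec", 1L, "Wi"), list("dec", 2L, "Wh"),
                list("dec", 1L, "bh"))
  h <- 1e-5
  for (path in paths) {
    base <- get_p(params, path)
    for (ii in sample(length(base), min(4L, length(base)))) {
      hi <- base; hi[ii] <- hi[ii] + h
      lo <- base; lo[ii] <- lo[ii] - h
      f_hi <- polygen:::vae_loss_and_grads(ids, set_p(params, path, hi),
                                           cfg, vocab, eps, 0.7)$total
      f_lo <- polygen:::vae_loss_and_grads(ids, set_p(params, path, lo),
                                           cfg, vocab, eps, 0.7)$total
      g_num <- (f_hi - f_lo) / (2 * h)
      g_ana <- get_p(lg$grads, path)[ii]
      expect_lt(abs(g_num - g_ana) / max(1e-6, abs(g_num) + abs(g_ana)),
                1e-3)
    }
  }
})

test_that("masked GRU steps copy the hidden state through padding", {
  set.seed(1)
  p <- polygen:::gru_init(3L, 4L)
  X <- list(matrix(rnorm(6), 2L, 3L), matrix(rnorm(6), 2L, 3L))
  h0 <- matrix(rnorm(8), 2L, 4L)
  mask <- list(c(1, 1), c(0, 1))   # first sequence ends after one step
  fw <- polygen:::gru_fwd(X, h0, p, mask)
  expect_identical(fw$hs[[2]][1, ], fw$hs[[1]][1, ])
  expect_false(isTRUE(all.equal(fw$hs[[2]][2, ], fw$hs[[1]][2, ])))
})

test_that("softmax rows normalize and cross-entropy respects the mask", {
  set.seed(2)
  L <- matrix(rnorm(12), 3L, 4L)
  P <- polygen:::softmax_rows(L)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
  cl <- polygen:::ce_loss(L, c(1L, 2L, 3L), mask = c(1, 0, 1))
  expect_equal(cl$loss,
               -log(P[1, 1]) - log(P[3, 3]), tolerance = 1e-12)
  expect_equal(cl$dlogits[2, ], rep(0, 4))
})

test_that("global-norm clipping rescales large gradients only", {
  g <- list(a = matrix(3, 2L, 2L), b = c(4, 0))
  norm <- polygen:::tree_global_norm(g)
  st <- polygen:::adam_init(g)
  up <- polygen:::adam_step(g, g, st, lr = 0, clip = norm / 2)
  expect_equal(up$params, g)   # lr 0: parameters untouched regardless
  small <- polygen:::adam_step(g, g, st, lr = 1, clip = 1e9)
  expect_false(identical(small$params, g))
})
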