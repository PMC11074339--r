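# SMILES variational autoencoder: a GRU encoder mapping token sequences to a
# Gaussian posterior (mu, logvar) over a continuous chemical embedding, and a
# GRU decoder generating token sequences from a latent coordinate z, with z
# concatenated to the input at every step. Trained with teacher forcing on
# masked cross-entropy plus the KL divergence to the standard-normal prior.

#' VAE architecture configuration
#'
#' Defaults mirror the full-scale architecture: 128-dim character embedding,
#' 1-layer 256-unit encoder GRU (dropout 0.2 between layers), 128-dim
#' latent, 3-layer 512-unit decoder GRU, sequences padded to length 100.
#' Desk-scale experiments shrink these via the arguments.
#'
#' @param char_embed_dim token embedding width.
#' @param encoder_hidden,encoder_layers,encoder_dropout encoder GRU shape.
#' @param latent_dim latent (chemical embedding) dimension.
#' @param decoder_hidden,decoder_layers,decoder_dropout decoder GRU shape.
#' @param max_len padded sequence length.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(char_embed_dim = 128L, encoder_hidden = 256L,
                       encoder_layers = 1L, encoder_dropout = 0.2,
                       latent_dim = 128L, decoder_hidden = 512L,
                       decoder_layers = 3L, decoder_dropout = 0.0,
                       max_len = 100L) {
  cfg <- list(char_embed_dim = as.integer(char_embed_dim),
              encoder_hidden = as.integer(encoder_hidden),
              encoder_layers = as.integer(encoder_layers),
              encoder_dropout = encoder_dropout,
              latent_dim = as.integer(latent_dim),
              decoder_hidden = as.integer(decoder_hidden),
              decoder_layers = as.integer(decoder_layers),
              decoder_dropout = decoder_dropout,
              max_len = as.integer(max_len))
  stopifnot(all(vapply(cfg[c(1:3, 5:7, 9)], function(x) x >= 1L, TRUE)),
            cfg$encoder_dropout >= 0, cfg$encoder_dropout < 1,
            cfg$decoder_dropout >= 0, cfg$decoder_dropout < 1)
  structure(cfg, class = "vae_config")
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam, learning rate 3e-4, batch
#' size 1024, gradient-norm clipping at 50, 200 epochs, KL weight 1.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size molecules per batch.
#' @param grad_clip global gradient-norm clip.
#' @param kl_weight weight on the KL term.
#' @param kl_warmup epochs over which the KL weight ramps linearly from 0
#'   to `kl_weight` (0 = no warm-up).
#' @param seed integer seed governing initialization, noise draws and batch
#'   order.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 3e-4,
                         batch_size = 1024L, grad_clip = 50,
                         kl_weight = 1.0, kl_warmup = 0L, seed = 1L) {
  stopifnot(epochs >= 0L, learning_rate > 0, batch_size >= 1L,
            grad_clip > 0, kl_weight >= 0, kl_warmup >= 0L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 kl_weight = kl_weight, kl_warmup = as.integer(kl_warmup),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Reparameterization trick
#'
#' Computes `z = mu + eps * exp(logvar / 2)` elementwise, where `eps` is
#' standard-normal noise, so gradients flow through the posterior
#' parameters.
#'
#' @param mu,logvar posterior mean and log-variance (vectors or matrices of
#'   equal shape).
#' @param eps noise of the same shape.
#' @return z of the same shape.
#' @export
reparameterize <- function(mu, logvar, eps) {
  stopifnot(length(mu) == length(logvar), length(mu) == length(eps))
  mu + eps * exp(logvar / 2)
}

#' Closed-form KL divergence to the standard normal
#'
#' `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))` per row, averaged over
#' rows (the batch).
#'
#' @param mu,logvar matrices (rows = batch) or vectors (a single point).
#' @return nonnegative scalar.
#' @export
kl_loss <- function(mu, logvar) {
  if (is.null(dim(mu))) { mu <- rbind(mu); logvar <- rbind(logvar) }
  per_row <- -0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))
  mean(per_row)
}

# --- parameter initialization -------------------------------------------

vae_init_params <- function(vocab_size, cfg) {
  enc <- vector("list", cfg$encoder_layers)
  for (l in seq_len(cfg$encoder_layers)) {
    in_dim <- if (l == 1L) cfg$char_embed_dim else cfg$encoder_hidden
    enc[[l]] <- gru_init(in_dim, cfg$encoder_hidden)
  }
  dec <- vector("list", cfg$decoder_layers)
  for (l in seq_len(cfg$decoder_layers)) {
    in_dim <- if (l == 1L) cfg$char_embed_dim + cfg$latent_dim
              else cfg$decoder_hidden
    dec[[l]] <- gru_init(in_dim, cfg$decoder_hidden)
  }
  list(
    E = nn_mat(vocab_size, cfg$char_embed_dim, 0.1),
    enc = enc,
    mu_head = linear_init(cfg$encoder_hidden, cfg$latent_dim),
    lv_head = linear_init(cfg$encoder_hidden, cfg$latent_dim),
    dec_lat = linear_init(cfg$latent_dim, cfg$decoder_hidden),
    dec = dec,
    out = linear_init(cfg$decoder_hidden, vocab_size)
  )
}

# --- encoder ------------------------------------------------------------

# ids: B x T integer matrix. Returns mu, logvar and caches for backprop.
vae_encode_fwd <- function(ids, params, cfg, vocab, want_cache = FALSE) {
  B <- nrow(ids)
  content <- ids != vocab$pad_id
  Tn <- max(1L, max(which(colSums(content) > 0L)))
  X <- vector("list", Tn)
  mask <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    X[[t]] <- params$E[ids[, t], , drop = FALSE]
    mask[[t]] <- as.numeric(content[, t])
  }
  layer_in <- X
  fwds <- vector("list", cfg$encoder_layers)
  for (l in seq_len(cfg$encoder_layers)) {
    h0 <- matrix(0, B, cfg$encoder_hidden)
    fwds[[l]] <- gru_fwd(layer_in, h0, params$enc[[l]], mask)
    layer_in <- fwds[[l]]$hs
  }
  h <- fwds[[cfg$encoder_layers]]$h_last
  mu <- linear_fwd(h, params$mu_head)
  logvar <- linear_fwd(h, params$lv_head)
  out <- list(mu = mu, logvar = logvar, Tn = Tn)
  if (want_cache) {
    out$cache <- list(X = X, mask = mask, fwds = fwds, h = h, ids = ids)
  }
  out
}

# --- decoder (teacher forcing) ------------------------------------------

vae_decode_fwd <- function(ids, z, params, cfg, vocab, want_cache = FALSE) {
  B <- nrow(ids)
  Tfull <- ncol(ids)
  target <- ids[, -1L, drop = FALSE]
  tmask <- target != vocab$pad_id
  Tn <- max(1L, max(which(colSums(tmask) > 0L)))
  h0 <- linear_fwd(z, params$dec_lat)
  X <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    X[[t]] <- cbind(params$E[ids[, t], , drop = FALSE], z)
  }
  layer_in <- X
  fwds <- vector("list", cfg$decoder_layers)
  for (l in seq_len(cfg$decoder_layers)) {
    fwds[[l]] <- gru_fwd(layer_in, h0, params$dec[[l]], mask = NULL)
    layer_in <- fwds[[l]]$hs
  }
  top <- fwds[[cfg$decoder_layers]]$hs
  loss <- 0
  dhs <- vector("list", Tn)
  logits_list <- if (want_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    logits <- linear_fwd(top[[t]], params$out)
    cl <- ce_loss(logits, target[, t], as.numeric(tmask[, t]))
    loss <- loss + cl$loss
    dhs[[t]] <- cl$dlogits
    if (want_cache) logits_list[[t]] <- logits
  }
  out <- list(recon_sum = loss, Tn = Tn)
  if (want_cache) {
    out$cache <- list(X = X, fwds = fwds, top = top, dlogits = dhs,
                      h0 = h0, ids = ids, target = target, tmask = tmask,
                      logits = logits_list)
  }
  out
}

# --- full training step (forward + backward) ----------------------------

vae_loss_and_grads <- function(ids, params, cfg, vocab, eps, kl_w) {
  B <- nrow(ids)
  enc <- vae_encode_fwd(ids, params, cfg, vocab, want_cache = TRUE)
  mu <- enc$mu; lv <- enc$logvar
  z <- mu + eps * exp(lv / 2)
  dec <- vae_decode_fwd(ids, z, params, cfg, vocab, want_cache = TRUE)
  recon <- dec$recon_sum / B
  kl <- kl_loss(mu, lv)
  grads <- tree_zeros(params)

  # ---- decoder backward
  dc <- dec$cache
  Tn <- dec$Tn
  dtop <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dlog <- dc$dlogits[[t]] / B
    grads$out$W <- grads$out$W + crossprod(dc$top[[t]], dlog)
    grads$out$b <- grads$out$b + colSums(dlog)
    dtop[[t]] <- dlog %*% t(params$out$W)
  }
  dh0_total <- matrix(0, B, cfg$decoder_hidden)
  dh_steps <- dtop
  dX_lower <- NULL
  for (l in rev(seq_len(cfg$decoder_layers))) {
    bw <- gru_bwd(dc$fwds[[l]], params$dec[[l]],
                  if (l == 1L) dc$X else dc$fwds[[l - 1L]]$hs,
                  mask = NULL, dh_steps = dh_steps, dh_last = NULL)
    grads$dec[[l]] <- tree_add(grads$dec[[l]], bw$grads)
    dh0_total <- dh0_total + bw$dh0
    dh_steps <- bw$dX
    if (l == 1L) dX_lower <- bw$dX
  }
  # h0 linear
  grads$dec_lat$W <- grads$dec_lat$W + crossprod(z, dh0_total)
  grads$dec_lat$b <- grads$dec_lat$b + colSums(dh0_total)
  dz <- dh0_total %*% t(params$dec_lat$W)
  # input concatenation: embedding part and z part
  ed <- cfg$char_embed_dim
  for (t in seq_len(Tn)) {
    dxt <- dX_lower[[t]]
    dz <- dz + dxt[, (ed + 1L):(ed + cfg$latent_dim), drop = FALSE]
    dE_t <- dxt[, seq_len(ed), drop = FALSE]
    idt <- dc$ids[, t]
    agg <- rowsum(dE_t, group = idt)
    rows <- as.integer(rownames(agg))
    grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + agg
  }

  # ---- reparameterization + KL backward
  dmu <- dz + mu / B * kl_w
  dlv <- dz * eps * 0.5 * exp(lv / 2) + 0.5 * (exp(lv) - 1) / B * kl_w

  # ---- encoder heads
  ec <- enc$cache
  grads$mu_head$W <- grads$mu_head$W + crossprod(ec$h, dmu)
  grads$mu_head$b <- grads$mu_head$b + colSums(dmu)
  grads$lv_head$W <- grads$lv_head$W + crossprod(ec$h, dlv)
  grads$lv_head$b <- grads$lv_head$b + colSums(dlv)
  dh_enc <- dmu %*% t(params$mu_head$W) + dlv %*% t(params$lv_head$W)

  # ---- encoder layers backward
  dh_steps <- NULL
  dh_last <- dh_enc
  for (l in rev(seq_len(cfg$encoder_layers))) {
    bw <- gru_bwd(ec$fwds[[l]], params$enc[[l]],
                  if (l == 1L) ec$X else ec$fwds[[l - 1L]]$hs,
                  mask = ec$mask, dh_steps = dh_steps, dh_last = dh_last)
    grads$enc[[l]] <- tree_add(grads$enc[[l]], bw$grads)
    dh_steps <- bw$dX
    dh_last <- NULL
  }
  for (t in seq_along(dh_steps)) {
    idt <- ec$ids[, t]
    agg <- rowsum(dh_steps[[t]], group = idt)
    rows <- as.integer(rownames(agg))
    grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + agg
  }

  list(recon = recon, kl = kl, total = recon + kl_w * kl, grads = grads)
}

# --- user-facing fitting function ---------------------------------------

#' Fit a SMILES variational autoencoder
#'
#' Trains the GRU encoder/decoder VAE on a curated corpus with teacher
#' forcing, Adam, global-norm gradient clipping and a seeded batch order.
#' All randomness (initialization, reparameterization noise, shuffling)
#' derives from `train$seed`.
#'
#' @param smiles character vector of curated canonical SMILES.
#' @param config a [vae_config()].
#' @param train a [train_config()].
#' @param vocab optional [build_vocabulary()] result; built from `smiles`
#'   when omitted.
#' @return object of class `smiles_vae` with elements `params`, `config`,
#'   `vocab`, `trace` (per-epoch loss data.frame), `seed`.
#' @seealso [fine_tune()], [sample_molecules()], [vae_encode()]
#' @export
smiles_vae <- function(smiles, config = vae_config(), train = train_config(),
                       vocab = NULL) {
  stopifnot(inherits(config, "vae_config"), inherits(train, "train_config"))
  smiles <- smiles[!is.na(smiles)]
  if (length(smiles) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)
  set.seed(train$seed)
  params <- vae_init_params(vocab$size, config)
  model <- structure(list(params = params, config = config, vocab = vocab,
                          trace = NULL, seed = train$seed,
                          schema = "polygen-vae-1"),
                     class = "smiles_vae")
  if (train$epochs == 0L) return(model)
  vae_train_loop(model, smiles, train)
}

vae_train_loop <- function(model, smiles, train, rng_offset = 0L) {
  cfg <- model$config; vocab <- model$vocab
  ids_all <- encode_corpus(smiles, vocab, cfg$max_len)
  n <- nrow(ids_all)
  params <- model$params
  opt <- adam_init(params)
  trace <- data.frame(epoch = integer(0), recon = numeric(0),
                      kl = numeric(0), total = numeric(0))
  set.seed(train$seed + rng_offset)
  for (ep in seq_len(train$epochs)) {
    kl_w <- if (train$kl_warmup > 0L) {
      train$kl_weight * min(1, ep / train$kl_warmup)
    } else train$kl_weight
    perm <- sample.int(n)
    ep_recon <- 0; ep_kl <- 0
    starts <- seq(1L, n, by = train$batch_size)
    for (s in starts) {
      sel <- perm[s:min(s + train$batch_size - 1L, n)]
      ids <- ids_all[sel, , drop = FALSE]
      B <- length(sel)
      eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
      lg <- vae_loss_and_grads(ids, params, cfg, vocab, eps, kl_w)
      st <- adam_step(params, lg$grads, opt, lr = train$learning_rate,
                      clip = train$grad_clip)
      params <- st$params; opt <- st$state
      ep_recon <- ep_recon + lg$recon * B
      ep_kl <- ep_kl + lg$kl * B
    }
    trace <- rbind(trace, data.frame(
      epoch = ep + NROW(model$trace), recon = ep_recon / n,
      kl = ep_kl / n, total = ep_recon / n + kl_w * ep_kl / n))
  }
  model$params <- params
  model$trace <- rbind(model$trace, trace)
  model
}

#' Fine-tune a fitted VAE on additional molecules
#'
#' Continues training from the current weights with the same objective
#' (reconstruction + KL), as used in each reinforcement cycle. The
#' full-scale recipe is 2 epochs at batch size 512.
#'
#' @param model a fitted `smiles_vae`.
#' @param smiles molecules to fine-tune on (must tokenize under the model's
#'   vocabulary).
#' @param epochs,batch_size,learning_rate training settings.
#' @param seed seed for this fine-tuning run.
#' @return the updated `smiles_vae`.
#' @export
fine_tune <- function(model, smiles, epochs = 2L, batch_size = 512L,
                      learning_rate = 3e-4, seed = model$seed + 1L) {
  stopifnot(inherits(model, "smiles_vae"))
  if (epochs == 0L || length(smiles) == 0L) return(model)
  tr <- train_config(epochs = epochs, learning_rate = learning_rate,
                     batch_size = batch_size, grad_clip = 50,
                     kl_weight = attr(model, "kl_weight") %||% 1.0,
                     seed = seed)
  vae_train_loop(model, smiles, tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode molecules into the chemical embedding
#'
#' Runs the encoder in evaluation mode (no dropout, no noise) and returns
#' the posterior mean and log-variance for each molecule.
#'
#' @param model a fitted `smiles_vae`.
#' @param smiles character vector of SMILES from the model's vocabulary.
#' @return list with matrices `mu` and `logvar` (rows = molecules).
#' @export
vae_encode <- function(model, smiles) {
  stopifnot(inherits(model, "smiles_vae"))
  ids <- encode_corpus(smiles, model$vocab, model$config$max_len)
  enc <- vae_encode_fwd(ids, model$params, model$config, model$vocab)
  list(mu = enc$mu, logvar = enc$logvar)
}

#' Generation context
#'
#' Settings for decoding without a source molecule: the start token plays
#' the role of the dummy input, and each subsequent step consumes the token
#' emitted at the previous one.
#'
#' @param mode `"argmax"` (deterministic) or `"multinomial"` (sample from
#'   the softmax).
#' @param max_steps maximum tokens to generate (defaults to the model's
#'   `max_len`).
#' @return object of class `generation_context`.
#' @export
generation_context <- function(mode = c("argmax", "multinomial"),
                               max_steps = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, max_steps = max_steps),
            class = "generation_context")
}

#' Decode latent coordinates into token sequences
#'
#' Iteratively generates a sequence character-by-character from each latent
#' coordinate: the hidden state is initialized from `z` through the latent
#' linear map, each step consumes `z` concatenated with the embedding of
#' the previous token, and emits a softmax over the vocabulary.
#'
#' @param model a fitted `smiles_vae`.
#' @param z numeric matrix (rows = latent points) or a single vector.
#' @param ctx a [generation_context()].
#' @param keep_probs return the per-step probability matrices.
#' @return list with `smiles` (character), `ids` (list of integer token
#'   sequences) and optionally `probs`.
#' @export
decode_sequence <- function(model, z, ctx = generation_context(),
                            keep_probs = FALSE) {
  stopifnot(inherits(model, "smiles_vae"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  cfg <- model$config; vocab <- model$vocab; params <- model$params
  stopifnot(ncol(z) == cfg$latent_dim)
  B <- nrow(z)
  # cap at the re-encodable content budget (max_len minus start/end frame),
  # so any decoded molecule can pass back through tokenize()
  max_steps <- min(ctx$max_steps %||% (cfg$max_len - 2L), cfg$max_len - 2L)
  h <- linear_fwd(z, params$dec_lat)
  hs <- rep(list(h), cfg$decoder_layers)
  prev <- rep(vocab$start_id, B)
  finished <- rep(FALSE, B)
  seqs <- matrix(vocab$pad_id, B, max_steps)
  probs <- if (keep_probs) vector("list", max_steps) else NULL
  for (t in seq_len(max_steps)) {
    x <- cbind(params$E[prev, , drop = FALSE], z)
    for (l in seq_len(cfg$decoder_layers)) {
      st <- gru_fwd(list(x), hs[[l]], params$dec[[l]])
      hs[[l]] <- st$h_last
      x <- st$h_last
    }
    logits <- linear_fwd(x, params$out)
    P <- softmax_rows(logits)
    if (keep_probs) probs[[t]] <- P
    tok <- if (ctx$mode == "argmax") {
      max.col(P, ties.method = "first")
    } else {
      vapply(seq_len(B), function(b) {
        sample.int(ncol(P), 1L, prob = P[b, ])
      }, 1L)
    }
    tok[finished] <- vocab$pad_id
    seqs[, t] <- tok
    finished <- finished | tok == vocab$end_id
    prev <- tok
    prev[prev == vocab$pad_id] <- vocab$end_id  # inert input once finished
    if (all(finished)) {
      seqs <- seqs[, seq_len(t), drop = FALSE]
      if (keep_probs) probs <- probs[seq_len(t)]
      break
    }
  }
  ids <- lapply(seq_len(B), function(b) {
    s <- seqs[b, ]
    stop_at <- which(s == vocab$end_id | s == vocab$pad_id)
    if (length(stop_at) > 0L) s <- s[seq_len(stop_at[1] - 1L)]
    as.integer(s)
  })
  smiles <- vapply(ids, function(s) paste(vocab$tokens[s], collapse = ""), "")
  out <- list(smiles = smiles, ids = ids)
  if (keep_probs) out$probs <- probs
  out
}

#' Sample de novo molecules from the latent prior
#'
#' Draws `n` coordinates from the standard-normal prior over the chemical
#' embedding, decodes each, and checks validity (parseable, valence-clean
#' SMILES).
#'
#' @param model a fitted `smiles_vae`.
#' @param n number of samples.
#' @param ctx a [generation_context()].
#' @param seed integer seed for the latent draws (and multinomial decoding).
#' @return data.frame with columns `smiles` and `valid`; the validity rate
#'   (valid / n) is attached as attribute `validity_rate` (`NULL` when
#'   `n = 0`).
#' @export
sample_molecules <- function(model, n, ctx = generation_context("multinomial"),
                             seed = 1L) {
  stopifnot(inherits(model, "smiles_vae"), n >= 0L)
  if (n == 0L) {
    out <- data.frame(smiles = character(0), valid = logical(0))
    attr(out, "validity_rate") <- NULL
    return(out)
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(n * model$config$latent_dim), n,
              model$config$latent_dim)
  dec <- decode_sequence(model, z, ctx)
  valid <- smiles_valid(dec$smiles)
  out <- data.frame(smiles = dec$smiles, valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "validity_rate") <- mean(valid)
  out
}

#' Evaluation losses without training
#'
#' Teacher-forced reconstruction loss (using the posterior mean as the
#' latent, no sampling noise) and KL term for a set of molecules under the
#' current weights. Used to compare models before/after fine-tuning.
#'
#' @param model a fitted `smiles_vae`.
#' @param smiles character vector of SMILES.
#' @return list with `recon` (mean per molecule) and `kl`.
#' @export
vae_eval_loss <- function(model, smiles) {
  ids <- encode_corpus(smiles, model$vocab, model$config$max_len)
  enc <- vae_encode_fwd(ids, model$params, model$config, model$vocab)
  dec <- vae_decode_fwd(ids, enc$mu, model$params, model$config, model$vocab)
  list(recon = dec$recon_sum / nrow(ids), kl = kl_loss(enc$mu, enc$logvar))
}

# --- checkpointing ------------------------------------------------------

#' Save / load a VAE checkpoint
#'
#' The checkpoint is a self-describing archive holding the schema version,
#' architecture config, vocabulary, weights, training seed and loss trace.
#' Reloading reproduces evaluation outputs bit-exactly.
#'
#' @param model a `smiles_vae`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `smiles_vae`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "smiles_vae"))
  saveRDS(unclass(model), path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "polygen-vae-1")) {
    stop("unrecognized checkpoint schema: ", obj$schema)
  }
  structure(obj, class = "smiles_vae")
}

# --- S3 methods ---------------------------------------------------------

#' @export
print.smiles_vae <- function(x, ...) {
  cfg <- x$config
  cat("SMILES variational autoencoder\n")
  cat(sprintf("  vocabulary: %d tokens; max length %d\n",
              x$vocab$size, cfg$max_len))
  cat(sprintf("  encoder: %d-layer GRU (%d units) -> latent %d\n",
              cfg$encoder_layers, cfg$encoder_hidden, cfg$latent_dim))
  cat(sprintf("  decoder: %d-layer GRU (%d units)\n",
              cfg$decoder_layers, cfg$decoder_hidden))
  if (!is.null(x$trace) && nrow(x$trace) > 0L) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  trained %d epochs; final loss %.4f (recon %.4f, KL %.4f)\n",
                nrow(x$trace), last$total, last$recon, last$kl))
  } else {
    cat("  untrained (random initialization)\n")
  }
  invisible(x)
}

#' @export
summary.smiles_vae <- function(object, ...) {
  n_par <- length(tree_gather(object$params))
  structure(list(config = object$config, vocab_size = object$vocab$size,
                 n_parameters = n_par, trace = object$trace,
                 seed = object$seed),
            class = "summary.smiles_vae")
}

#' @export
print.summary.smiles_vae <- function(x, ...) {
  cat(sprintf("SMILES VAE: %d parameters, vocabulary %d, seed %d\n",
              x$n_parameters, x$vocab_size, x$seed))
  if (!is.null(x$trace) && nrow(x$trace) > 0L) {
    cat("loss trace (last 5 epochs):\n")
    print(utils::tail(x$trace, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Predict method: encode or reconstruct molecules
#'
#' `type = "latent"` returns the posterior mean embedding; `type =
#' "reconstruction"` decodes each molecule's posterior mean back to a
#' SMILES string (argmax decoding).
#'
#' @param object a fitted `smiles_vae`.
#' @param newdata character vector of SMILES.
#' @param type `"latent"` or `"reconstruction"`.
#' @param ... unused.
#' @export
predict.smiles_vae <- function(object, newdata,
                               type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  enc <- vae_encode(object, newdata)
  if (type == "latent") return(enc$mu)
  decode_sequence(object, enc$mu, generation_context("argmax"))$smiles
}

#' Simulate method: draw de novo molecules
#'
#' @param object a fitted `smiles_vae`.
#' @param nsim number of molecules to sample from the latent prior.
#' @param seed integer seed.
#' @param ... passed to [sample_molecules()].
#' @export
simulate.smiles_vae <- function(object, nsim = 1L, seed = 1L, ...) {
  sample_molecules(object, n = nsim, seed = seed, ...)
}
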