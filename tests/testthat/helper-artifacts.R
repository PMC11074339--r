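# Expensive shared artifacts (trained models, scenarios) built once per test
# run and cached for every file that needs them.

.artifact_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .artifact_cache)) {
    assign(name, builder(), envir = .artifact_cache)
  }
  get(name, envir = .artifact_cache)
}

# 2-family, 50-molecule fixture corpus used for the memorization and
# embedding-structure experiments.
toy_corpus <- function() {
  cached("toy_corpus", function() generate_fixture_corpus(2L, 25L, seed = 7L))
}

# Desk-scale VAE memorized on the toy corpus (~1 min of CPU).
toy_vae <- function() {
  cached("toy_vae", function() {
    corp <- toy_corpus()
    smiles_vae(
      corp$smiles,
      vae_config(char_embed_dim = 32L, encoder_hidden = 64L,
                 encoder_layers = 1L, encoder_dropout = 0,
                 latent_dim = 16L, decoder_hidden = 96L,
                 decoder_layers = 1L, max_len = 30L),
      train_config(epochs = 500L, learning_rate = 5e-3, batch_size = 50L,
                   grad_clip = 50, kl_weight = 0.02, kl_warmup = 200L,
                   seed = 11L))
  })
}

# Full synthetic dual-target scenario with its own trained VAE (~3 min).
scen5 <- function() {
  cached("scen5", function() {
    build_scenario(scenario_spec(seed = 5L), train_vae = TRUE)
  })
}

# Family-stratified disjoint molecule split of the scenario corpus.
scen5_split <- function() {
  cached("scen5_split", function() {
    corp <- scen5()$corpus
    ord <- order(corp$family, corp$smiles, method = "radix")
    train <- corp$smiles[ord[seq(1L, nrow(corp), by = 2L)]]
    list(train = train, eval = setdiff(corp$smiles, train))
  })
}

# Scorers trained only on the training half of the scenario molecules
# (1000 trees; used by both the reinforcement and dual-activity tests).
scen5_scorers <- function() {
  cached("scen5_scorers", function() {
    sc <- scen5()
    split <- scen5_split()
    lapply(sc$activity, function(a) {
      target_scorer(a[a$smiles %in% split$train, , drop = FALSE],
                    seed = 11L, cv_folds = 0L)
    })
  })
}

# Evaluation-half triplets with observed and scorer-predicted affinities.
scen5_triplets <- function() {
  cached("scen5_triplets", function() {
    sc <- scen5()
    split <- scen5_split()
    scorers <- scen5_scorers()
    cols <- c("smiles", "target_id", "affinity_value")
    recs <- rbind(
      sc$activity$T1[sc$activity$T1$smiles %in% split$eval, cols],
      sc$activity$T2[sc$activity$T2$smiles %in% split$eval, cols])
    trip <- filter_dual_assayed(recs, canonicalize = FALSE)
    predict_dual(trip, scorers$T1, scorers$T2)
  })
}

# Cheap low-fidelity scorers for plumbing tests where forest quality is
# irrelevant (tree count and mtry shrunk for speed).
cheap_scorers <- function() {
  cached("cheap_scorers", function() {
    sc <- scen5()
    lapply(sc$activity, function(a) {
      target_scorer(a[seq_len(60L), , drop = FALSE], n_trees = 50L,
                    seed = 3L, cv_folds = 0L, mtry = 64L)
    })
  })
}
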