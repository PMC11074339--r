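test_that("top-k selection equals a brute-force sort with stated tie-breaks", {
  set.seed(10)
  n <- 1000L
  cand <- data.frame(
    smiles = replicate(n, paste(sample(c("C", "N", "O"), 8, TRUE),
                                collapse = "")),
    R = round(runif(n), 3))   # rounding forces plenty of ties
  k <- 100L
  sel <- select_top_k(cand, k)
  oracle <- cand[order(-cand$R, cand$smiles, method = "radix"), ][1:k, ]
  rownames(oracle) <- NULL
  expect_identical(sel, oracle)
  expect_true(all(diff(sel$R) <= 0))
  # explicit boundary tie: lexicographically smaller SMILES wins
  tie <- data.frame(smiles = c("CCN", "CCC", "CCO"), R = c(1, 0.5, 0.5))
  expect_equal(select_top_k(tie, 2L)$smiles, c("CCN", "CCC"))
  # k = n returns everything; k > n warns and returns all
  expect_equal(nrow(select_top_k(cand, n)), n)
  expect_warning(all_rows <- select_top_k(tie, 10L), "exceeds")
  expect_equal(nrow(all_rows), 3L)
})

test_that("a reinforcement cycle logs nested counts and respects no-op", {
  sc <- scen5()
  scorers <- cheap_scorers()
  cfg <- generation_config(n_cycles = 1L, samples_per_cycle = 64L,
                           top_k = 16L, finetune_epochs = 0L,
                           mode = "multinomial", seed = 77L)
  res <- run_cycle(sc$vae, scorers, sc$ligand_sets, sc$specs, cfg)
  lg <- res$log
  expect_true(lg$n_scored <= lg$n_unique)
  expect_true(lg$n_unique <= lg$n_valid)
  expect_true(lg$n_valid <= lg$n_sampled)
  expect_equal(lg$n_sampled, 64L)
  # finetune_epochs = 0: model untouched, log still complete
  expect_identical(res$model$params, sc$vae$params)
  expect_false(anyNA(unlist(lg[c("mean_R", "median_R", "max_R")])))
  # seeded rerun is identical
  res2 <- run_cycle(sc$vae, scorers, sc$ligand_sets, sc$specs, cfg)
  expect_identical(res$log, res2$log)
  expect_identical(res$scored, res2$scored)
})

test_that("the full loop returns a ranked table and honours degenerate configs", {
  sc <- scen5()
  scorers <- cheap_scorers()
  cfg0 <- generation_config(n_cycles = 0L, samples_per_cycle = 32L,
                            top_k = 8L, seed = 1L)
  run0 <- run_polygon(sc$vae, scorers, sc$ligand_sets, sc$specs, cfg0)
  expect_identical(run0$model$params, sc$vae$params)
  expect_equal(nrow(run0$cycles), 0L)
  expect_equal(nrow(run0$ranked), 0L)

  cfg <- generation_config(n_cycles = 2L, samples_per_cycle = 48L,
                           top_k = 12L, finetune_epochs = 1L,
                           finetune_batch = 12L, mode = "multinomial",
                           seed = 42L)
  run <- run_polygon(sc$vae, scorers, sc$ligand_sets, sc$specs, cfg)
  expect_equal(nrow(run$cycles), 2L)
  expect_true(all(diff(run$ranked$R) <= 0))
  expect_equal(anyDuplicated(run$ranked$canonical), 0L)
  expect_true(all(run$ranked$first_seen_cycle %in% 1:2))
  # full reproducibility from the master seed
  run2 <- run_polygon(sc$vae, scorers, sc$ligand_sets, sc$specs, cfg)
  expect_identical(run$cycles, run2$cycles)
  expect_identical(run$ranked, run2$ranked)
})

test_that("component mismatches abort before the first cycle", {
  sc <- scen5()
  scorers <- cheap_scorers()
  cfg <- generation_config(n_cycles = 1L, samples_per_cycle = 8L,
                           top_k = 2L, seed = 1L)
  bad_lig <- list(known_ligand_set("T1", matrix(0, 3L, 7L)),
                  known_ligand_set("T2", matrix(0, 3L, 7L)))
  expect_error(run_polygon(sc$vae, scorers, bad_lig, sc$specs, cfg),
               "latent dimension")
  expect_error(run_polygon(sc$vae, list(1, 2), sc$ligand_sets, sc$specs, cfg),
               "target_scorer")
  expect_error(generation_config(top_k = 100L, samples_per_cycle = 10L))
})
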