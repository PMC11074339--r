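test_that("the ligand-efficiency formula and its inverse are exact", {
  expect_equal(ligand_efficiency(1e-6, 14L), 0.6)
  expect_equal(ligand_efficiency(1e-9, 14L), 0.9)
  expect_equal(ligand_efficiency(1, 27L), 0)
  expect_equal(efficiency_to_pic50(0.6, 14L), 6)
  expect_equal(efficiency_to_pic50(0, 99L), 0)
  set.seed(8)
  y <- runif(50, 0, 1); n <- sample(5:40, 50, replace = TRUE)
  expect_equal(ligand_efficiency(10^(-efficiency_to_pic50(y, n)), n), y,
               tolerance = 1e-12)
  expect_error(ligand_efficiency(0, 10L), "positive")
  expect_error(ligand_efficiency(-1, 10L), "positive")
  expect_error(ligand_efficiency(1e-6, 0L), ">= 1")
  expect_error(efficiency_to_pic50(0.5, 0L), ">= 1")
})

test_that("scorer input validation rejects malformed tables", {
  act <- generate_synthetic_activity(30L, "T1", c(5L, 9L), seed = 1L)
  mixed <- act; mixed$target_id[1] <- "T2"
  expect_error(target_scorer(mixed), "multiple targets")
  kinds <- act; kinds$affinity_kind[1] <- "Kd"
  expect_error(target_scorer(kinds), "affinity kinds")
  expect_error(target_scorer(act[1:10, ]), "at least 20")
})

test_that("the planted SAR is recovered and degrades with noise", {
  corp <- generate_fixture_corpus(4L, 10L, seed = 3L)
  fp <- morgan_fingerprint(corp$smiles)
  freq <- colMeans(fp)
  set.seed(2)
  bits <- sample(which(freq > 0.15 & freq < 0.6), 10L)
  r2 <- vapply(c(0, 0.05, 0.2), function(s) {
    act <- generate_synthetic_activity(200L, "T1", bits, seed = 3L,
                                       molecules = corp, noise_sigma = s)
    sc <- target_scorer(act, n_trees = 200L, seed = 9L, cv_folds = 3L)
    mean(sc$cv_metrics$r2)
  }, numeric(1))
  expect_true(all(diff(r2) < 0))          # monotone degradation
  expect_gt(r2[1], 0.9)
  # training-set fit in the noise-free regime is near-exact
  act0 <- generate_synthetic_activity(200L, "T1", bits, seed = 3L,
                                      molecules = corp, noise_sigma = 0)
  sc0 <- target_scorer(act0, n_trees = 200L, seed = 9L, cv_folds = 0L)
  pred <- predict_efficiency(sc0, act0$smiles)
  expect_lt(mean(abs(pred - act0$y)), 0.05)
  # the two predictors agree through the algebraic identity
  p50 <- predict_pic50(sc0, act0$smiles, act0$heavy_atoms)
  expect_equal(p50, efficiency_to_pic50(pred, act0$heavy_atoms))
  # prediction is invariant to SMILES respelling
  expect_equal(predict_efficiency(sc0, "OCC"),
               predict_efficiency(sc0, "CCO"))
})

test_that("scorer fitting is deterministic under a seed", {
  act <- generate_synthetic_activity(40L, "T1", c(3L, 7L, 11L), seed = 5L)
  s1 <- target_scorer(act, n_trees = 100L, seed = 4L, cv_folds = 2L,
                      mtry = 64L)
  s2 <- target_scorer(act, n_trees = 100L, seed = 4L, cv_folds = 2L,
                      mtry = 64L)
  probe <- unique(act$smiles)[1:5]
  expect_identical(predict_efficiency(s1, probe),
                   predict_efficiency(s2, probe))
  expect_identical(s1$cv_metrics, s2$cv_metrics)
  expect_identical(s1$training_set_hash, s2$training_set_hash)
})

test_that("the synthetic activity generator is internally consistent", {
  a1 <- generate_synthetic_activity(100L, "T1", c(2L, 4L), seed = 3L)
  a2 <- generate_synthetic_activity(100L, "T1", c(2L, 4L), seed = 3L)
  expect_identical(a1, a2)
  expect_equal(ligand_efficiency(a1$affinity_value, a1$heavy_atoms), a1$y,
               tolerance = 1e-12)
  # zero planted effect: y varies only by noise
  null <- generate_synthetic_activity(200L, "T1", c(2L, 4L), seed = 3L,
                                      effect = 0, noise_sigma = 0.05)
  expect_lt(sd(null$y), 0.07)
  expect_equal(mean(null$y), 0.25, tolerance = 0.02)
  # Kd mode produces the same structure with the other label
  kd <- generate_synthetic_activity(30L, "T1", c(2L, 4L), seed = 3L,
                                    affinity_kind = "Kd")
  expect_true(all(kd$affinity_kind == "Kd"))
  expect_s3_class(target_scorer(kd, n_trees = 50L, cv_folds = 0L,
                                mtry = 64L), "target_scorer")
})

test_that("activity CSV units are converted to molar", {
  df <- data.frame(smiles = c("CCO", "CCN"), target_id = "T1",
                   affinity_value = c(1, 500), affinity_kind = "IC50",
                   units = c("uM", "nM"))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  out <- read_activity_csv(p)
  expect_equal(out$affinity_value, c(1e-6, 5e-7))
  df$units <- NULL
  write.csv(df, p, row.names = FALSE)
  expect_warning(read_activity_csv(p), "molar")
  df$affinity_value <- NULL
  write.csv(df, p, row.names = FALSE)
  expect_error(suppressWarnings(read_activity_csv(p)), "columns")
})
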