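test_that("half-Gaussian scaling matches its closed form on both sides", {
  mx <- reward_spec("le_target1", "maximize", mu = 0.4, sigma = 0.1)
  expect_equal(normalize_half_gaussian(0.4, mx), 1)
  expect_equal(normalize_half_gaussian(0.3, mx), exp(-0.5))
  expect_equal(normalize_half_gaussian(0.9, mx), 1)
  mn <- reward_spec("sa", "minimize", mu = 4, sigma = 1)
  expect_equal(normalize_half_gaussian(4, mn), 1)
  expect_equal(normalize_half_gaussian(5, mn), exp(-0.5))
  expect_equal(normalize_half_gaussian(1, mn), 1)
})

test_that("normalization is monotone, bounded and direction-aware", {
  grid <- seq(-3, 3, length.out = 201)
  mx <- reward_spec("qed", "maximize", mu = 0.5, sigma = 0.7)
  vx <- normalize_half_gaussian(grid, mx)
  expect_true(all(diff(vx) >= 0))
  expect_true(all(vx >= 0 & vx <= 1))
  expect_true(all(vx[grid >= 0.5] == 1))
  mn <- reward_spec("dist_target1", "minimize", mu = 0.5, sigma = 0.7)
  vn <- normalize_half_gaussian(grid, mn)
  expect_true(all(diff(vn) <= 0))
  expect_true(all(vn[grid <= 0.5] == 1))
})

test_that("distance rewards agree with brute-force oracles", {
  set.seed(6)
  E <- matrix(rnorm(40 * 5), 40, 5)
  v <- rnorm(5)
  d_all <- sqrt(colSums((t(E) - v)^2))
  # k = set size: plain average over all ligands
  expect_equal(distance_reward(v, known_ligand_set("t", E, k = 40L)),
               mean(d_all))
  # k = 20: average of the 20 smallest distances from a full sort
  expect_equal(distance_reward(v, known_ligand_set("t", E, k = 20L)),
               mean(sort(d_all)[1:20]))
  # min statistic and the zero-distance degenerate case
  expect_equal(distance_reward(v, known_ligand_set("t", E, k = 20L),
                               stat = "min"), min(d_all))
  expect_equal(distance_reward(v, known_ligand_set("t", rbind(v), k = 1L)), 0)
  expect_error(distance_reward(v, known_ligand_set("t", E[, 1:3], k = 5L)),
               "dimension")
  # k is capped at the set size
  expect_equal(known_ligand_set("t", E[1:4, ], k = 20L)$k, 4L)
})

test_that("SA scores are deterministic, in range, ordered by complexity", {
  smis <- c("CCCCCC", "C1C2C3C1C1C2C31", "C1C2CC3CC1CC(C2)C3", "CCOCC")
  s1 <- sa_score(smis); s2 <- sa_score(smis)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 10))
  expect_lt(s1[1], s1[2])    # hexane easier than a caged polycycle
  expect_lt(s1[4], s1[3])
  expect_true(is.na(sa_score("C1CC")))
})

test_that("drug-likeness scores stay in [0,1] and favour drug-like size", {
  corp <- generate_fixture_corpus(3L, 8L, seed = 4L)
  q <- qed_score(corp$smiles)
  expect_true(all(q >= 0 & q <= 1))
  expect_identical(q, qed_score(corp$smiles))
  # a reasonable small drug beats a C20 grease ball
  q2 <- qed_score(c("CC(=O)Nc1ccc(O)cc1", "CCCCCCCCCCCCCCCCCCCC"))
  expect_gt(q2[1], q2[2])
})

test_that("candidate scoring aggregates six normalized rewards", {
  sc <- scen5()
  scorers <- cheap_scorers()
  smis <- sc$corpus$smiles[c(1, 25, 50, 75)]
  tab <- score_candidates(smis, sc$vae, scorers, sc$ligand_sets, sc$specs)
  expect_equal(nrow(tab), 4L)
  rn <- as.matrix(tab[, paste0("rn", 1:6)])
  expect_true(all(rn >= 0 & rn <= 1))
  expect_equal(tab$R, rowMeans(rn), tolerance = 1e-12)
  # R is the plain mean: permutation-invariant and bounded by components
  expect_true(all(tab$R <= apply(rn, 1L, max) + 1e-12))
  expect_true(all(tab$R >= apply(rn, 1L, min) - 1e-12))
  # invalid candidates are dropped, not scored as zero
  tab2 <- score_candidates(c(smis[1], "C1CC", "((("), sc$vae, scorers,
                           sc$ligand_sets, sc$specs)
  expect_equal(nrow(tab2), 1L)
  expect_equal(attr(tab2, "n_unscorable"), 2L)
})

test_that("forcing all six normalized rewards to their extremes bounds R", {
  sc <- scen5()
  scorers <- cheap_scorers()
  smi <- sc$corpus$smiles[1]
  # specs satisfied everywhere: every reward normalizes to 1
  loose <- list(
    le_target1 = reward_spec("le_target1", "maximize", -1e6, 1),
    le_target2 = reward_spec("le_target2", "maximize", -1e6, 1),
    dist_target1 = reward_spec("dist_target1", "minimize", 1e6, 1),
    dist_target2 = reward_spec("dist_target2", "minimize", 1e6, 1),
    sa = reward_spec("sa", "minimize", 1e6, 1),
    qed = reward_spec("qed", "maximize", -1e6, 1))
  tab <- score_candidates(smi, sc$vae, scorers, sc$ligand_sets, loose)
  expect_equal(tab$R, 1)
  # three rewards satisfied, three pushed to ~0: R -> 0.5
  half <- loose
  half$le_target1 <- reward_spec("le_target1", "maximize", 1e3, 1e-6)
  half$dist_target1 <- reward_spec("dist_target1", "minimize", -1e3, 1e-6)
  half$sa <- reward_spec("sa", "minimize", -1e3, 1e-6)
  tab2 <- score_candidates(smi, sc$vae, scorers, sc$ligand_sets, half)
  expect_equal(tab2$R, 0.5, tolerance = 1e-6)
})
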