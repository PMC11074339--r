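make_records <- function(smiles, targets, affinities) {
  data.frame(smiles = smiles, target_id = targets,
             affinity_value = affinities, stringsAsFactors = FALSE)
}

test_that("dual-assay filtering keeps exactly-two-target compounds", {
  recs <- make_records(
    c("CCO", "CCO", "CCN", "CCN", "CCN", "CCC", "CCCC", "CCCC"),
    c("A", "B", "A", "B", "C", "A", "A", "B"),
    10^-(6:13))
  trip <- filter_dual_assayed(recs, canonicalize = FALSE)
  # CCN is on three targets, CCC on one: both excluded
  expect_equal(sort(trip$smiles), c("CCCC", "CCO"))
  expect_true(all(trip$target1 < trip$target2))
  # compounds from the scorer training set are removed
  trip2 <- filter_dual_assayed(recs, training_smiles = "CCO",
                               canonicalize = FALSE)
  expect_equal(trip2$smiles, "CCCC")
  # training match is by canonical structure, not spelling
  trip3 <- filter_dual_assayed(recs, training_smiles = "OCC")
  expect_false("CCO" %in% trip3$smiles)
})

test_that("replicate measurements aggregate by the configured statistic", {
  recs <- make_records(rep("CCO", 4), c("A", "A", "B", "B"),
                       c(1e-6, 1e-8, 1e-5, 1e-5))
  g <- filter_dual_assayed(recs, canonicalize = FALSE)
  expect_equal(g$observed1, 1e-7)          # geometric mean
  m <- filter_dual_assayed(recs, aggregate = "min", canonicalize = FALSE)
  expect_equal(m$observed1, 1e-8)
})

test_that("dual classification is strict at the threshold", {
  trip <- data.frame(
    observed1 = c(5e-7, 2e-6, 5e-7), observed2 = c(9e-7, 1e-7, 1e-6),
    predicted1 = c(5e-7, 1e-6, 9e-7), predicted2 = c(9e-7, 5e-7, 1e-9))
  cl <- classify_dual(trip, threshold = 1e-6)
  expect_equal(cl$observed_dual, c(TRUE, FALSE, FALSE))
  expect_equal(cl$predicted_dual, c(TRUE, FALSE, TRUE))
  expect_error(classify_dual(trip[, -1]), "observed1")
  trip$predicted1[2] <- NA
  expect_error(classify_dual(trip), "predicted1")
})

test_that("the contingency table reproduces hand-computed statistics", {
  lab <- function(tp, fp, fn, tn) {
    data.frame(observed_dual = rep(c(TRUE, FALSE, TRUE, FALSE),
                                   c(tp, fp, fn, tn)),
               predicted_dual = rep(c(TRUE, TRUE, FALSE, FALSE),
                                    c(tp, fp, fn, tn)))
  }
  tb <- tabulate_dual(lab(90L, 10L, 10L, 90L))
  expect_equal(tb$odds_ratio, 81)
  expect_equal(tb$tp + tb$fp + tb$fn + tb$tn, 200L)
  expect_equal(tb$accuracy, 0.9)
  expect_false(tb$continuity_corrected)
  expect_lt(tb$fisher_p, 1e-10)
  expect_lt(tb$chi2_p, 1e-10)
  # identical rows: independence, odds ratio 1
  expect_equal(tabulate_dual(lab(45L, 45L, 45L, 45L))$odds_ratio, 1)
  # swapping both row and column labels leaves the odds ratio unchanged
  expect_equal(tabulate_dual(lab(10L, 40L, 20L, 30L))$odds_ratio,
               tabulate_dual(lab(30L, 20L, 40L, 10L))$odds_ratio)
  # zero margins flag the continuity correction
  tb0 <- tabulate_dual(lab(5L, 0L, 0L, 5L))
  expect_true(tb0$continuity_corrected)
  expect_true(is.finite(tb0$odds_ratio))
})

test_that("a perfect predictor yields the identity confusion structure", {
  set.seed(12)
  aff1 <- 10^-runif(60, 4, 9); aff2 <- 10^-runif(60, 4, 9)
  trip <- data.frame(observed1 = aff1, observed2 = aff2,
                     predicted1 = aff1, predicted2 = aff2)
  for (th in 10^-(5:8)) {
    tb <- tabulate_dual(classify_dual(trip, th))
    expect_equal(tb$fp, 0L)
    expect_equal(tb$fn, 0L)
    expect_equal(tb$accuracy, 1)
  }
})

test_that("threshold sweeps hit the degenerate limits monotonically", {
  set.seed(13)
  trip <- data.frame(observed1 = 10^-runif(80, 4, 9),
                     observed2 = 10^-runif(80, 4, 9),
                     predicted1 = 10^-runif(80, 4, 9),
                     predicted2 = 10^-runif(80, 4, 9))
  sw <- threshold_sweep(trip, c(1, 10^-(4:12), 1e-20))
  # everything active at a huge threshold; nothing at a vanishing one
  expect_equal(sw$recall[1], 1)
  expect_equal(sw$fpr[1], 1)
  expect_equal(sw$recall[nrow(sw)], 0)
  expect_equal(sw$tp[nrow(sw)] + sw$fp[nrow(sw)], 0L)
  # predicted-positive count shrinks as the threshold tightens
  expect_true(all(diff(sw$tp + sw$fp) <= 0))
  # cells always conserve the triplet count
  expect_true(all(sw$tp + sw$fp + sw$fn + sw$tn == 80L))
})
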