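# Dual-target (polypharmacology) classification benchmark: compounds
# assayed against exactly two targets are classified as dual-active when
# both affinities fall strictly below an activity threshold (1 uM by
# default), observed and predicted labels are tabulated in a 2x2
# contingency table, and agreement is quantified by the odds ratio with
# Fisher-exact and chi-squared p-values.

#' Build dual-assay triplets from an activity table
#'
#' Keeps compounds assayed against exactly two distinct targets and forms
#' one (compound, target1, target2) triplet per compound, with targets
#' ordered lexicographically. Compounds present in the scorer training set
#' are removed (matching on canonical SMILES). Replicate measurements for
#' the same compound-target pair are aggregated by geometric mean
#' (configurable to median or min).
#'
#' @param records activity data.frame (`smiles`, `target_id`,
#'   `affinity_value` in molar).
#' @param training_smiles character vector of SMILES used to train the
#'   scorers (removed from the benchmark); already-canonical input is
#'   matched as-is.
#' @param aggregate how to combine replicate affinities: `"geomean"`,
#'   `"median"` or `"min"`.
#' @param canonicalize canonicalize SMILES before grouping (default TRUE).
#' @return data.frame of triplets: `smiles`, `target1`, `target2`,
#'   `observed1`, `observed2`.
#' @export
filter_dual_assayed <- function(records, training_smiles = character(0),
                                aggregate = c("geomean", "median", "min"),
                                canonicalize = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("smiles", "target_id", "affinity_value") %in% names(records)))
  smi <- records$smiles
  if (canonicalize) {
    can <- canonical_smiles(smi)
    keep <- !is.na(can)
    records <- records[keep, , drop = FALSE]
    records$smiles <- can[keep]
    if (length(training_smiles) > 0L) {
      tcan <- canonical_smiles(training_smiles)
      training_smiles <- tcan[!is.na(tcan)]
    }
  }
  agg_fun <- switch(aggregate,
                    geomean = function(x) exp(mean(log(x))),
                    median = stats::median,
                    min = min)
  key <- paste(records$smiles, records$target_id, sep = "\r")
  aff <- tapply(records$affinity_value, key, agg_fun)
  parts <- strsplit(names(aff), "\r", fixed = TRUE)
  pair <- data.frame(smiles = vapply(parts, `[`, "", 1L),
                     target_id = vapply(parts, `[`, "", 2L),
                     affinity = as.numeric(aff),
                     stringsAsFactors = FALSE)
  n_targets <- table(pair$smiles)
  dual <- names(n_targets)[n_targets == 2L]
  dual <- setdiff(dual, training_smiles)
  if (length(dual) == 0L) {
    return(data.frame(smiles = character(0), target1 = character(0),
                      target2 = character(0), observed1 = numeric(0),
                      observed2 = numeric(0)))
  }
  pair <- pair[pair$smiles %in% dual, , drop = FALSE]
  pair <- pair[order(pair$smiles, pair$target_id, method = "radix"), ,
               drop = FALSE]
  odd <- seq(1L, nrow(pair), by = 2L)
  out <- data.frame(
    smiles = pair$smiles[odd],
    target1 = pair$target_id[odd],
    target2 = pair$target_id[odd + 1L],
    observed1 = pair$affinity[odd],
    observed2 = pair$affinity[odd + 1L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify triplets as dual-active
#'
#' A side (observed or predicted) is dual-active iff BOTH its affinities
#' are strictly below the threshold; a boundary value counts as inactive.
#'
#' @param triplets data.frame with `observed1`, `observed2`, `predicted1`,
#'   `predicted2` (molar affinities).
#' @param threshold activity threshold in molar units (default 1e-6, i.e.
#'   1 uM).
#' @return the input with logical columns `observed_dual` and
#'   `predicted_dual` appended.
#' @export
classify_dual <- function(triplets, threshold = 1e-6) {
  need <- c("observed1", "observed2", "predicted1", "predicted2")
  missing_col <- setdiff(need, names(triplets))
  if (length(missing_col) > 0L) {
    stop("missing affinity column(s): ", paste(missing_col, collapse = ", "))
  }
  for (cc in need) {
    if (anyNA(triplets[[cc]])) {
      stop(sprintf("missing values in %s", cc))
    }
  }
  stopifnot(threshold > 0)
  triplets$observed_dual <- triplets$observed1 < threshold &
    triplets$observed2 < threshold
  triplets$predicted_dual <- triplets$predicted1 < threshold &
    triplets$predicted2 < threshold
  triplets
}

#' Tabulate observed vs predicted dual activity
#'
#' Builds the 2x2 contingency table (true/false positives/negatives), the
#' sample (cross-product) odds ratio, and p-values from the two-sided
#' Fisher exact test and the chi-squared test on the same table. With a
#' zero cell the odds ratio uses the Haldane-Anscombe +0.5 continuity
#' correction and is flagged.
#'
#' @param triplets output of [classify_dual()].
#' @return object of class `dual_contingency`: list with `tp`, `fp`, `fn`,
#'   `tn`, `odds_ratio`, `fisher_p`, `chi2_p`, `accuracy`,
#'   `balanced_accuracy`, `continuity_corrected`.
#' @export
tabulate_dual <- function(triplets) {
  stopifnot(nrow(triplets) > 0L,
            all(c("observed_dual", "predicted_dual") %in% names(triplets)))
  obs <- triplets$observed_dual
  pred <- triplets$predicted_dual
  tp <- sum(obs & pred); fp <- sum(!obs & pred)
  fn <- sum(obs & !pred); tn <- sum(!obs & !pred)
  cc <- any(c(tp, fp, fn, tn) == 0L)
  or <- if (cc) {
    ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
  } else {
    (as.numeric(tp) * tn) / (as.numeric(fp) * fn)
  }
  m <- matrix(c(tp, fn, fp, tn), 2L)
  fisher_p <- stats::fisher.test(m)$p.value
  chi2_p <- tryCatch(
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    odds_ratio = or, fisher_p = fisher_p, chi2_p = chi2_p,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    balanced_accuracy = mean(c(sens, spec)),
    continuity_corrected = cc
  ), class = "dual_contingency")
}

#' @export
print.dual_contingency <- function(x, ...) {
  cat("Dual-activity contingency table\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L,
              dimnames = list(observed = c("dual", "not dual"),
                              predicted = c("dual", "not dual")))
  print(m)
  cat(sprintf("odds ratio %.3f%s | Fisher p %.3g | chi-squared p %.3g\n",
              x$odds_ratio,
              if (x$continuity_corrected) " (continuity-corrected)" else "",
              x$fisher_p, x$chi2_p))
  cat(sprintf("accuracy %.3f | balanced accuracy %.3f\n",
              x$accuracy, x$balanced_accuracy))
  invisible(x)
}

#' Sweep the activity threshold
#'
#' Re-classifies and re-tabulates the triplets at each threshold and
#' reports precision, recall (TPR) and FPR — the points of the
#' precision-recall and ROC curves.
#'
#' @param triplets data.frame with observed and predicted affinities.
#' @param thresholds positive molar thresholds (default the decade grid
#'   1e-5 .. 1e-10 M).
#' @return data.frame with one row per threshold: `threshold`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `tpr`, `fpr`, `accuracy`.
#' @export
threshold_sweep <- function(triplets, thresholds = 10^-(5:10)) {
  stopifnot(all(thresholds > 0), !anyDuplicated(thresholds))
  do.call(rbind, lapply(thresholds, function(th) {
    cl <- classify_dual(triplets, threshold = th)
    tb <- tabulate_dual(cl)
    data.frame(
      threshold = th,
      tp = tb$tp, fp = tb$fp, fn = tb$fn, tn = tb$tn,
      # conventions at empty margins: with no observed positives recall is
      # 0 (nothing can be recovered); with no observed negatives FPR is 1
      # (every predicted positive is "false" relative to an empty class)
      precision = if (tb$tp + tb$fp > 0L) tb$tp / (tb$tp + tb$fp) else NA_real_,
      recall = if (tb$tp + tb$fn > 0L) tb$tp / (tb$tp + tb$fn) else 0,
      tpr = if (tb$tp + tb$fn > 0L) tb$tp / (tb$tp + tb$fn) else 0,
      fpr = if (tb$fp + tb$tn > 0L) tb$fp / (tb$fp + tb$tn) else 1,
      accuracy = tb$accuracy
    )
  }))
}

#' Predict dual-target affinities for triplets
#'
#' Runs the two per-target scorers on each triplet's compound and appends
#' `predicted1` / `predicted2` as molar affinities (10^-pIC50).
#'
#' @param triplets data.frame from [filter_dual_assayed()].
#' @param scorer1,scorer2 fitted `target_scorer`s for target1/target2.
#' @return the triplets with predicted affinity columns appended.
#' @export
predict_dual <- function(triplets, scorer1, scorer2) {
  heavy <- heavy_atom_count(triplets$smiles)
  p1 <- predict_pic50(scorer1, triplets$smiles, heavy)
  p2 <- predict_pic50(scorer2, triplets$smiles, heavy)
  triplets$predicted1 <- 10^(-p1)
  triplets$predicted2 <- 10^(-p2)
  triplets
}
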