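# Per-target ligand-efficiency regressors: a 1000-tree random forest over
# 2048-bit Morgan fingerprints predicting ligand efficiency
# y = 1.4 * (-log10(affinity) / N), with seeded five-fold cross-validation.

#' Ligand efficiency
#'
#' `y = 1.4 * (-log10(affinity) / N)`: potency normalized by molecular
#' size, with `affinity` in molar units (IC50 or Kd) and `N` the number of
#' non-hydrogen atoms.
#'
#' @param affinity_value positive affinity in molar units.
#' @param heavy_atoms positive integer atom count.
#' @return ligand efficiency (vectorized).
#' @examples
#' ligand_efficiency(1e-6, 14)   # 0.6
#' ligand_efficiency(1e-9, 14)   # 0.9
#' @export
ligand_efficiency <- function(affinity_value, heavy_atoms) {
  if (any(!is.finite(affinity_value)) || any(affinity_value <= 0)) {
    stop("affinity_value must be positive (molar units)")
  }
  if (any(heavy_atoms < 1L)) stop("heavy_atoms must be >= 1")
  1.4 * (-log10(affinity_value) / heavy_atoms)
}

#' Convert ligand efficiency back to pIC50
#'
#' Inverse of [ligand_efficiency()]: `pIC50 = y * N / 1.4`
#' (= -log10 of the affinity in molar units).
#'
#' @param y ligand efficiency.
#' @param heavy_atoms positive integer atom count.
#' @return pIC50 (vectorized).
#' @export
efficiency_to_pic50 <- function(y, heavy_atoms) {
  if (any(heavy_atoms < 1L)) stop("heavy_atoms must be >= 1")
  y * heavy_atoms / 1.4
}

#' Featurize a molecule for target scoring
#'
#' 2048-bit Morgan (circular, radius 2) fingerprint; see
#' [morgan_fingerprint()]. Accepts a vector of SMILES.
#'
#' @param smiles character vector.
#' @return integer matrix (rows = molecules, 2048 columns).
#' @export
featurize <- function(smiles) {
  fp <- morgan_fingerprint(smiles)
  if (anyNA(fp)) {
    bad <- which(apply(is.na(fp), 1L, any))
    stop(sprintf("unparseable SMILES at position(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  fp
}

#' Fit a per-target ligand-efficiency scorer
#'
#' Trains a 1000-tree random-forest regressor from Morgan fingerprints to
#' ligand efficiency for one target and one affinity kind (IC50 or Kd; the
#' Kd variant is the configuration used for binding-constant retraining).
#' Five-fold cross-validation metrics with seeded fold assignment are
#' computed and stored.
#'
#' @param records data.frame with columns `smiles`, `target_id`,
#'   `affinity_value` (molar), `affinity_kind` (`"IC50"` or `"Kd"`), and
#'   optionally `heavy_atoms` (computed when absent).
#' @param n_trees forest size (default 1000).
#' @param seed integer seed for forest growth and fold assignment.
#' @param cv_folds number of CV folds (default 5; 0 skips CV).
#' @param mtry candidate features per split. The default considers every
#'   feature at every split and grows leaves to purity, the behaviour of
#'   the reference random-forest regressor this module mirrors; set a
#'   smaller value (for example `sqrt(p)`) to trade accuracy for speed.
#' @param min_node_size minimal node size (default 1).
#' @return object of class `target_scorer`.
#' @export
target_scorer <- function(records, n_trees = 1000L, seed = 1L, cv_folds = 5L,
                          mtry = NULL, min_node_size = 1L) {
  req <- c("smiles", "target_id", "affinity_value", "affinity_kind")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) < 20L) stop("need at least 20 activity records")
  if (length(unique(records$target_id)) != 1L) {
    stop("records mix multiple targets; fit one scorer per target")
  }
  if (length(unique(records$affinity_kind)) != 1L) {
    stop("records mix affinity kinds (IC50 vs Kd)")
  }
  if (any(records$affinity_value <= 0)) stop("non-positive affinity values")
  if (is.null(records$heavy_atoms)) {
    records$heavy_atoms <- heavy_atom_count(records$smiles)
  }
  y <- ligand_efficiency(records$affinity_value, records$heavy_atoms)
  X <- featurize(records$smiles)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  # constant (all-0 / all-1) fingerprint bits can never be split on; they
  # are dropped before fitting, which preserves the model while removing
  # most of the per-node feature-scan cost on sparse corpora
  on_counts <- colSums(X)
  keep_bits <- which(on_counts > 0L & on_counts < nrow(X))
  if (length(keep_bits) == 0L) stop("all fingerprint bits are constant")
  X <- X[, keep_bits, drop = FALSE]
  dat <- data.frame(y = y, X)
  if (is.null(mtry)) mtry <- ncol(X)

  cv <- NULL
  if (cv_folds >= 2L) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(dat)))
    cv <- do.call(rbind, lapply(seq_len(cv_folds), function(k) {
      tr <- dat[fold != k, , drop = FALSE]
      te <- dat[fold == k, , drop = FALSE]
      fit <- ranger::ranger(y ~ ., data = tr, num.trees = n_trees,
                            seed = seed + k, num.threads = 1L, verbose = FALSE,
                            mtry = mtry, min.node.size = min_node_size)
      pred <- stats::predict(fit, te)$predictions
      ss_res <- sum((te$y - pred)^2)
      ss_tot <- sum((te$y - mean(te$y))^2)
      data.frame(fold = k, n = nrow(te),
                 r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(mean((te$y - pred)^2)))
    }))
  }
  fit <- ranger::ranger(y ~ ., data = dat, num.trees = n_trees,
                        seed = seed, num.threads = 1L, verbose = FALSE,
                        mtry = mtry, min.node.size = min_node_size)
  structure(list(
    target_id = records$target_id[1],
    affinity_kind = records$affinity_kind[1],
    model = fit,
    n_trees = n_trees,
    n_records = nrow(records),
    seed = seed,
    feature_bits = keep_bits,
    cv_metrics = cv,
    training_set_hash = corpus_hash(sort(records$smiles)),
    training_smiles = unique(records$smiles),
    hyperparameters = list(mtry = fit$mtry, min_node_size = fit$min.node.size,
                           splitrule = fit$splitrule)
  ), class = "target_scorer")
}

# Stable content hash of a character vector (md5 of the serialized text).
corpus_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Predict ligand efficiency / pIC50 for molecules
#'
#' `predict_efficiency` returns the forest's ligand-efficiency prediction;
#' `predict_pic50` converts it through the exact inverse map using each
#' molecule's heavy-atom count.
#'
#' @param scorer a fitted `target_scorer`.
#' @param smiles character vector of SMILES.
#' @param heavy_atoms optional heavy-atom counts (computed when absent).
#' @return numeric vector.
#' @export
predict_efficiency <- function(scorer, smiles) {
  stopifnot(inherits(scorer, "target_scorer"))
  X <- featurize(smiles)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  X <- X[, scorer$feature_bits, drop = FALSE]
  stats::predict(scorer$model, data.frame(X))$predictions
}

#' @rdname predict_efficiency
#' @export
predict_pic50 <- function(scorer, smiles, heavy_atoms = NULL) {
  if (is.null(heavy_atoms)) heavy_atoms <- heavy_atom_count(smiles)
  efficiency_to_pic50(predict_efficiency(scorer, smiles), heavy_atoms)
}

#' @export
predict.target_scorer <- function(object, newdata,
                                  type = c("efficiency", "pic50"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- newdata$smiles
  if (type == "efficiency") predict_efficiency(object, newdata)
  else predict_pic50(object, newdata)
}

#' @export
print.target_scorer <- function(x, ...) {
  cat(sprintf("Target scorer for %s (%s, %d records, %d trees)\n",
              x$target_id, x$affinity_kind, x$n_records, x$n_trees))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  5-fold CV: R2 = %.3f, RMSE = %.4f\n",
                mean(x$cv_metrics$r2), mean(x$cv_metrics$rmse)))
  }
  invisible(x)
}

#' @export
summary.target_scorer <- function(object, ...) {
  out <- list(target_id = object$target_id,
              affinity_kind = object$affinity_kind,
              n_records = object$n_records,
              cv_metrics = object$cv_metrics,
              hyperparameters = object$hyperparameters)
  class(out) <- "summary.target_scorer"
  out
}

#' @export
print.summary.target_scorer <- function(x, ...) {
  cat(sprintf("Target scorer: %s (%s), %d records\n",
              x$target_id, x$affinity_kind, x$n_records))
  if (!is.null(x$cv_metrics)) print(x$cv_metrics, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic activity table with a planted SAR
#'
#' Draws molecules from a fixture corpus and assigns affinities so that
#' ligand efficiency follows a linear map of designated fingerprint bits
#' plus Gaussian noise: `y = base + sum(beta * bit) + noise`. The affinity
#' is back-computed so that `y = 1.4 * (-log10(affinity) / N)` holds
#' exactly for every record.
#'
#' @param n number of records.
#' @param target_id target label.
#' @param planted_bits integer indices (1-based, in 1..2048) of the
#'   informative fingerprint bits.
#' @param seed integer seed.
#' @param molecules optional data.frame with `smiles` and `heavy_atoms`
#'   (defaults to a 4-family, 40-molecule fixture corpus derived from
#'   `seed`).
#' @param base_efficiency intercept of the planted map.
#' @param effect per-bit coefficient (scalar or one per planted bit).
#' @param noise_sigma Gaussian noise standard deviation on y.
#' @param affinity_kind `"IC50"` or `"Kd"`.
#' @return data.frame of activity records including the true `y`.
#' @export
generate_synthetic_activity <- function(n, target_id, planted_bits, seed = 1L,
                                        molecules = NULL,
                                        base_efficiency = 0.25,
                                        effect = 0.1,
                                        noise_sigma = 0.05,
                                        affinity_kind = "IC50") {
  stopifnot(n >= 1L, all(planted_bits >= 1L), all(planted_bits <= 2048L))
  if (is.null(molecules)) {
    molecules <- generate_fixture_corpus(4L, 10L, seed = seed)
  }
  fp <- morgan_fingerprint(molecules$smiles)
  set.seed(seed)
  pick <- sample.int(nrow(molecules), n, replace = n > nrow(molecules))
  beta <- rep_len(effect, length(planted_bits))
  signal <- as.numeric(fp[pick, planted_bits, drop = FALSE] %*% beta)
  y <- base_efficiency + signal + stats::rnorm(n, 0, noise_sigma)
  heavy <- molecules$heavy_atoms[pick]
  affinity <- 10^(-(y * heavy / 1.4))
  data.frame(
    smiles = molecules$smiles[pick],
    target_id = target_id,
    affinity_value = affinity,
    affinity_kind = affinity_kind,
    heavy_atoms = heavy,
    y = y,
    stringsAsFactors = FALSE
  )
}

#' Read / write activity tables
#'
#' CSV tables with header columns `smiles`, `target_id`, `affinity_value`,
#' `affinity_kind` and optional `units` (`M`, `mM`, `uM`, `nM`, `pM`);
#' values are converted to molar. Without a units column, molar is assumed
#' and a warning is issued.
#'
#' @param path CSV file path.
#' @return data.frame of activity records in molar units.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("smiles", "target_id", "affinity_value", "affinity_kind")
  if (!all(req %in% names(df))) {
    stop("activity CSV must have columns: ", paste(req, collapse = ", "))
  }
  if ("units" %in% names(df)) {
    mult <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
    u <- df$units
    if (any(!u %in% names(mult))) {
      stop("unrecognized units: ", paste(unique(setdiff(u, names(mult))),
                                         collapse = ", "))
    }
    df$affinity_value <- df$affinity_value * mult[u]
    df$units <- NULL
  } else {
    warning("no units column; assuming affinity_value is in molar units")
  }
  df
}

#' @rdname read_activity_csv
#' @param records data.frame of activity records.
#' @export
write_activity_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
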