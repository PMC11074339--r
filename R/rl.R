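# The reinforcement loop: sample latent coordinates from the prior, decode
# to SMILES, curate and deduplicate, score against the six rewards, keep the
# top-k, fine-tune the VAE on them, repeat. Fine-tuning re-maps the prior's
# mass onto high-reward regions of the embedding, so successive cycles
# sample progressively better candidates.

#' Generation (reinforcement) configuration
#'
#' Full-scale defaults: 200 cycles of 8192 sampled coordinates, the top
#' 4096 candidates fine-tuning the VAE for 2 epochs at batch size 512.
#'
#' @param n_cycles number of reinforcement cycles.
#' @param samples_per_cycle latent draws per cycle.
#' @param top_k candidates kept for fine-tuning (must not exceed
#'   `samples_per_cycle`).
#' @param finetune_epochs,finetune_batch fine-tuning settings per cycle.
#' @param finetune_lr fine-tuning learning rate.
#' @param mode decoding mode (`"multinomial"` explores; `"argmax"` is
#'   deterministic).
#' @param seed master seed; every cycle derives its own latent-draw,
#'   decoding and fine-tuning seeds from it.
#' @return object of class `generation_config`.
#' @export
generation_config <- function(n_cycles = 200L, samples_per_cycle = 8192L,
                              top_k = 4096L, finetune_epochs = 2L,
                              finetune_batch = 512L, finetune_lr = 3e-4,
                              mode = c("multinomial", "argmax"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 0L, samples_per_cycle >= 1L, top_k >= 1L,
            top_k <= samples_per_cycle, finetune_epochs >= 0L,
            finetune_batch >= 1L)
  structure(list(n_cycles = as.integer(n_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 top_k = as.integer(top_k),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_batch = as.integer(finetune_batch),
                 finetune_lr = finetune_lr,
                 mode = mode, seed = as.integer(seed)),
            class = "generation_config")
}

#' Select the top-scoring candidates
#'
#' Returns the `k` candidates with the highest aggregate reward, exactly as
#' a full descending sort truncated at `k`. Ties at the boundary are broken
#' by lexicographically smallest SMILES (C locale), so selection is
#' deterministic.
#'
#' @param candidates data.frame with columns `smiles` and `R`.
#' @param k number to keep; if `k` exceeds the candidate count, all are
#'   returned with a warning.
#' @return the selected rows, ordered by decreasing `R`.
#' @export
select_top_k <- function(candidates, k) {
  stopifnot(is.data.frame(candidates),
            all(c("smiles", "R") %in% names(candidates)), k >= 1L)
  if (k > nrow(candidates)) {
    warning(sprintf("k = %d exceeds %d candidates; returning all",
                    k, nrow(candidates)))
    k <- nrow(candidates)
  }
  ord <- order(-candidates$R, candidates$smiles, method = "radix")
  out <- candidates[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a component seed from a master seed
#'
#' One master seed fans out to per-component seeds through a deterministic
#' label hash, so each sub-run (latent sampling, fine-tuning, fold
#' assignment, scenario expansion) is independently reproducible. Results
#' stay within the 32-bit integer range R's RNG accepts.
#'
#' @param master integer master seed.
#' @param label character label naming the component.
#' @return integer seed in [1, 2147483562].
#' @export
derive_seed <- function(master, label) {
  x <- utf8ToInt(label)
  h <- sum(x * (seq_along(x) %% 31 + 1)) %% 1000003L
  as.integer((as.numeric(master) * 7919 + h) %% 2147483562) + 1L
}

#' Run one reinforcement cycle
#'
#' Samples `samples_per_cycle` latent coordinates from the standard-normal
#' prior, decodes them, curates and deduplicates the resulting SMILES,
#' scores survivors against the six rewards, selects the top `top_k`, and
#' fine-tunes the VAE on them. A cycle with zero valid candidates leaves
#' the model unchanged.
#'
#' @param model a fitted `smiles_vae`.
#' @param scorers,ligand_sets,specs as in [score_candidates()].
#' @param cfg a [generation_config()].
#' @param cycle_index 1-based index (enters seed derivation and the log).
#' @return list with `model` (possibly updated) and `log` (a one-row
#'   data.frame: counts, reward summary) plus `scored` (the scored
#'   candidate table) and `top` (selected molecules).
#' @export
run_cycle <- function(model, scorers, ligand_sets, specs, cfg,
                      cycle_index = 1L) {
  stopifnot(inherits(cfg, "generation_config"))
  cyc_seed <- derive_seed(cfg$seed, paste0("cycle", cycle_index))
  samp <- sample_molecules(model, cfg$samples_per_cycle,
                           generation_context(cfg$mode), seed = cyc_seed)
  n_sampled <- nrow(samp)
  valid_smiles <- samp$smiles[samp$valid]
  n_valid <- length(valid_smiles)
  # canonical SMILES is the deduplication key, but the decoded spelling is
  # what gets scored and fine-tuned on: it is guaranteed to tokenize under
  # the model's vocabulary, while the canonical respelling is not
  canon <- canonical_smiles(valid_smiles)
  ok <- !is.na(canon)
  valid_smiles <- valid_smiles[ok]; canon <- canon[ok]
  first <- !duplicated(canon)
  uniq <- valid_smiles[first]
  uniq_canon <- canon[first]
  n_unique <- length(uniq)
  scored <- if (n_unique > 0L) {
    score_candidates(uniq, model, scorers, ligand_sets, specs)
  } else {
    data.frame(smiles = character(0), R = numeric(0))
  }
  if (nrow(scored) > 0L) {
    scored$canonical <- uniq_canon[match(scored$smiles, uniq)]
  }
  n_scored <- nrow(scored)
  top <- NULL
  if (n_scored > 0L) {
    top <- select_top_k(scored, min(cfg$top_k, n_scored))
    if (cfg$finetune_epochs > 0L) {
      model <- fine_tune(model, top$smiles, epochs = cfg$finetune_epochs,
                         batch_size = cfg$finetune_batch,
                         learning_rate = cfg$finetune_lr,
                         seed = derive_seed(cfg$seed,
                                            paste0("finetune", cycle_index)))
    }
  }
  log <- data.frame(
    cycle = cycle_index,
    n_sampled = n_sampled, n_valid = n_valid,
    n_unique = n_unique, n_scored = n_scored,
    mean_R = if (n_scored > 0L) mean(scored$R) else NA_real_,
    median_R = if (n_scored > 0L) stats::median(scored$R) else NA_real_,
    max_R = if (n_scored > 0L) max(scored$R) else NA_real_
  )
  list(model = model, log = log, scored = scored, top = top)
}

#' Run the full reinforcement generation loop
#'
#' Executes `n_cycles` reinforcement cycles and aggregates every scored
#' candidate into a ranked compound table (distinct canonical SMILES,
#' keeping each compound's maximum reward and first cycle of appearance).
#'
#' @param model trained base `smiles_vae`.
#' @param scorers list of two fitted `target_scorer`s.
#' @param ligand_sets list of two [known_ligand_set()]s.
#' @param specs six [reward_spec()]s (see [default_reward_specs()]).
#' @param cfg a [generation_config()].
#' @param verbose print a one-line summary per cycle.
#' @return object of class `polygon_run`: list with `model` (final),
#'   `cycles` (per-cycle log data.frame), `ranked` (ranked compound table
#'   with `smiles`, `r1`..`r6`, `R`, `first_seen_cycle`), `config`, and
#'   provenance (`seed`, reward specs, scorer hashes).
#' @export
run_polygon <- function(model, scorers, ligand_sets, specs, cfg,
                        verbose = FALSE) {
  stopifnot(inherits(model, "smiles_vae"), inherits(cfg, "generation_config"))
  if (!inherits(scorers[[1]], "target_scorer") ||
      !inherits(scorers[[2]], "target_scorer")) {
    stop("scorers must be two fitted target_scorer objects")
  }
  if (!inherits(ligand_sets[[1]], "known_ligand_set") ||
      !inherits(ligand_sets[[2]], "known_ligand_set")) {
    stop("ligand_sets must be two known_ligand_set objects")
  }
  if (ncol(ligand_sets[[1]]$embeddings) != model$config$latent_dim) {
    stop("ligand embeddings do not match the model's latent dimension")
  }
  logs <- vector("list", cfg$n_cycles)
  pool <- list()
  for (i in seq_len(cfg$n_cycles)) {
    res <- run_cycle(model, scorers, ligand_sets, specs, cfg, cycle_index = i)
    model <- res$model
    logs[[i]] <- res$log
    if (nrow(res$scored) > 0L) {
      sc <- res$scored
      sc$first_seen_cycle <- i
      pool[[length(pool) + 1L]] <- sc
    }
    if (verbose) {
      cat(sprintf("cycle %3d: %4d valid / %4d unique, mean R %.4f, max R %.4f\n",
                  i, res$log$n_valid, res$log$n_unique,
                  res$log$mean_R, res$log$max_R))
    }
  }
  cycles <- if (cfg$n_cycles > 0L) do.call(rbind, logs) else
    data.frame(cycle = integer(0))
  ranked <- if (length(pool) > 0L) {
    all <- do.call(rbind, pool)
    # collapse duplicates (by canonical SMILES) across cycles: keep max R,
    # earliest sighting
    ord <- order(all$canonical, -all$R, all$first_seen_cycle, method = "radix")
    all <- all[ord, , drop = FALSE]
    first <- !duplicated(all$canonical)
    seen <- tapply(all$first_seen_cycle, all$canonical, min)
    all <- all[first, , drop = FALSE]
    all$first_seen_cycle <- as.integer(seen[all$canonical])
    all <- all[order(-all$R, all$smiles, method = "radix"), , drop = FALSE]
    rownames(all) <- NULL
    all
  } else {
    data.frame(smiles = character(0), R = numeric(0))
  }
  structure(list(model = model, cycles = cycles, ranked = ranked,
                 config = cfg, specs = specs,
                 scorer_hashes = vapply(scorers, function(s)
                   s$training_set_hash, ""),
                 seed = cfg$seed),
            class = "polygon_run")
}

#' @export
print.polygon_run <- function(x, ...) {
  cat(sprintf("Polypharmacology generation run: %d cycles, seed %d\n",
              nrow(x$cycles), x$seed))
  if (nrow(x$cycles) > 0L) {
    first <- x$cycles$mean_R[1]; last <- x$cycles$mean_R[nrow(x$cycles)]
    cat(sprintf("  mean reward: %.4f (cycle 1) -> %.4f (cycle %d)\n",
                first, last, nrow(x$cycles)))
  }
  cat(sprintf("  %d distinct compounds scored\n", nrow(x$ranked)))
  if (nrow(x$ranked) > 0L) {
    cat("  top compounds:\n")
    print(utils::head(x$ranked[, c("smiles", "R")], 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.polygon_run <- function(object, ...) {
  structure(list(cycles = object$cycles,
                 n_compounds = nrow(object$ranked),
                 best = utils::head(object$ranked, 10L),
                 seed = object$seed),
            class = "summary.polygon_run")
}

#' @export
print.summary.polygon_run <- function(x, ...) {
  cat(sprintf("Generation run, seed %d: %d compounds over %d cycles\n",
              x$seed, x$n_compounds, nrow(x$cycles)))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' Reward trajectory plot
#'
#' Mean, median and maximum aggregate reward per reinforcement cycle.
#'
#' @param x a `polygon_run`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.polygon_run <- function(x, ...) {
  cy <- x$cycles
  if (nrow(cy) == 0L) {
    warning("no cycles to plot")
    return(invisible(x))
  }
  graphics::matplot(cy$cycle, cbind(cy$mean_R, cy$median_R, cy$max_R),
                    type = "b", pch = c(1, 2, 3), lty = 1,
                    col = c("black", "grey40", "firebrick"),
                    xlab = "reinforcement cycle", ylab = "aggregate reward R",
                    ...)
  graphics::legend("bottomright", c("mean", "median", "max"),
                   pch = c(1, 2, 3), col = c("black", "grey40", "firebrick"),
                   bty = "n")
  invisible(x)
}
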