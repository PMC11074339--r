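# Run configuration, provenance and the command-line entry point. A run
# configuration is a YAML tree with a fixed schema; unknown keys are
# rejected before any compute. One master seed fans out to per-component
# seeds through derive_seed(), so sub-runs are independently reproducible.

.config_schema <- list(
  seed = "integer",
  paths = c("corpus", "activity_target1", "activity_target2", "output_dir",
            "checkpoint"),
  vae = c("char_embed_dim", "encoder_hidden", "encoder_layers",
          "encoder_dropout", "latent_dim", "decoder_hidden",
          "decoder_layers", "decoder_dropout", "max_len"),
  train = c("epochs", "learning_rate", "batch_size", "grad_clip",
            "kl_weight", "kl_warmup"),
  generation = c("n_cycles", "samples_per_cycle", "top_k",
                 "finetune_epochs", "finetune_batch", "finetune_lr", "mode"),
  rewards = c("le_target1", "le_target2", "dist_target1", "dist_target2",
              "sa", "qed"),
  scenario = c("n_families", "family_size", "n_records", "n_bits",
               "n_active_families", "dual_overlap", "noise_sigma",
               "base_efficiency", "effect_total")
)

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, rejects unknown sections or keys, and
#' returns the validated tree. Every section is optional; missing values
#' fall back to the package defaults of the corresponding constructor.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run configuration must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown) > 0L) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in setdiff(names(cfg), c("seed"))) {
    allowed <- .config_schema[[sec]]
    if (sec == "rewards") {
      bad <- setdiff(names(cfg$rewards), allowed)
      if (length(bad) > 0L) {
        stop("unknown reward name(s): ", paste(bad, collapse = ", "))
      }
      for (rn in names(cfg$rewards)) {
        rkeys <- setdiff(names(cfg$rewards[[rn]]), c("direction", "mu", "sigma"))
        if (length(rkeys) > 0L) {
          stop(sprintf("unknown key(s) in rewards$%s: %s", rn,
                       paste(rkeys, collapse = ", ")))
        }
      }
    } else {
      bad <- setdiff(names(cfg[[sec]]), allowed)
      if (length(bad) > 0L) {
        stop(sprintf("unknown key(s) in section %s: %s", sec,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

# Reward specs from a config tree (package defaults where unspecified).
config_reward_specs <- function(cfg) {
  specs <- default_reward_specs()
  for (rn in names(cfg$rewards %||% list())) {
    r <- cfg$rewards[[rn]]
    specs[[rn]] <- reward_spec(rn,
                               r$direction %||% specs[[rn]]$direction,
                               r$mu %||% specs[[rn]]$mu,
                               r$sigma %||% specs[[rn]]$sigma)
  }
  specs
}

config_call <- function(fun, args) {
  do.call(fun, args[names(args) %in% names(formals(fun))])
}

#' Provenance block for run outputs
#'
#' @param config the run configuration (hashed into the block).
#' @param seed the effective seed.
#' @return list with package version, R version, config hash and seed.
#' @export
provenance <- function(config = NULL, seed = NA_integer_) {
  cfg_hash <- if (is.null(config)) NA_character_ else {
    corpus_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  }
  list(package = "polygen",
       version = as.character(utils::packageVersion("polygen")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config_hash = cfg_hash,
       seed = seed)
}

write_provenance <- function(dir, config, seed) {
  jsonlite::write_json(provenance(config, seed),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Command-line dispatcher
#'
#' Entry point behind the `polygen` script. Subcommands: `curate`,
#' `train-vae`, `train-scorer`, `generate`, `score-dual`, `fixtures`.
#' Each reads a run configuration (`--config`), writes its outputs under
#' `--out` together with a provenance block, and returns a process exit
#' status (0 on success).
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status, invisibly.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: polygen <command> [--config run.yaml] [--in FILE] [--out DIR]",
    "commands: curate | train-vae | train-scorer | generate | score-dual | fixtures",
    sep = "\n")
  if (length(argv) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  known <- c("curate", "train-vae", "train-scorer", "generate",
             "score-dual", "fixtures")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else
    structure(list(seed = 1L), class = "run_config")
  out_dir <- opts$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- tryCatch({
    switch(cmd,
           "curate" = cli_curate(cfg, opts, out_dir),
           "train-vae" = cli_train_vae(cfg, opts, out_dir),
           "train-scorer" = cli_train_scorer(cfg, opts, out_dir),
           "generate" = cli_generate(cfg, opts, out_dir),
           "score-dual" = cli_score_dual(cfg, opts, out_dir),
           "fixtures" = cli_fixtures(cfg, opts, out_dir))
    write_provenance(out_dir, unclass(cfg), cfg$seed)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i + 1L > length(args)) stop("missing value for --", key)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop("unexpected argument: ", a)
    }
  }
  opts
}

cli_curate <- function(cfg, opts, out_dir) {
  inp <- opts$`in` %||% cfg$paths$corpus
  if (is.null(inp)) stop("curate needs --in or paths$corpus")
  raw <- read_smi(inp)
  res <- curate_corpus(raw$smiles, ids = raw$id)
  write_smi(res$smiles[res$accepted], file.path(out_dir, "curated.smi"),
            ids = res$source_id[res$accepted])
  utils::write.csv(
    res[!res$accepted, c("source_id", "raw_smiles", "reason", "detail")],
    file.path(out_dir, "rejections.csv"), row.names = FALSE)
  message(sprintf("curate: %d accepted, %d rejected",
                  sum(res$accepted), sum(!res$accepted)))
}

cli_train_vae <- function(cfg, opts, out_dir) {
  inp <- opts$`in` %||% cfg$paths$corpus
  if (is.null(inp)) stop("train-vae needs --in or paths$corpus")
  smiles <- read_smi(inp)$smiles
  vcfg <- config_call(vae_config, cfg$vae %||% list())
  tcfg <- config_call(train_config,
                      c(cfg$train %||% list(),
                        list(seed = derive_seed(cfg$seed, "vae"))))
  model <- smiles_vae(smiles, vcfg, tcfg)
  save_checkpoint(model, file.path(out_dir, "vae.rds"))
  utils::write.csv(model$trace, file.path(out_dir, "loss_trace.csv"),
                   row.names = FALSE)
  message(sprintf("train-vae: %d epochs, final loss %.4f",
                  nrow(model$trace), model$trace$total[nrow(model$trace)]))
}

cli_train_scorer <- function(cfg, opts, out_dir) {
  inp <- opts$`in` %||% cfg$paths$activity_target1
  if (is.null(inp)) stop("train-scorer needs --in or paths$activity_target1")
  records <- read_activity_csv(inp)
  sc <- target_scorer(records, seed = derive_seed(cfg$seed, "scorer"))
  saveRDS(sc, file.path(out_dir, "scorer.rds"))
  utils::write.csv(sc$cv_metrics, file.path(out_dir, "cv_metrics.csv"),
                   row.names = FALSE)
  message(sprintf("train-scorer: %s, CV R2 %.3f", sc$target_id,
                  mean(sc$cv_metrics$r2)))
}

cli_generate <- function(cfg, opts, out_dir) {
  ckpt <- opts$checkpoint %||% cfg$paths$checkpoint
  if (is.null(ckpt)) stop("generate needs --checkpoint or paths$checkpoint")
  model <- load_checkpoint(ckpt)
  s1 <- readRDS(opts$scorer1 %||% stop("generate needs --scorer1"))
  s2 <- readRDS(opts$scorer2 %||% stop("generate needs --scorer2"))
  lig <- readRDS(opts$ligands %||% stop("generate needs --ligands"))
  gcfg <- config_call(generation_config,
                      c(cfg$generation %||% list(),
                        list(seed = derive_seed(cfg$seed, "generate"))))
  run <- run_polygon(model, list(s1, s2), lig, config_reward_specs(cfg), gcfg)
  utils::write.csv(run$cycles, file.path(out_dir, "cycles.csv"),
                   row.names = FALSE)
  utils::write.csv(run$ranked, file.path(out_dir, "ranked_compounds.csv"),
                   row.names = FALSE)
  save_checkpoint(run$model, file.path(out_dir, "vae_final.rds"))
  message(sprintf("generate: %d cycles, %d compounds",
                  nrow(run$cycles), nrow(run$ranked)))
}

cli_score_dual <- function(cfg, opts, out_dir) {
  inp <- opts$`in` %||% stop("score-dual needs --in (triplet CSV)")
  trip <- utils::read.csv(inp, stringsAsFactors = FALSE)
  need <- c("smiles", "target1", "target2", "observed1", "observed2",
            "predicted1", "predicted2")
  if (!all(need %in% names(trip))) {
    stop("triplet CSV must have columns: ", paste(need, collapse = ", "))
  }
  cl <- classify_dual(trip)
  tb <- tabulate_dual(cl)
  jsonlite::write_json(unclass(tb), file.path(out_dir, "contingency.json"),
                       auto_unbox = TRUE, digits = NA)
  sweep <- threshold_sweep(trip)
  utils::write.csv(sweep, file.path(out_dir, "threshold_sweep.csv"),
                   row.names = FALSE)
  message(sprintf("score-dual: accuracy %.3f, odds ratio %.2f",
                  tb$accuracy, tb$odds_ratio))
}

cli_fixtures <- function(cfg, opts, out_dir) {
  sspec <- config_call(scenario_spec,
                       c(cfg$scenario %||% list(), list(seed = cfg$seed)))
  sc <- build_scenario(sspec)
  write_smi(sc$corpus$smiles, file.path(out_dir, "corpus.smi"),
            ids = sc$corpus$family)
  write_activity_csv(sc$activity$T1, file.path(out_dir, "activity_T1.csv"))
  write_activity_csv(sc$activity$T2, file.path(out_dir, "activity_T2.csv"))
  jsonlite::write_json(as.list(sc$manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  message(sprintf("fixtures: %d molecules, %d activity records per target",
                  nrow(sc$corpus), nrow(sc$activity$T1)))
}
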