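write_yaml_config <- function(text) {
  p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  writeLines(text, p)
  p
}

test_that("run configurations validate their schema strictly", {
  p <- write_yaml_config(c("seed: 7", "train:", "  epochs: 3",
                           "rewards:", "  qed:", "    mu: 0.6",
                           "    sigma: 0.2"))
  cfg <- read_run_config(p)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 7L)
  specs <- polygen:::config_reward_specs(cfg)
  expect_equal(specs$qed$mu, 0.6)
  expect_equal(specs$le_target1$mu, 0.4)    # untouched default

  expect_error(read_run_config(write_yaml_config(c("bogus:", "  x: 1"))),
               "bogus")
  expect_error(read_run_config(write_yaml_config(c("train:", "  turbo: 1"))),
               "turbo")
  expect_error(read_run_config(write_yaml_config(c("rewards:", "  zing:",
                                                   "    mu: 1"))),
               "zing")
})

test_that("seed derivation is deterministic, label-sensitive and in range", {
  s1 <- polygen:::derive_seed(7L, "cycle1")
  expect_identical(s1, polygen:::derive_seed(7L, "cycle1"))
  expect_false(s1 == polygen:::derive_seed(7L, "cycle2"))
  expect_false(s1 == polygen:::derive_seed(8L, "cycle1"))
  for (m in c(1L, 1000L, 2147483000L)) {
    d <- polygen:::derive_seed(m, "x")
    expect_true(d >= 1L && d <= 2147483562L)
  }
})

test_that("the curate subcommand writes outputs with provenance", {
  fx <- curation_defect_fixture()
  smi <- withr::local_tempfile(fileext = ".smi")
  write_smi(fx$raw_smiles, smi)
  out <- withr::local_tempdir()
  expect_message(status <- cli_dispatch(c("curate", "--in", smi,
                                          "--out", out)),
                 "15 accepted, 5 rejected")
  expect_identical(status, 0L)
  expect_equal(length(read_smi(file.path(out, "curated.smi"))$smiles), 15L)
  rej <- read.csv(file.path(out, "rejections.csv"))
  expect_equal(nrow(rej), 5L)
  expect_setequal(unique(rej$reason), c("too_long", "disallowed_atom"))
  prov <- jsonlite::read_json(file.path(out, "provenance.json"))
  expect_equal(prov$package, "polygen")
  expect_true(!is.null(prov$seed))
})

test_that("unknown subcommands and missing inputs exit nonzero", {
  expect_message(status <- cli_dispatch("frobnicate"), "unknown subcommand")
  expect_identical(status, 1L)
  out <- withr::local_tempdir()
  expect_message(status2 <- cli_dispatch(c("curate", "--out", out)), "error")
  expect_identical(status2, 1L)
  expect_message(status3 <- cli_dispatch(character(0)), "usage")
  expect_identical(status3, 1L)
})

test_that("the fixtures subcommand is reproducible end to end", {
  cfgp <- write_yaml_config(c("seed: 9", "scenario:", "  n_families: 4",
                              "  family_size: 6", "  n_records: 40"))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  expect_message(s1 <- cli_dispatch(c("fixtures", "--config", cfgp,
                                      "--out", out1)), "molecules")
  s2 <- suppressMessages(cli_dispatch(c("fixtures", "--config", cfgp,
                                        "--out", out2)))
  expect_identical(s1, 0L); expect_identical(s2, 0L)
  for (f in c("corpus.smi", "activity_T1.csv", "activity_T2.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  act <- suppressWarnings(read_activity_csv(file.path(out1, "activity_T1.csv")))
  expect_equal(nrow(act), 40L)
})
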