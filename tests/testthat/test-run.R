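# End-to-end drivers behind the command-line interface.

small_scenario <- function(seed = 9) {
  synthetic_config(grid = c(10, 10), n_genes = 40,
                   shared_domains = list(
                     synthetic_domain(c(1, 5), c(1, 10), 1:15,
                                      effect_size = 0.5, variance_scale = 1,
                                      n_factors = 3)),
                   target_only_domains = list(
                     synthetic_domain(c(7, 9), c(7, 9), 16:25,
                                      effect_size = 1, variance_scale = 0.1)),
                   seed = seed)
}

test_that("run_fit writes model, embeddings and a resolved config echo", {
  out <- file.path(withr::local_tempdir(), "run1")
  pair <- generate_pair(small_scenario())
  cfg <- list(preprocess = list(normalization = "log_cpm"),
              graph = list(k = 6), model = list(p = 4), seed = 11)
  model <- suppressMessages(
    run_fit(cfg, out, background = pair$background, target = pair$target))
  expect_true(file.exists(file.path(out, "Zt.tsv")))
  expect_true(file.exists(file.path(out, "Zb.tsv")))
  expect_true(file.exists(file.path(out, "model", "model.json")))
  echo <- yaml::read_yaml(file.path(out, "config_resolved.yaml"))
  expect_equal(echo$model$p, 4)
  expect_equal(echo$graph$mu1, 0.5)     # defaults surfaced
  expect_false(is.null(echo$graph$t_t)) # resolved bandwidth recorded
  Zt <- read_embedding(file.path(out, "Zt.tsv"))
  expect_equal(nrow(Zt), n_spots(pair$target))
})

test_that("identical config and seed give byte-identical outputs", {
  base <- withr::local_tempdir()
  pair <- generate_pair(small_scenario())
  cfg <- list(graph = list(k = 6), model = list(p = 3), seed = 21)
  suppressMessages(run_fit(cfg, file.path(base, "a"),
                           background = pair$background,
                           target = pair$target))
  suppressMessages(run_fit(cfg, file.path(base, "b"),
                           background = pair$background,
                           target = pair$target))
  for (f in c("Zt.tsv", "Zb.tsv", "config_resolved.yaml"))
    expect_identical(readLines(file.path(base, "a", f)),
                     readLines(file.path(base, "b", f)))
})

test_that("run_fit removes a partial output directory on failure", {
  out <- file.path(withr::local_tempdir(), "bad")
  cfg <- list(input = list(background_matrix = "/nonexistent.tsv",
                           background_coords = "/nonexistent2.tsv",
                           target_matrix = "/nonexistent3.tsv",
                           target_coords = "/nonexistent4.tsv"))
  expect_error(run_fit(cfg, out), "not found")
  expect_false(dir.exists(out))
})

test_that("run_transform reproduces the fit-time target embedding", {
  base <- withr::local_tempdir()
  pair <- suppressMessages(run_synth(small_scenario(), file.path(base, "data")))
  cfg <- list(input = list(
                background_matrix = file.path(base, "data", "background_matrix.tsv"),
                background_coords = file.path(base, "data", "background_coords.tsv"),
                target_matrix = file.path(base, "data", "target_matrix.tsv"),
                target_coords = file.path(base, "data", "target_coords.tsv")),
              graph = list(k = 6), model = list(p = 3), seed = 31)
  suppressMessages(run_fit(cfg, file.path(base, "fit")))
  Z <- suppressMessages(run_transform(
    file.path(base, "fit", "model"),
    file.path(base, "data", "target_matrix.tsv"),
    file.path(base, "data", "target_coords.tsv"),
    file.path(base, "out.tsv")))
  Zt <- read_embedding(file.path(base, "fit", "Zt.tsv"))
  expect_equal(unname(as.matrix(Z)), unname(Zt), tolerance = 1e-12)

  # a slice with permuted gene columns transforms identically
  ds <- read_dataset(file.path(base, "data", "target_matrix.tsv"),
                     file.path(base, "data", "target_coords.tsv"),
                     format = "delimited")
  perm <- sample(n_genes(ds))
  pm <- file.path(base, "perm_matrix.tsv")
  m <- as.matrix(ds$expr)[, perm]
  write.table(data.frame(spot_id = ds$spot_ids, m, check.names = FALSE),
              pm, sep = "\t", quote = FALSE, row.names = FALSE)
  Zp <- suppressMessages(run_transform(
    file.path(base, "fit", "model"), pm,
    file.path(base, "data", "target_coords.tsv"),
    file.path(base, "out2.tsv")))
  expect_equal(unname(as.matrix(Zp)), unname(as.matrix(Z)))
})

test_that("run_transform names missing model genes", {
  base <- withr::local_tempdir()
  suppressMessages(run_synth(small_scenario(), file.path(base, "data")))
  cfg <- list(input = list(
                background_matrix = file.path(base, "data", "background_matrix.tsv"),
                background_coords = file.path(base, "data", "background_coords.tsv"),
                target_matrix = file.path(base, "data", "target_matrix.tsv"),
                target_coords = file.path(base, "data", "target_coords.tsv")),
              graph = list(k = 6), model = list(p = 3), seed = 41)
  suppressMessages(run_fit(cfg, file.path(base, "fit")))
  ds <- read_dataset(file.path(base, "data", "target_matrix.tsv"),
                     file.path(base, "data", "target_coords.tsv"),
                     format = "delimited")
  short <- file.path(base, "short_matrix.tsv")
  m <- as.matrix(ds$expr)[, -1]
  write.table(data.frame(spot_id = ds$spot_ids, m, check.names = FALSE),
              short, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(run_transform(
    file.path(base, "fit", "model"), short,
    file.path(base, "data", "target_coords.tsv"),
    file.path(base, "out3.tsv"))), "gene001")
})
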