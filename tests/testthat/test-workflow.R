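make_tiny_data <- function(n = 12, seed = 1L) {
  build_scene_list(n, tiny_scene_spec(seed = seed), train_fraction = 5 / 6)
}

tiny_tc <- function(...) {
  args <- list(...)
  defaults <- list(optimizer = "adam", lr = 1e-3, max_epochs = 3L,
                   patience = 2L, batch_size = 4L, seed = 5L)
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

test_that("train_config validates its invariants", {
  expect_error(train_config(patience = 10, max_epochs = 10), "patience")
  expect_error(train_config(lr = 0), "lr")
  expect_s3_class(train_config(), "train_config")
})

test_that("a frozen validation metric triggers early stopping after
          `patience` stalled epochs", {
  data <- make_tiny_data()
  # an SGD step of 1e-30 underflows against the weights: the model, and
  # hence the validation metric, is frozen by construction
  tc <- tiny_tc(optimizer = "sgd", lr = 1e-30, max_epochs = 10L,
                patience = 2L)
  fit <- train_multisams(tiny_model_config(), tc, data)
  expect_equal(fit$stop_reason, "early_stop")
  expect_equal(nrow(fit$history), 3L)       # best at 1, stalls at 2 and 3
  expect_equal(fit$best_epoch, 1L)
})

test_that("training reduces the loss on a small overfit set", {
  data <- make_tiny_data(n = 10, seed = 2L)
  data$split[] <- "train"
  fit <- train_multisams(tiny_model_config(), tiny_tc(max_epochs = 5L,
                                                      patience = 4L), data)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(fit$stop_reason, "max_epochs")
  # best validation SI-SNR is the max over epochs
  expect_equal(fit$best_val_si_snr_db, max(fit$history$val_si_snr_db))
})

test_that("training is deterministic under fixed seeds", {
  data <- make_tiny_data(seed = 3L)
  cfg <- tiny_model_config()
  f1 <- train_multisams(cfg, tiny_tc(max_epochs = 2L, patience = 1L), data)
  f2 <- train_multisams(cfg, tiny_tc(max_epochs = 2L, patience = 1L), data)
  expect_identical(f1$history, f2$history)
  expect_identical(ns$tree_flatten(unclass(f1$weights)),
                   ns$tree_flatten(unclass(f2$weights)))
})

test_that("checkpoints round-trip weights and config", {
  data <- make_tiny_data(seed = 4L)
  cfg <- tiny_model_config()
  fit <- train_multisams(cfg, tiny_tc(max_epochs = 2L, patience = 1L), data)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  ck <- load_checkpoint(path)
  expect_identical(ck$config$rnn_type, cfg$rnn_type)
  sc <- data$scenes[[1]]
  a <- multisams_forward(sc$mixture, cfg, fit$weights)
  b <- multisams_forward(sc$mixture, ck$config, ck$weights)
  expect_identical(a$sources, b$sources)
})

test_that("the experiment grid reports parameter ordering and shared
          evaluation scenes", {
  data <- make_tiny_data(seed = 6L)
  grid <- lapply(c("rnn", "gru", "lstm"), function(ty) {
    list(config = tiny_model_config(rnn_type = ty), label = ty)
  })
  tab <- run_experiment_grid(grid, tiny_tc(max_epochs = 2L, patience = 1L), data)
  expect_equal(nrow(tab), 3L)
  expect_gt(tab$n_params[tab$label == "lstm"],
            tab$n_params[tab$label == "gru"])
  expect_gt(tab$n_params[tab$label == "gru"],
            tab$n_params[tab$label == "rnn"])
  # all cells saw the same test scenes: identical mixture baselines
  expect_equal(length(unique(round(tab$mean_mixture_si_snr_db, 10))), 1L)
})

test_that("a grid over use_msam and channel subsets runs both cells on
          identical scenes", {
  data <- make_tiny_data(seed = 7L)
  grid <- list(
    list(config = tiny_model_config(use_msam = TRUE), label = "msam",
         n_sensors = 3L),
    list(config = tiny_model_config(use_msam = FALSE), label = "plain",
         n_sensors = 2L))
  tab <- run_experiment_grid(grid, tiny_tc(max_epochs = 2L, patience = 1L), data)
  expect_equal(tab$n_sensors, c(3L, 2L))
  expect_true(all(is.finite(tab$mean_si_snr_db)))
  # channel subsetting keeps channel 1 (the references coincide)
  sub <- subset_channels(data, 2L)
  expect_equal(sub$scenes[[1]]$mixture$samples[1, ],
               data$scenes[[1]]$mixture$samples[1, ])
  expect_equal(n_channels(sub$scenes[[1]]$mixture), 2L)
})

cli_path <- function() {
  p <- system.file("cli", "multisams.R", package = "multisams")
  if (nzchar(p)) p else testthat::skip("CLI script not installed")
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_path(), ...),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cli synth is byte-reproducible under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a1 <- run_cli("synth", "--out", d1, "--n-scenes", "3", "--seed", "7",
                "--sample-rate", "4000", "--duration-s", "0.05",
                "--n-sensors", "2", "--train-fraction", "0.67")
  a2 <- run_cli("synth", "--out", d2, "--n-scenes", "3", "--seed", "7",
                "--sample-rate", "4000", "--duration-s", "0.05",
                "--n-sensors", "2", "--train-fraction", "0.67")
  expect_equal(a1$status, 0L)
  expect_equal(a2$status, 0L)
  for (f in list.files(d1, pattern = "wav$")) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
})

test_that("cli separate rejects single-channel input with non-zero exit", {
  ckpt <- withr::local_tempfile(fileext = ".rds")
  cfg <- tiny_model_config()
  save_checkpoint(multisams_init(cfg), ckpt, config = cfg)
  wav <- withr::local_tempfile(fileext = ".wav")
  write_multichannel_wav(multichannel_recording(rnorm(200) / 10, 4000), wav)
  out <- withr::local_tempfile(fileext = ".wav")
  r <- run_cli("separate", "--checkpoint", ckpt, "--in", wav, "--out", out)
  expect_true(r$status != 0L)
  r2 <- run_cli("separate", "--frobnicate")
  expect_equal(r2$status, 2L)
})

test_that("cli evaluate on identity estimates reproduces the metrics module", {
  dir <- withr::local_tempdir()
  est <- withr::local_tempdir()
  manifest <- build_dataset(4, tiny_scene_spec(), dir, train_fraction = 0.5)
  rows <- manifest[manifest$split == "test", ]
  for (i in seq_len(nrow(rows))) {
    file.copy(rows$clean_path[i],
              file.path(est, paste0(rows$scene_id[i], ".wav")))
  }
  outcsv <- withr::local_tempfile(fileext = ".csv")
  r <- run_cli("evaluate", "--manifest", file.path(dir, "manifest.csv"),
               "--estimates", est, "--out", outcsv)
  expect_equal(r$status, 0L)
  tab <- read.csv(outcsv)
  direct <- evaluate_pairs(manifest, est)
  expect_equal(tab$si_snr_db, direct$per_scene$si_snr_db, tolerance = 1e-9)
})
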