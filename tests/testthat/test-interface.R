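test_that("long CSV round-trips values at full precision and masks exactly", {
  set.seed(19)
  mk <- function(i) {
    s <- rand_sample(5, 2, 0.4, paste0("p", i))
    # long format carries a stamp only while something is observed there,
    # so keep at least one observation per row
    for (t in which(rowSums(s$mask) == 0)) {
      s$mask[t, 1] <- 1
      s$values[t, 1] <- rnorm(1)
    }
    ts_sample(ifelse(s$mask == 1, s$values, NA), s$stamps, s$sample_id)
  }
  ds <- ts_dataset(lapply(1:3, mk), labels = c(0, 1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(ds, path)
  back <- read_long_csv(path)
  for (i in 1:3) {
    orig <- ds$samples[[i]]
    ids <- vapply(back$samples, function(s) s$sample_id, character(1))
    got <- back$samples[[match(orig$sample_id, ids)]]
    expect_identical(got$mask, unname(orig$mask))
    expect_equal(got$values, unname(orig$values), tolerance = 1e-15)
    expect_equal(got$stamps, orig$stamps, tolerance = 1e-15)
  }
})

test_that("times are shifted so every sample starts at stamp 0", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time,variable,value",
               "a,3,v1,1.5", "a,5,v1,2.5"), path)
  ds <- read_long_csv(path)
  expect_equal(ds$samples[[1]]$stamps, c(0, 2))
})

test_that("format errors are reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,time,variable,value", path)
  expect_error(read_long_csv(path), "empty")
  writeLines(c("sample_id,time,variable,value", "a,0,v9,1"), path)
  expect_error(read_long_csv(path, variables = c("v1")), "unknown variable")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,value", "a,1"), path2)
  expect_error(read_long_csv(path2), "columns")
})

test_that("labels attach by sample id, including multitask matrices", {
  ds <- ts_dataset(lapply(1:3, function(i) rand_sample(4, 2, 0.3,
                                                       paste0("p", i))))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label", "p3,1", "p1,0", "p2,1"), path)
  ds2 <- attach_labels(ds, path)
  expect_equal(ds2$labels, c(0, 1, 1))
  writeLines(c("sample_id,t1,t2", "p1,0,1", "p2,1,0", "p3,1,1"), path)
  ds3 <- attach_labels(ds, path)
  expect_equal(dim(ds3$labels), c(3L, 2L))
  writeLines(c("sample_id,label", "p1,0"), path)
  expect_error(attach_labels(ds, path), "missing labels")
})

test_that("checkpoints restore a model that predicts identically", {
  ds <- separable_dataset(n = 40, Tn = 5, seed = 20)
  parts <- train_valid_test_split(ds, c(0.6, 0.4, 0), seed = 21)
  cfg <- model_config(mode = "grud", hidden_size = 4L, max_epochs = 3L,
                      seed = 22L)
  m <- suppressMessages(fit_model(parts$train, parts$valid, cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_equal(predict(m2, parts$valid), predict(m, parts$valid),
               tolerance = 1e-15)
})

test_that("config files reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(mode = "grud", hidden_size = 4), path,
                       auto_unbox = TRUE)
  cfg <- read_config(path, "model")
  expect_equal(cfg$mode, "grud")
  jsonlite::write_json(list(modee = "grud"), path, auto_unbox = TRUE)
  expect_error(read_config(path, "model"), "unknown config key")
})

test_that("cli: generate writes data, labels and a faithful report", {
  out <- file.path(withr::local_tempdir(), "syn")
  status <- suppressMessages(
    run_cli(c("generate", "--out", out, "--rho", "0", "--n", "500",
              "--seed", "3")))
  expect_identical(status, 0L)
  expect_true(file.exists(paste0(out, ".csv")))
  ds <- attach_labels(read_long_csv(paste0(out, ".csv")),
                      paste0(out, "_labels.csv"))
  r <- missingness_label_correlation(ds)
  expect_true(all(abs(r) < 0.1))
  rep <- jsonlite::read_json(paste0(out, "_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$seed, 3)
})

test_that("cli: train is deterministic and evaluate/online/decay run", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "toy")
  suppressMessages(run_cli(c("generate", "--out", out, "--n", "60",
                             "--T", "6", "--seed", "5")))
  ck1 <- file.path(dir, "m1.json"); ck2 <- file.path(dir, "m2.json")
  args <- c("train", "--data", paste0(out, ".csv"),
            "--labels", paste0(out, "_labels.csv"), "--mode", "gru_mean",
            "--seed", "6")
  log1 <- capture.output(expect_identical(
    run_cli(c(args, "--out", ck1)), 0L), type = "message")
  log2 <- capture.output(expect_identical(
    run_cli(c(args, "--out", ck2)), 0L), type = "message")
  drop_out_flag <- function(x) grep("event=epoch", x, value = TRUE)
  expect_identical(drop_out_flag(log1), drop_out_flag(log2))

  curve_json <- file.path(dir, "curve.json")
  expect_identical(suppressMessages(run_cli(
    c("online-curve", "--model", ck1, "--data", paste0(out, ".csv"),
      "--labels", paste0(out, "_labels.csv"), "--cutoffs", "2,5",
      "--out", curve_json))), 0L)
  curve <- jsonlite::read_json(curve_json, simplifyVector = TRUE)
  expect_equal(curve$cutoff, c(2, 5))
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
})

test_that("cli: sweep writes a mode x rho table and errors exit nonzero", {
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "sweep.csv")
  status <- suppressMessages(run_cli(
    c("sweep", "--rho-grid", "0,0.9", "--seeds", "1", "--n", "60",
      "--T", "6", "--hidden", "4", "--epochs", "2", "--seed", "7",
      "--out", tab)))
  expect_identical(status, 0L)
  sw <- utils::read.csv(tab)
  expect_equal(nrow(sw), 8)           # 4 modes x 2 settings
  expect_setequal(unique(sw$mode),
                  c("grud", "gru_mean", "gru_forward", "gru_simple"))
  expect_true(all(sw$mean_auc >= 0 & sw$mean_auc <= 1))

  expect_identical(suppressMessages(run_cli(c("nonsense"))), 1L)
  expect_identical(suppressMessages(run_cli(c("train", "--badflag"))), 1L)
  expect_identical(suppressMessages(run_cli(character(0))), 1L)
})
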