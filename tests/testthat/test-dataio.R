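test_that("a toy delimited file is read back verbatim", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ch1\tch2\tch3\tch4\tangle",
               "1\t2\t3\t4\t10",
               "5\t6\t7\t8\t20",
               "9\t10\t11\t12\t30",
               "13\t14\t15\t16\t40",
               "17\t18\t19\t20\t50"), path)
  rec <- read_recording(path, column_map(), cls = "walking",
                        subject_id = "toy", cohort = "healthy")
  expect_equal(rec$emg, matrix(c(1, 5, 9, 13, 17, 2, 6, 10, 14, 18,
                                 3, 7, 11, 15, 19, 4, 8, 12, 16, 20), 5, 4))
  expect_equal(rec$angle, c(10, 20, 30, 40, 50))
  expect_identical(rec$cls, 0L)
})

test_that("column mismatch and non-numeric payloads are hard errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tc", "1\t2\t3"), path)
  expect_error(read_recording(path, column_map(), cls = 0), "only 3 columns")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("h\th\th\th\th", "1\t2\t3\t4\t5", "1\tx\t3\t4\t5"), path2)
  expect_error(read_recording(path2, column_map(), cls = 0), "row 2")
  expect_error(read_recording(tempfile(), column_map(), cls = 0), "not found")
  expect_error(column_map(emg_cols = c(1, 2, 2, 3)), "distinct")
})

test_that("write/read recording round trip is lossless to precision", {
  rec <- gen_recording("walking", tiny_sim(seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path, column_map(), cls = rec$cls,
                         subject_id = rec$subject_id, cohort = "synthetic")
  expect_lt(max(abs(back$emg - rec$emg)), 1e-6 * max(abs(rec$emg)))
  expect_lt(max(abs(back$angle - rec$angle)), 1e-5)
})

test_that("model save/load round trip preserves weights and predictions", {
  segs <- tiny_segments()
  model <- build_lrcn(tiny_lrcn())
  model <- train_angle_predictor(model, segs, epochs = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(back$training_stage, "angle_trained")
  expect_equal(predict_angle(back, segs), predict_angle(model, segs))
  bl <- model_blocks(back)
  expect_named(bl, c("feature_extractor", "angle_head", "classification_head"))
  expect_length(intersect(names(bl$feature_extractor), names(bl$angle_head)), 0)
})

test_that("loading a corrupted model container fails with a format error", {
  path <- withr::local_tempfile(fileext = ".rds")
  writeLines("this is not a model", path)
  expect_error(load_model(path), "not a valid model container")
  saveRDS(list(foo = 1), path)
  expect_error(load_model(path), "format header")
})

test_that("metrics report round trips through JSON", {
  cm <- matrix(c(100, 0, 0, 0, 100, 0, 0, 50, 50), 3, 3, byrow = TRUE,
               dimnames = list(movement_classes(), movement_classes()))
  rep <- metrics_report(mae_percent = 8.125, accuracy = 100,
                        pearson_r = 0.9971, confusion = cm)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, "\"accuracy\": 100")
  back <- read_metrics_report(path)
  expect_equal(back$accuracy, 100)
  expect_equal(back$mae_percent, 8.125)
  expect_equal(unname(back$confusion), unname(cm))
  expect_true(all(abs(rowSums(back$confusion) - 100) <= 0.01))
})
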