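test_that("configuration fixes the published architecture shapes", {
  cfg <- lrcn_config()
  sh <- lrcn_shapes(cfg)
  expect_equal(sh$t1, 64)            # per-branch map after the first pool
  expect_equal(sh$t2, 16)            # after the second conv stage's pool
  expect_equal(sh$flatten, 320)      # 16 x 20 into the classification head
  expect_equal(sh$angle_dense_params, 16640)   # 64*256 + 256
  expect_equal(sh$class_dense_params, 963)     # 320*3 + 3
  # shape contract holds for any window divisible by 16 under 'same' padding
  for (W in c(128L, 256L, 512L)) {
    shw <- lrcn_shapes(lrcn_config(window = W))
    expect_equal(shw$t2, W / 16)
    expect_equal(shw$flatten, W / 16 * 20)
    m <- build_lrcn(lrcn_config(window = W))
    expect_equal(dim(m$params[["ah.dense.W"]]), c(64, W))
  }
  expect_error(lrcn_config(window = 100), "not divisible")
  expect_error(lrcn_config(window = 256, padding = "valid"), "not divisible")
  expect_error(lrcn_config(dropout = 1), "dropout")
})

test_that("initialization is reproducible from the seed", {
  expect_identical(build_lrcn(lrcn_config(seed = 5))$params,
                   build_lrcn(lrcn_config(seed = 5))$params)
  expect_false(identical(build_lrcn(lrcn_config(seed = 5))$params,
                         build_lrcn(lrcn_config(seed = 6))$params))
})

test_that("angle outputs have window length and class rows sum to one", {
  segs <- tiny_segments()
  model <- train_angle_predictor(build_lrcn(tiny_lrcn()), segs, epochs = 1)
  pa <- predict_angle(model, segs)
  expect_equal(dim(pa), c(n_segments(segs), 64))
  expect_true(all(is.finite(pa)))
  model <- transfer_to_classifier(model, segs, epochs = 1)
  pm <- predict_movement(model, segs)
  expect_equal(dim(pm$probs), c(n_segments(segs), 3))
  expect_true(all(abs(rowSums(pm$probs) - 1) < 1e-6))
  expect_true(all(pm$labels %in% 0:2))
})

test_that("angle training reduces the loss and is reproducible", {
  segs <- tiny_segments(duration_s = 4)
  m1 <- train_angle_predictor(build_lrcn(tiny_lrcn(seed = 3)), segs, epochs = 8)
  expect_lt(tail(m1$history$angle_loss, 1), m1$history$angle_loss[1])
  m2 <- train_angle_predictor(build_lrcn(tiny_lrcn(seed = 3)), segs, epochs = 8)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$angle_loss, m2$history$angle_loss)
})

test_that("epochs = 0 leaves the model untouched", {
  segs <- tiny_segments()
  model <- build_lrcn(tiny_lrcn())
  expect_identical(train_angle_predictor(model, segs, epochs = 0), model)
})

test_that("training-state preconditions are enforced", {
  segs <- tiny_segments()
  model <- build_lrcn(tiny_lrcn())
  expect_error(transfer_to_classifier(model, segs), "angle_trained")
  expect_error(predict_angle(model, segs), "trained")
  expect_error(predict_movement(model, segs), "transfer_complete")
  trained <- train_angle_predictor(model, segs, epochs = 1)
  expect_error(predict_movement(trained, segs), "transfer_complete")
  done <- transfer_to_classifier(trained, segs, epochs = 1)
  expect_error(transfer_to_classifier(done, segs), "angle_trained")
  expect_error(train_angle_predictor(done, segs), "untrained or angle_trained")
})

test_that("transfer learning freezes the feature extractor bit-exactly", {
  segs <- tiny_segments(duration_s = 4)
  model <- train_angle_predictor(build_lrcn(tiny_lrcn()), segs, epochs = 3)
  fe_before <- serialize(model_blocks(model)$feature_extractor, NULL)
  ah_before <- serialize(model_blocks(model)$angle_head, NULL)
  done <- transfer_to_classifier(model, segs, epochs = 10)
  expect_identical(serialize(model_blocks(done)$feature_extractor, NULL),
                   fe_before)
  expect_identical(serialize(model_blocks(done)$angle_head, NULL), ah_before)
  expect_false(identical(done$params[["ch.dense.W"]],
                         model$params[["ch.dense.W"]]))
})

test_that("the classifier beats chance on held-out synthetic data", {
  recs <- gen_dataset(2, sim_config(duration_s = 4, seed = 21))
  segs <- bind_segments(lapply(recs, segment_windows, window_ms = 64,
                               overlap_ms = 16))
  sp <- kfold_split(n_segments(segs), k = 3, seed = 2)
  train_idx <- sp$assignments != 1
  norm <- fit_normalizer(segs[train_idx])
  train <- apply_normalizer(norm, segs[train_idx])
  test <- apply_normalizer(norm, segs[!train_idx])
  model <- train_angle_predictor(build_lrcn(tiny_lrcn(seed = 2)), train,
                                 epochs = 10)
  model <- transfer_to_classifier(model, train, epochs = 30)
  pm <- predict_movement(model, test)
  expect_gt(mean(pm$labels == test$y_class) * 100, 33.4)
})

test_that("the full-size network can overfit 25 segments (capacity check)", {
  recs <- gen_dataset(1, sim_config(duration_s = 2, seed = 5))
  segs <- bind_segments(lapply(recs, segment_windows))
  segs <- apply_normalizer(fit_normalizer(segs), segs)[1:25]
  model <- train_angle_predictor(build_lrcn(lrcn_config(seed = 9)), segs,
                                 epochs = 200)
  losses <- model$history$angle_loss
  expect_lt(tail(losses, 1), 0.1 * losses[1])
})

test_that("a diverging loss aborts with diagnostics", {
  segs <- tiny_segments()
  segs$x <- segs$x * 1e150    # overflows the forward pass
  model <- build_lrcn(tiny_lrcn())
  expect_error(train_angle_predictor(model, segs, epochs = 1), "non-finite")
  expect_error(train_angle_predictor(model, tiny_segments()[0], epochs = 1),
               "empty")
})
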