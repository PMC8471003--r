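# CNN tests run on a 48-sample grid: the smallest grid comfortably above
# the three-block minimum input length, so training stays fast while
# exercising the full topology.

cnn_dataset <- function(name = "binary", n = 48L, seed = 1L,
                        noise_scale = 1, fibers = c("R1", "R5")) {
  mod <- scale_model_noise(tiny_model(n), noise_scale)
  des <- quick_design(name, fibers = fibers)
  list(dataset = simulate_study(des, mod, seed = seed), design = des)
}

test_that("model topology matches the configuration", {
  cfg <- cnn_config(input_length = 48L)
  set.seed(1)
  m <- build_model(cfg, n_classes = 6L)
  expect_identical(dim(m$weights$W1), c(5L, 8L))
  expect_identical(dim(m$weights$W2), c(5L * 8L, 10L))
  expect_identical(dim(m$weights$W3), c(5L * 10L, 12L))
  # 48 -> conv 44 -> pool 22 -> conv 18 -> pool 9 -> conv 5 -> pool 2
  expect_identical(m$dims$flatten, 2L * 12L)
  expect_identical(dim(m$weights$Wd), c(24L, 6L))
  # untrained forward pass already yields a probability simplex
  m$classes <- study_design("depth")$classes
  p <- predict(m, matrix(rnorm(3 * 48), 3, 48))
  expect_equal(unname(rowSums(p$probabilities)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p$labels %in% m$classes))
  # binary head gives a single sigmoid unit reported over two classes
  set.seed(1)
  mb <- build_model(cnn_config(input_length = 48L), n_classes = 2L)
  expect_true(mb$binary)
  expect_identical(dim(mb$weights$Wd), c(24L, 1L))
  pb <- predict(mb, matrix(rnorm(48), 1, 48))
  expect_true(all(pb$probabilities >= 0 & pb$probabilities <= 1))
  # the full-resolution combined-feature length is accepted
  expect_s3_class(cnn_config(input_length = 7174L), "lss_cnn_config")
  expect_error(cnn_config(input_length = 30L), "too short")
  expect_error(predict(mb, matrix(0, 1, 47)), "length")
})

test_that("subject-wise split holds out whole rebuilds without leakage", {
  fx <- cnn_dataset("depth")
  features <- make_features(fx$dataset, "R1")
  set.seed(42)
  sp <- subject_wise_split(features, fx$design)
  expect_setequal(c(sp$train, sp$validation, sp$test),
                  seq_along(features$labels))
  for (cls in fx$design$classes) {
    test_rb <- unique(features$rebuild_id[intersect(
      sp$test, which(features$labels == cls))])
    expect_length(test_rb, 1L)
    train_rb <- features$rebuild_id[c(sp$train, sp$validation)]
    expect_false(test_rb %in% train_rb)
  }
  # validation is ~30% of the post-test samples (rounded per class)
  val_share <- length(sp$validation) /
    (length(features$labels) - length(sp$test))
  expect_gte(val_share, 0.2)
  expect_lte(val_share, 0.4)
  per_class_val <- table(features$labels[sp$validation])
  expect_true(all(per_class_val > 0))
  # a class with a single rebuild cannot be split
  one <- features
  one$rebuild_id[features$labels == fx$design$classes[1]] <- 1L
  expect_error(subject_wise_split(one, fx$design), "fewer than 2 rebuilds")
})

test_that("feature assembly pairs fibers on probe placement", {
  fx <- cnn_dataset("binary")
  single <- make_features(fx$dataset, "R5")
  expect_identical(ncol(single$X), 48L)
  expect_equal(unname(rowMeans(single$X)), rep(1, nrow(single$X)),
               tolerance = 1e-9)
  pair <- make_features(fx$dataset, c("R5", "R1"))
  expect_identical(pair$fibers, c("R1", "R5"))  # canonical ordering
  expect_identical(ncol(pair$X), 96L)
  expect_identical(nrow(pair$X), nrow(single$X))
  # each half of a combined row is itself mean-normalized
  expect_equal(unname(rowMeans(pair$X[, 1:48])), rep(1, nrow(pair$X)),
               tolerance = 1e-9)
  expect_error(make_features(fx$dataset, "R3"), "absent")
  expect_error(make_features(fx$dataset, c("R1", "R1")), "distinct")
})

test_that("training is deterministic given the base seed", {
  fx <- cnn_dataset("binary", noise_scale = 0.5)
  cfg <- cnn_config(input_length = 48L, max_epochs = 60L,
                    patience_epochs = 60L, n_replicates = 2L)
  r1 <- train_replicates(fx$dataset, fx$design, cfg, "R1", base_seed = 7L)
  r2 <- train_replicates(fx$dataset, fx$design, cfg, "R1", base_seed = 7L)
  expect_identical(lapply(r1, `[[`, "test_predictions"),
                   lapply(r2, `[[`, "test_predictions"))
  expect_identical(r1[[1]]$history$train_loss, r2[[1]]$history$train_loss)
  # distinct replicate seeds give distinct initializations
  expect_false(identical(r1[[1]]$model$weights$W1, r1[[2]]$model$weights$W1))
})

test_that("training separates well-separated binary constructs", {
  fx <- cnn_dataset("binary", noise_scale = 0.25, seed = 3L)
  cfg <- cnn_config(input_length = 48L, max_epochs = 300L,
                    patience_epochs = 300L, n_replicates = 3L)
  reps <- train_replicates(fx$dataset, fx$design, cfg, "R1", base_seed = 11L)
  expect_length(reps, 3L)
  for (r in reps) {
    expect_lte(r$epochs, cfg$max_epochs)
    expect_length(r$history$train_loss, r$epochs)
    # loss decreases over training
    expect_lt(tail(r$history$train_loss, 1), r$history$train_loss[1])
    acc <- mean(r$test_predictions == r$test_truth)
    expect_gte(acc, 0.95)
  }
})

test_that("the stopping rule halts training when the loss plateaus", {
  fx <- cnn_dataset("binary")
  cfg <- cnn_config(input_length = 48L, learning_rate = 1e-30,
                    max_epochs = 200L, patience_epochs = 10L,
                    n_replicates = 1L)
  rep1 <- train_replicates(fx$dataset, fx$design, cfg, "R1", base_seed = 1L)[[1]]
  expect_true(rep1$stopped_early)
  expect_identical(as.integer(rep1$epochs), 11L)  # 1 best + 10 flat epochs
})

test_that("training a requested absent fiber fails loudly", {
  fx <- cnn_dataset("binary")
  cfg <- quick_cnn_config(48L)
  expect_error(train_replicates(fx$dataset, fx$design, cfg, "R4", 1L),
               "absent")
  expect_error(train_replicates(fx$dataset, fx$design,
                                quick_cnn_config(96L), "R1", 1L),
               "does not match")
})
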