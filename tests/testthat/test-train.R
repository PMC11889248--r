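# Training-loop contracts on a deliberately small configuration: 32 px
# inputs with 1x1 patches and single-layer transformers keep each run to a
# few seconds.

small_cfg <- function(...) {
  args <- list(name = "small", decomposed = TRUE, mv2_attention = "se",
               mb_attention = "nam", transformer_depths = c(1, 1, 1),
               num_classes = 2, input_size = 32, patch_size = c(1, 1))
  do.call(variant_config, utils::modifyList(args, list(...)))
}

small_data <- function(n_train = 24, n_val = 12, seed = 31) {
  tr <- tiny_dataset(n_train, 0.5, seed = seed, side = 32)
  va <- tiny_dataset(n_val, 0.5, seed = seed + 1, side = 32)
  tr$manifest$split <- "train"
  va$manifest$split <- "val"
  list(man = rbind(tr$manifest, va$manifest),
       imgs = c(tr$samples, va$samples))
}

test_that("training reduces the loss on separable data and logs history", {
  d <- small_data()
  m <- build_model(small_cfg(), seed = 2)
  hist_file <- file.path(tempdir(), "hist.jsonl")
  cfg <- train_config(batch_size = 8, initial_lr = 0.001, epochs = 3,
                      input_side = 32, seed = 1, history_file = hist_file)
  h <- train_model(m, d$man, cfg, images = d$imgs)
  expect_s3_class(h, "mn_training_history")
  expect_equal(nrow(h), 3L)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
  expect_false(any(is.na(h$val_avg_acc)))
  expect_equal(length(readLines(hist_file)), 3L)
  expect_true(!is.na(attr(h, "best_epoch")))
})

test_that("training is deterministic for a fixed seed", {
  d <- small_data()
  cfg <- train_config(batch_size = 8, epochs = 2, input_side = 32, seed = 9)
  m1 <- build_model(small_cfg(), seed = 3)
  h1 <- train_model(m1, d$man, cfg, images = d$imgs)
  m2 <- build_model(small_cfg(), seed = 3)
  h2 <- train_model(m2, d$man, cfg, images = d$imgs)
  expect_identical(h1$train_loss[1], h2$train_loss[1])
  expect_equal(h1$train_loss, h2$train_loss)
  expect_equal(collect_params(m1$net), collect_params(m2$net))
})

test_that("fully frozen weights stay fixed through training", {
  d <- small_data()
  m <- build_model(small_cfg(), seed = 4)
  mnvit:::walk_modules(m$net, function(mod, path) mod$frozen <- TRUE)
  before <- collect_params(m$net)
  cfg <- train_config(batch_size = 8, epochs = 2, input_side = 32, seed = 1,
                      recalibrate_bn = FALSE)
  h <- train_model(m, d$man, cfg, images = d$imgs)
  expect_identical(collect_params(m$net), before)
})

test_that("freeze_trunk trains only the classification head", {
  d <- small_data()
  m <- build_model(small_cfg(), seed = 5)
  before <- collect_params(m$net)
  cfg <- train_config(batch_size = 8, epochs = 1, input_side = 32, seed = 1,
                      freeze_trunk = TRUE, recalibrate_bn = FALSE)
  train_model(m, d$man, cfg, images = d$imgs)
  after <- collect_params(m$net)
  head_keys <- grep("^head/classifier", names(after), value = TRUE)
  trunk_keys <- setdiff(names(after), head_keys)
  expect_identical(after[trunk_keys], before[trunk_keys])
  expect_false(identical(after[head_keys], before[head_keys]))
})

test_that("training rejects degenerate splits", {
  d <- small_data()
  man <- d$man
  man$label[man$split == "train"] <- 0L
  m <- build_model(small_cfg(), seed = 6)
  expect_error(train_model(m, man, train_config(epochs = 1, input_side = 32),
                           images = d$imgs), "both classes")
  man2 <- d$man
  man2$split[man2$split == "train"] <- "nope"
  expect_error(train_model(m, man2, train_config(epochs = 1, input_side = 32),
                           images = d$imgs), "empty training split")
})

test_that("evaluating a constant-output model scores balanced accuracy 0.5", {
  d <- small_data()
  m <- build_model(small_cfg(), seed = 7)
  # zero the head: identical logits for both classes on every image
  mnvit:::walk_modules(m$net, function(mod, path) {
    if (path == "head/classifier") {
      mod$par$w[] <- 0
      mod$par$b[] <- 0
    }
  })
  r <- evaluate_model(m, d$man, split = "val", images = d$imgs)
  expect_identical(r$avg_acc, 0.5)
  expect_equal(sum(r$confusion), sum(d$man$split == "val"))
})

test_that("checkpoints round-trip and transfer matching follows name/shape", {
  d <- small_data()
  m <- build_model(small_cfg(), seed = 8)
  ck <- file.path(tempdir(), "m.ckpt")
  save_checkpoint(m, ck)
  expect_true(file.exists(ck))
  expect_true(file.exists(paste0(ck, ".json")))
  # identical architecture: everything matches
  m2 <- build_model(small_cfg(), seed = 9)
  rep_same <- load_pretrained(m2, ck, exclude_head = FALSE)
  expect_equal(rep_same$skipped, 0L)
  expect_equal(rep_same$reinitialized, 0L)
  expect_equal(collect_params(m2$net), collect_params(m$net))
  # standard-conv variant: decomposed tensors are skipped, shared trunk matches
  m3 <- build_model(small_cfg(decomposed = FALSE), seed = 10)
  stem_before <- collect_params(m3$net)[["stem/conv.w"]]
  rep_dd <- load_pretrained(m3, ck, exclude_head = FALSE)
  expect_gt(rep_dd$skipped, 0L)
  expect_gt(rep_dd$matched, 0L)
  expect_true(any(grepl("local", rep_dd$detail$tensor[
    startsWith(rep_dd$detail$status, "skipped")])))
  expect_equal(collect_params(m3$net)[["stem/conv.w"]],
               collect_params(m$net)[["stem/conv.w"]])
  # wider head: trunk matches fully, head reported reinitialized
  m4 <- build_model(small_cfg(num_classes = 4), seed = 11)
  rep_head <- load_pretrained(m4, ck, exclude_head = TRUE)
  expect_equal(rep_head$reinitialized, 2L)
  expect_equal(rep_head$skipped, 0L)
  expect_error(load_checkpoint(file.path(tempdir(), "missing.ckpt")),
               "not found")
})

test_that("predict resizes, standardizes and returns the requested type", {
  m <- build_model(small_cfg(), seed = 12)
  imgs <- list(array(runif(48 * 48 * 3), c(48, 48, 3)),
               array(runif(20 * 20 * 3), c(20, 20, 3)))
  pr <- predict(m, imgs, type = "prob")
  expect_equal(dim(pr), c(2L, 2L))
  expect_equal(colSums(pr), c(1, 1), tolerance = 1e-12)
  cl <- predict(m, imgs, type = "class")
  expect_true(all(cl %in% c(0L, 1L)))
  lg <- predict(m, imgs[[1]], type = "logits")
  expect_equal(dim(lg), c(2L, 1L))
})
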