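# Training loop contracts and evaluation plumbing (the full overfit smoke
# lives in the acceptance suite).

make_tiny_ds <- function(n = 6, seed = 5, dirname = "ds_train") {
  td <- file.path(tempdir(), dirname)
  unlink(td, recursive = TRUE)
  sp <- scene_spec(image_hw = c(64, 64), num_classes = 2,
                   area_range = c(150, 900), mean_objects = 2,
                   clutter_level = 0.3)
  generate_dataset(td, n, sp, seed = seed)
  td
}

test_that("zero iterations leaves weights unchanged with empty history", {
  td <- make_tiny_ds()
  set.seed(1)
  m <- build_model(model_variant(width_mult = 0.125, num_classes = 2))
  before <- lapply(collect_params(m), function(p) p$v)
  res <- train(m, td, train_config(image_size = 64, iterations = 0,
                                   batch_size = 4, lr = 0.01))
  expect_equal(nrow(res$history), 0)
  after <- lapply(collect_params(m), function(p) p$v)
  expect_identical(before, after)
})

test_that("a short run logs finite loss components and responds to the seed", {
  td <- make_tiny_ds()
  run <- function(seed) {
    set.seed(seed)
    m <- build_model(model_variant(width_mult = 0.125, num_classes = 2))
    train(m, td, train_config(image_size = 64, iterations = 3,
                              batch_size = 4, lr = 0.01, seed = seed))$history
  }
  h1 <- run(3)
  expect_equal(nrow(h1), 3)
  expect_true(all(is.finite(unlist(h1[, c("loss", "cls", "box", "dfl")]))))
  h1b <- run(3)
  expect_equal(h1$loss, h1b$loss, tolerance = 1e-12)  # same-seed reproducible
})

test_that("training aborts on an empty split", {
  td <- file.path(tempdir(), "ds_empty")
  unlink(td, recursive = TRUE)
  sp <- scene_spec(image_hw = c(64, 64), num_classes = 2,
                   area_range = c(150, 900))
  generate_dataset(td, 2, sp, seed = 1)  # 2 scenes: train split gets 1
  # remove the train images to simulate an empty split
  unlink(list.files(file.path(td, "images", "train"), full.names = TRUE))
  set.seed(1)
  m <- build_model(model_variant(width_mult = 0.125, num_classes = 2))
  expect_error(train(m, td, train_config(image_size = 64, iterations = 1)),
               "empty train split")
  unlink(td, recursive = TRUE)
})

test_that("evaluation is deterministic and bounded for an untrained model", {
  td <- make_tiny_ds(n = 6, seed = 9, dirname = "ds_eval")
  set.seed(2)
  m <- build_model(model_variant(width_mult = 0.125, num_classes = 2))
  c1 <- tempfile(fileext = ".csv"); c2 <- tempfile(fileext = ".csv")
  s1 <- evaluate(m, td, split = "val", image_size = 64, csv = c1)
  s2 <- evaluate(m, td, split = "val", image_size = 64, csv = c2)
  expect_identical(readLines(c1), readLines(c2))
  vals <- unlist(s1$table[, c("P", "R", "mAP50", "mAP50_95")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  unlink(c(c1, c2))
})

test_that("feeding the ground truth as predictions yields mAP50 = 1", {
  td <- make_tiny_ds(n = 6, seed = 4, dirname = "ds_gt")
  ds <- read_dataset(td)
  man <- ds$manifest
  gts <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    a <- read_yolo_labels(man$label[i])
    if (!nrow(a)) return(NULL)
    data.frame(image_id = i, class_id = a$class_id,
               x1 = (a$cx - a$w / 2) * 64, y1 = (a$cy - a$h / 2) * 64,
               x2 = (a$cx + a$w / 2) * 64, y2 = (a$cy + a$h / 2) * 64)
  }))
  preds <- transform(gts, conf = 1.0)
  expect_equal(map_at(preds, gts, 2, 0.5), 1)
  expect_equal(map50_95(preds, gts, 2), 1)
  unlink(td, recursive = TRUE)
})

test_that("the checkpoint written by train() restores the trained weights", {
  td <- make_tiny_ds(n = 6, seed = 6, dirname = "ds_ckpt")
  set.seed(4)
  m <- build_model(model_variant(width_mult = 0.125, num_classes = 2))
  ck <- tempfile(fileext = ".rds")
  train(m, td, train_config(image_size = 64, iterations = 2, batch_size = 4,
                            lr = 0.01, seed = 4), checkpoint = ck)
  m2 <- load_checkpoint(ck)
  x <- array(0.3, dim = c(1, 3, 64, 64))
  expect_equal(lapply(forward(m2, tz(x)), tz_value),
               lapply(forward(m, tz(x)), tz_value), tolerance = 1e-12)
  unlink(ck)
})
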