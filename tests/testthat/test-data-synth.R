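# Synthetic scenes, splits, YOLO labels and augmentation geometry.

test_that("scene generation is deterministic and respects the area range", {
  sp <- scene_spec(image_hw = c(96, 96), num_classes = 5,
                   area_range = c(200, 2000), tail_prob = 0)
  s1 <- generate_scene(sp, 7)
  s2 <- generate_scene(sp, 7)
  expect_identical(s1, s2)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  for (seed in 1:25) {
    a <- generate_scene(sp, seed)$annotations
    if (!nrow(a)) next
    areas <- a$w * 96 * a$h * 96
    # tight boxes shrink below the sampled ellipse box; never above range
    expect_true(all(areas <= 2000 * 1.05))
    expect_true(all(a$cx >= 0 & a$cx <= 1 & a$cy >= 0 & a$cy <= 1))
    expect_true(all(a$w > 0 & a$w <= 1 & a$h > 0 & a$h <= 1))
    expect_true(all(a$cx - a$w / 2 >= -1e-9 & a$cx + a$w / 2 <= 1 + 1e-9))
    expect_true(all(a$class_id >= 0 & a$class_id < 5))
  }
})

test_that("lesion counts follow the configured Poisson mean", {
  sp <- scene_spec(image_hw = c(64, 64), num_classes = 3, mean_objects = 2,
                   area_range = c(100, 600), clutter_level = 0,
                   max_objects = 50L)
  counts <- vapply(1:1000, function(s) {
    nrow(generate_scene(sp, s)$annotations)
  }, numeric(1))
  se <- sqrt(2 / 1000)
  expect_lt(abs(mean(counts) - 2), 3 * se)
})

test_that("the 7:2:1 split uses floor/floor/remainder and is a bijection", {
  s <- split_dataset(5841, c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(unname(s$sizes), c(4088, 1168, 585))
  expect_equal(unname(split_dataset(10)$sizes), c(7, 2, 1))
  expect_equal(unname(split_dataset(3)$sizes), c(2, 0, 1))
  for (n in c(1, 2, 17, 100)) {
    sp <- split_dataset(n, seed = 3)
    expect_equal(sum(sp$sizes), n)
    expect_equal(length(sp$split), n)
    expect_equal(as.vector(table(factor(sp$split,
                                        c("train", "val", "test")))),
                 unname(sp$sizes))
  }
})

test_that("YOLO label files parse, validate and round-trip", {
  path <- tempfile(fileext = ".txt")
  writeLines("3 0.5 0.5 0.2 0.1", path)
  a <- read_yolo_labels(path)
  expect_equal(a$class_id, 3L)
  expect_equal(unlist(a[1, 2:5], use.names = FALSE), c(0.5, 0.5, 0.2, 0.1))
  ann <- data.frame(class_id = c(0L, 4L), cx = c(0.25, 0.662501),
                    cy = c(0.5, 0.125), w = c(0.2, 0.04), h = c(0.1, 0.06))
  write_yolo_labels(path, ann)
  back <- read_yolo_labels(path)
  expect_equal(back, ann, tolerance = 1e-6)
  writeLines("3 1.5 0.5 0.2 0.1", path)
  expect_error(read_yolo_labels(path), "line 1.*out of")
  writeLines(c("0 0.5 0.5 0.1 0.1", "junk line"), path)
  expect_error(read_yolo_labels(path), "line 2")
  writeLines("7 0.5 0.5 0.1 0.1", path)
  expect_error(read_yolo_labels(path, num_classes = 5), "class id")
  unlink(path)
})

test_that("augmentation geometry identities hold", {
  sp <- scene_spec(image_hw = c(64, 64), num_classes = 3,
                   area_range = c(100, 800))
  sc <- generate_scene(sp, 3)
  expect_gt(nrow(sc$annotations), 0)
  # hflip maps cx -> 1 - cx and is an involution
  h1 <- augment(sc$image, sc$annotations, "hflip")
  expect_equal(h1$annotations$cx, 1 - sc$annotations$cx)
  expect_equal(h1$annotations[, c("cy", "w", "h")],
               sc$annotations[, c("cy", "w", "h")])
  h2 <- augment(h1$image, h1$annotations, "hflip")
  expect_equal(h2$image, sc$image)
  expect_equal(h2$annotations, sc$annotations)
  # rotation by 0 and 360 degrees is the identity on boxes
  for (ang in c(0, 360)) {
    r <- augment(sc$image, sc$annotations, "rotate", angle = ang)
    expect_equal(r$annotations, sc$annotations)
    expect_equal(r$image, sc$image)
  }
  # photometric ops leave annotations untouched
  b <- augment(sc$image, sc$annotations, "brightness", factor = 1.3)
  expect_identical(b$annotations, sc$annotations)
  expect_true(all(b$image >= 0 & b$image <= 1))
  ct <- augment(sc$image, sc$annotations, "contrast", factor = 0.7)
  expect_identical(ct$annotations, sc$annotations)
  # crops transform surviving boxes and fail on oversized windows
  cr <- augment(sc$image, sc$annotations, "crop", crop_box = c(8, 8, 40, 40))
  expect_equal(dim(cr$image), c(40, 40, 3))
  expect_true(all(cr$annotations$cx >= 0 & cr$annotations$cx <= 1))
  expect_error(augment(sc$image, sc$annotations, "crop",
                       crop_box = c(0, 0, 100, 100)), "crop larger")
})

test_that("a crop keeping the full frame preserves every annotation", {
  sp <- scene_spec(image_hw = c(64, 64), num_classes = 2,
                   area_range = c(100, 500))
  sc <- generate_scene(sp, 9)
  cr <- augment(sc$image, sc$annotations, "crop", crop_box = c(0, 0, 64, 64))
  expect_equal(cr$annotations, sc$annotations, tolerance = 1e-12)
})

test_that("dataset directories follow the YOLO layout and reload", {
  td <- file.path(tempdir(), "ds_layout")
  unlink(td, recursive = TRUE)
  sp <- scene_spec(image_hw = c(48, 48), num_classes = 3,
                   area_range = c(80, 400))
  man <- generate_dataset(td, 10, sp, seed = 2)
  expect_equal(nrow(man), 10)
  expect_true(file.exists(file.path(td, "data.yaml")))
  cfg <- yaml::read_yaml(file.path(td, "data.yaml"))
  expect_equal(cfg$nc, 3)
  expect_equal(length(cfg$names), 3)
  ds <- read_dataset(td)
  expect_equal(nrow(ds$manifest), 10)
  expect_equal(as.vector(table(factor(ds$manifest$split,
                                      c("train", "val", "test")))),
               c(7L, 2L, 1L))
  # labels re-read cleanly for every image
  for (l in ds$manifest$label) expect_silent(read_yolo_labels(l, 3))
  unlink(td, recursive = TRUE)
})
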