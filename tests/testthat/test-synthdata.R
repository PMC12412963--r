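# Procedural scene generator: determinism, label contracts, presets,
# rendering/label consistency, dataset layout.

test_that("scenes are bitwise reproducible and counts are exact", {
  sp <- scene_spec(image_size = 96)
  s1 <- generate_scene(sp, seed = 11)
  s2 <- generate_scene(sp, seed = 11)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  # zero objects: valid background, empty labels
  s0 <- generate_scene(scene_spec(image_size = 96, objects_range = c(0L, 0L)),
                       seed = 3)
  expect_equal(nrow(s0$labels), 0)
  expect_equal(dim(s0$image), c(96, 96, 3))
  # requested count on a roomy canvas is met exactly
  sp12 <- scene_spec(image_size = 400, occluder_density = 0, cluster_prob = 0)
  s12 <- generate_scene(sp12, seed = 5, n_objects = 12)
  expect_equal(nrow(s12$labels), 12)
})

test_that("labels are normalized center boxes inside the unit square", {
  sp <- scene_spec(image_size = 128)
  for (seed in 1:10) {
    lb <- generate_scene(sp, seed = seed)$labels
    if (nrow(lb) == 0) next
    expect_true(all(lb$w > 0 & lb$h > 0))
    expect_true(all(lb$cx - lb$w / 2 >= -1e-9 & lb$cx + lb$w / 2 <= 1 + 1e-9))
    expect_true(all(lb$cy - lb$h / 2 >= -1e-9 & lb$cy + lb$h / 2 <= 1 + 1e-9))
    expect_true(all(lb$class %in% 0:6))
  }
})

test_that("emitted boxes match boxes re-measured from the instance masks", {
  sp <- scene_spec(image_size = 160)
  n <- sp$image_size
  for (seed in c(2, 9, 17)) {
    sc <- generate_scene(sp, seed = seed)
    for (i in seq_along(sc$masks)) {
      ij <- which(sc$masks[[i]], arr.ind = TRUE)
      xs <- range(ij[, 2]); ys <- range(ij[, 1])
      meas <- c(mean(xs) / n, mean(ys) / n, (diff(xs) + 1) / n, (diff(ys) + 1) / n)
      lab <- unlist(sc$labels[i, c("cx", "cy", "w", "h")])
      expect_gte(bf_iou(meas, lab), 0.8)
    }
  }
})

test_that("difficulty presets order and coverage of scene conditions", {
  pr <- difficulty_presets(96)
  expect_equal(pr$easy$occluder_density, 0)
  expect_lte(mean(pr$easy$objects_range), 5)
  expect_gt(mean(pr$hard$objects_range), mean(pr$easy$objects_range))
  conds <- character()
  for (seed in 1:100)
    conds <- union(conds, generate_scene(pr$cfruit_like, seed = seed)$meta$conditions)
  needed <- c("cluster", "leaf_occlusion", "branch_occlusion", "overlap",
              "dense_targets", "size_variation", "backlight", "side_light",
              "earth_background", "foliage_similar_background", "sky_background")
  expect_true(all(needed %in% conds), info = paste("missing:",
              paste(setdiff(needed, conds), collapse = ", ")))
})

test_that("class draws track the configured class proportions", {
  sp <- scene_spec(image_size = 64)
  cls <- vapply(1:700, function(i) generate_scene(sp, seed = i)$meta$class, 0L)
  freq <- tabulate(cls + 1L, 7) / length(cls)
  expect_true(all(abs(freq - sp$class_probs) / sp$class_probs < 0.2))
})

test_that("write_dataset lays out YOLO files and round-trips labels", {
  root <- file.path(tempdir(), "ycf_ds_test")
  unlink(root, recursive = TRUE)
  sp <- scene_spec(image_size = 96)
  cfgp <- write_dataset(root, sp, n_train = 8, n_val = 2, seed = 1)
  expect_equal(length(dir(file.path(root, "images/train"))), 8)
  expect_equal(length(dir(file.path(root, "images/val"))), 2)
  expect_equal(length(dir(file.path(root, "labels/train"))), 8)
  cfg <- yaml::read_yaml(cfgp)
  expect_equal(cfg$names, c("bitter-melon", "cucumber", "cherry", "jujube",
                            "melon-boyang", "muskmelon", "strawberry"))
  # every label line parses as int + four floats in [0,1]
  for (f in dir(file.path(root, "labels/train"), full.names = TRUE)) {
    lb <- read_labels(f)
    if (nrow(lb) == 0) next
    expect_true(all(lb$class == floor(lb$class)))
    expect_true(all(lb$cx >= 0 & lb$cx <= 1 & lb$w >= 0 & lb$w <= 1))
  }
  # reload equals the generator output for the same seed stream
  ds <- load_dataset(cfgp, "train")
  sc1 <- generate_scene(sp, seed = 1 + 1 * 10007L)
  expect_equal(ds$labels[[1]], sc1$labels, tolerance = 1e-5)
  img1 <- read_image(ds$images[[1]])
  expect_equal(dim(img1), c(96, 96, 3))
  expect_lt(max(abs(img1 - sc1$image)), 1 / 255)   # 8-bit PNG quantization
  expect_error(write_dataset(root, sp, 1, 1, overwrite = FALSE), "non-empty")
  unlink(root, recursive = TRUE)
})
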