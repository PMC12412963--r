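# Assembly, variant factory, forward contracts, anchors.

test_that("head grids are img/stride at each scale with 3*(5+nc) channels", {
  m <- yolocf(variant = "cf5", num_classes = 7, img_size = 64)
  out <- yolocf_forward(m, rand_input(64, 64))
  expect_equal(lapply(out, function(o) dim(o)[1:3]),
               list(c(8, 8, 36), c(4, 4, 36), c(2, 2, 36)))
  # shape trace at the full 640 without computing
  s <- shape_tensor(640, 640, 3)
  outs <- yolocf_forward(m, s)
  expect_equal(vapply(outs, function(o) o$h, 0), c(80, 40, 20))
  expect_error(yolocf_forward(m, rand_input(60, 60)), "divisible")
  expect_error(yolocf(img_size = 100), "divisible")
})

test_that("variant factory fills the C-slots as specified", {
  slot_kinds <- function(v) {
    m <- yolocf(variant = v, img_size = 64)
    vapply(m$layers[c(3, 5, 7, 9)], function(l) l$block$kind, "")
  }
  expect_equal(slot_kinds("cf1"), rep("C2f", 4))
  expect_equal(slot_kinds("cf2"), c("C3", "C2f", "C3", "C2f"))
  expect_equal(slot_kinds("cf3"), c("C3", "C2fR", "C3", "C2fR"))
  expect_equal(slot_kinds("cf4"), rep("C3", 4))
  expect_equal(slot_kinds("cf5"), rep("C2fR", 4))
  expect_error(yolocf(variant = "cf9"))
})

test_that("batching and determinism of the forward pass", {
  m <- yolocf(variant = "cf3", img_size = 64)
  x <- rand_input(64, 64, 3, 2, seed = 21)
  o1 <- yolocf_forward(m, x)
  expect_equal(dim(o1[[1]])[4], 2L)
  o2 <- yolocf_forward(m, x)
  expect_identical(o1, o2)
})

test_that("every parameter receives a gradient after one training step", {
  m <- yolocf(variant = "cf5", num_classes = 2, img_size = 64)
  labels <- data.frame(image = 1L, class = 0:1, cx = c(0.3, 0.7),
                       cy = c(0.4, 0.6), w = c(0.2, 0.3), h = c(0.25, 0.2))
  ctx <- ycf_ctx(training = TRUE)
  x <- ag_leaf(rand_input(64, 64, 3, 1, seed = 22), ctx$tape)
  preds <- yolocf_forward(m, x, ctx)
  ls <- detection_loss(preds, labels, m$config)
  ag_backward(ls$total)
  expect_equal(length(ctx$params), length(m$params))
  missing <- vapply(ctx$params, function(p)
    any(vapply(p$.nodes, function(nd) is.null(nd$g), TRUE)), TRUE)
  expect_false(any(missing))
})

test_that("model YAML dump describes every layer", {
  m <- yolocf(variant = "cf5", img_size = 64)
  doc <- yaml::yaml.load(model_yaml(m))
  expect_equal(length(doc$layers), length(m$layers))
  expect_equal(doc$layers[[10]]$kind, "SPPR")
  expect_equal(doc$variant, "cf5")
})

test_that("weights round-trip through a checkpoint", {
  m <- yolocf(variant = "cf1", img_size = 64)
  x <- rand_input(64, 64, 3, 1, seed = 23)
  y1 <- yolocf_forward(m, x)
  ck <- tempfile(fileext = ".rds")
  save_weights(m, ck)
  m2 <- load_weights(ck)
  expect_equal(yolocf_forward(m2, x), y1)
})

test_that("autoanchor recovers degenerate and clustered box sizes", {
  lab1 <- data.frame(w = rep(0.1, 20), h = rep(0.2, 20))
  a1 <- autoanchor(lab1, k = 3, img_size = 100)
  expect_true(all(abs(a1[, "w"] - 10) < 1e-9 & abs(a1[, "h"] - 20) < 1e-9))
  set.seed(31)
  lab2 <- data.frame(w = c(runif(40, 0.05, 0.06), runif(40, 0.4, 0.42)),
                     h = c(runif(40, 0.05, 0.06), runif(40, 0.4, 0.42)))
  a2 <- autoanchor(lab2, k = 2, img_size = 100)
  expect_lt(abs(a2[1, "w"] - 5.5) / 5.5, 0.05)
  expect_lt(abs(a2[2, "w"] - 41) / 41, 0.05)
  expect_error(autoanchor(lab1[1:2, ], k = 3), "at least")
})

test_that("autoanchor falls back to the stock table when it cannot improve", {
  # boxes drawn exactly at the stock anchor sizes, in proportion
  def <- do.call(rbind, default_anchors())
  lab <- data.frame(w = rep(def[, 1], 8) / 640, h = rep(def[, 2], 8) / 640)
  a <- autoanchor(lab, k = 9, img_size = 640)
  expect_true(isTRUE(attr(a, "fallback")))
  expect_equal(a$p3, default_anchors()$p3)
})
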