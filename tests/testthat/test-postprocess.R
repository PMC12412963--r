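# Decoding, NMS, letterbox, timing identity.

test_that("decode: threshold behavior and per-anchor counting", {
  cfg <- yolocf_config(num_classes = 7, img_size = 64)
  off <- lapply(c(8, 4, 2), function(g) array(-1e4, c(g, g, 36, 1)))
  expect_equal(nrow(decode_predictions(off, cfg, 0.25)), 0)
  # conf 0 returns one detection per anchor per cell
  zero <- lapply(c(8, 4, 2), function(g) array(0, c(g, g, 36, 1)))
  expect_equal(nrow(decode_predictions(zero, cfg, 0)), 3 * (64 + 16 + 4))
})

test_that("decode inverts the encoding transform to high precision", {
  cfg <- yolocf_config(num_classes = 7, img_size = 64)
  set.seed(51)
  for (rep in 1:20) {
    s <- sample(1:3, 1)
    g <- c(8, 4, 2)[s]; stride <- 64 / g
    a <- sample(1:3, 1); anc <- cfg$anchors[[paste0("p", s + 2)]][a, ]
    gi <- sample(0:(g - 1), 1); gj <- sample(0:(g - 1), 1)
    fx <- runif(1, -0.4, 1.4); fy <- runif(1, -0.4, 1.4)
    sw <- runif(1, 0.3, 1.9); sh <- runif(1, 0.3, 1.9)
    logit <- function(p) log(p / (1 - p))
    preds <- lapply(c(8, 4, 2), function(gg) array(-1e4, c(gg, gg, 36, 1)))
    ch0 <- (a - 1) * 12
    preds[[s]][gj + 1, gi + 1, ch0 + 1:5, 1] <-
      c(logit((fx + 0.5) / 2), logit((fy + 0.5) / 2),
        logit(sqrt(sw) / 2), logit(sqrt(sh) / 2), 20)
    preds[[s]][gj + 1, gi + 1, ch0 + 5 + 4, 1] <- 20
    det <- decode_predictions(preds, cfg, 0.25)
    expect_equal(nrow(det), 1)
    expect_equal(det$cx, (gi + fx) * stride, tolerance = 1e-6)
    expect_equal(det$cy, (gj + fy) * stride, tolerance = 1e-6)
    expect_equal(det$w, sw * anc[1], tolerance = 1e-6)
    expect_equal(det$h, sh * anc[2], tolerance = 1e-6)
    expect_equal(det$class, 3)
  }
})

test_that("nms handles the worked example, disjoint boxes, and duplicates", {
  # A(0.9) suppresses B(0.7) at IoU ~0.8; disjoint C(0.6) survives
  d <- data.frame(cx = c(0, 1, 100), cy = c(0, 0, 100), w = c(10, 10, 5),
                  h = c(10, 10, 5), class = 0L, score = c(0.9, 0.7, 0.6))
  r <- nms(d, 0.5)
  expect_equal(sort(r$score), c(0.6, 0.9))
  expect_equal(nrow(nms(d[c(1, 3), ], 0.5)), 2)    # disjoint preserved
  dup <- d[c(1, 1, 1), ]
  expect_equal(nrow(nms(dup, 0.5)), 1)             # exact duplicates collapse
  # different classes never suppress each other
  d2 <- d[1:2, ]; d2$class <- c(0L, 1L)
  expect_equal(nrow(nms(d2, 0.5)), 2)
})

test_that("nms equals the brute-force suppression oracle on random scenes", {
  set.seed(52)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    d <- data.frame(cx = runif(n, 0, 40), cy = runif(n, 0, 40),
                    w = runif(n, 4, 20), h = runif(n, 4, 20),
                    class = sample(0:2, n, replace = TRUE),
                    score = round(runif(n), 3))
    thr <- sample(c(0.3, 0.45, 0.6), 1)
    got <- nms(d, thr)
    want <- bf_nms(d, thr)
    expect_equal(got[order(-got$score), c("cx", "score", "class")],
                 want[order(-want$score), c("cx", "score", "class")],
                 ignore_attr = TRUE)
    # post-hoc: no surviving same-class pair above the threshold
    if (nrow(got) > 1) {
      iou <- yolocf:::box_iou_xywh(as.matrix(got[, 1:4]), as.matrix(got[, 1:4]))
      same <- outer(got$class, got$class, "==")
      diag(iou) <- 0
      expect_lte(max(iou[same]), thr)
    }
  }
})

test_that("letterbox preserves aspect and maps coordinates back", {
  img <- array(runif(30 * 60 * 3), c(30, 60, 3))
  lb <- letterbox(img, 64)
  expect_equal(dim(lb$img), c(64, 64, 3))
  expect_equal(lb$scale, 64 / 60)
  expect_equal(lb$pad[1], (64 - round(30 * 64 / 60)) %/% 2)
})

test_that("timing report satisfies the fps identity", {
  m <- yolocf(variant = "cf5", img_size = 64)
  tr <- time_inference(m, array(runif(64 * 64 * 3), c(64, 64, 3)), repeats = 1)
  expect_equal(tr$fps, 1000 / (tr$t_pre + tr$t_infer + tr$t_post))
  # synthetic stage times: (1, 2, 1) ms give 250 fps
  expect_equal(1000 / (1 + 2 + 1), 250)
})

test_that("detection writers emit jsonl and YOLO text with scores", {
  d <- data.frame(cx = 32, cy = 16, w = 10, h = 8, class = 2L, score = 0.75)
  fj <- tempfile(fileext = ".jsonl"); ft <- tempfile(fileext = ".txt")
  write_detections(d, fj)
  write_detections(d, ft, img_dim = c(64, 64))
  j <- jsonlite::fromJSON(readLines(fj))
  expect_equal(j$cx, 32)
  tx <- strsplit(readLines(ft), " ")[[1]]
  expect_equal(as.integer(tx[1]), 2L)
  expect_equal(as.numeric(tx[2]), 0.5)
  expect_equal(as.numeric(tx[6]), 0.75)
})
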