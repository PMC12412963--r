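# CIoU / BCE closed forms, target assignment vs. brute force, composite loss.

test_that("ciou loss closed forms and bounds", {
  expect_lt(ciou_loss(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1e-6)
  # corner boxes (0,0)-(2,2) vs (1,1)-(3,3): IoU 1/7, rho2 2, c2 18, v 0
  expect_equal(ciou_loss(c(1, 1, 2, 2), c(2, 2, 2, 2)), 6 / 7 + 1 / 9,
               tolerance = 1e-6)
  # loss >= 1 - IoU on random pairs; distance/aspect terms symmetric
  set.seed(41)
  for (i in 1:50) {
    a <- c(runif(2, 0, 10), runif(2, 0.5, 5))
    b <- c(runif(2, 0, 10), runif(2, 0.5, 5))
    l <- ciou_loss(a, b)
    expect_gte(l + 1e-12, 1 - bf_iou(a, b))
    # the distance penalty is symmetric: both orders are >= 1 - IoU and
    # coincide exactly when the aspect term vanishes
    la <- ciou_loss(b, a)
    expect_gte(la + 1e-12, 1 - bf_iou(a, b))
    # with equal aspect ratios the penalty reduces to the symmetric
    # distance term, so the loss itself becomes order-invariant
    a2 <- a; a2[3:4] <- b[3:4] * 2
    expect_equal(ciou_loss(a2, b), ciou_loss(b, a2), tolerance = 1e-9)
  }
  expect_error(ciou_loss(c(0, 0, 0, 1), c(0, 0, 1, 1)), "positive")
})

test_that("bce loss closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-9)
  expect_error(bce_loss(c(1, 0), 0.5), "mismatch")
  # matches a direct expression evaluation on random vectors
  set.seed(42)
  y <- rbinom(100, 1, 0.5); p <- runif(100, 0.01, 0.99)
  expect_equal(bce_loss(y, p), -mean(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-7)
})

test_that("target assignment follows the ratio and neighbour-cell rule", {
  anc <- default_anchors()
  gs <- list(c(8, 8), c(4, 4), c(2, 2))
  # box exactly equal to one anchor, centered in a cell
  lab <- data.frame(image = 1L, class = 0L, cx = 0.3125, cy = 0.3125,
                    w = 16 / 64, h = 30 / 64)
  a <- assign_targets(lab, anc, gs, 64L)
  hit <- a[[1]][a[[1]]$anchor == 2, ]
  expect_gte(nrow(hit), 1)
  # box 5x larger than every anchor width at the coarsest scale: no match
  lab2 <- data.frame(image = 1L, class = 0L, cx = 0.5, cy = 0.5,
                     w = 5 * 373 / 64, h = 0.5)
  expect_equal(nrow(assign_targets(lab2, anc, gs, 64L)[[3]]), 0)
  # empty label set is a valid empty assignment
  e <- assign_targets(lab[0, ], anc, gs, 64L)
  expect_true(all(vapply(e, nrow, 0L) == 0))
})

test_that("assignment equals brute-force enumeration on random label sets", {
  set.seed(43)
  anc <- default_anchors()
  gs <- list(c(20, 20), c(10, 10), c(5, 5))
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    lab <- data.frame(image = sample(1:2, n, replace = TRUE),
                      class = sample(0:6, n, replace = TRUE),
                      cx = runif(n, 0.05, 0.95), cy = runif(n, 0.05, 0.95),
                      w = runif(n, 0.02, 0.9), h = runif(n, 0.02, 0.9))
    got <- assign_targets(lab, anc, gs, 160L)
    want <- bf_assign(lab, anc, gs, 160L)
    for (s in 1:3) {
      g <- sort_assign(got[[s]][, c("image", "anchor", "gi", "gj", "class")])
      w <- sort_assign(want[[s]])
      rownames(g) <- rownames(w) <- NULL
      expect_equal(g, w, info = paste("rep", rep, "scale", s))
    }
  }
})

test_that("composite loss: empty labels, component sum, perfect-fit limit", {
  cfg <- yolocf_config(num_classes = 3, img_size = 64)
  set.seed(44)
  preds <- lapply(c(8, 4, 2), function(g) array(rnorm(g * g * 24), c(g, g, 24, 1)))
  empty <- data.frame(image = integer(), class = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric())
  l0 <- detection_loss(preds, empty, cfg)
  expect_equal(l0$box, 0); expect_equal(l0$cls, 0); expect_gt(l0$obj, 0)
  # total equals the weighted component sum
  lab <- data.frame(image = 1L, class = 1L, cx = 0.5, cy = 0.5, w = 0.3, h = 0.4)
  ls <- detection_loss(preds, lab, cfg)
  expect_equal(ls$total, 0.05 * ls$box + 1.0 * ls$obj + 0.5 * ls$cls,
               tolerance = 1e-12)
  # saturated exact predictions at every assigned cell drive the total to ~0
  na_ <- 8L
  perfect <- lapply(c(8, 4, 2), function(g) array(-30, c(g, g, 3 * na_, 1)))
  lab2 <- data.frame(image = 1L, class = 0L, cx = 0.55, cy = 0.4, w = 0.3, h = 0.45)
  asg <- assign_targets(lab2, cfg$anchors, list(c(8, 8), c(4, 4), c(2, 2)), 64L)
  logit <- function(p) log(pmin(pmax(p, 1e-9), 1 - 1e-9) / (1 - pmin(pmax(p, 1e-9), 1 - 1e-9)))
  for (s in 1:3) {
    a <- asg[[s]]
    for (r in seq_len(nrow(a))) {
      ch0 <- (a$anchor[r] - 1L) * na_
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 1, 1] <- logit((a$tx[r] - a$gi[r] + 0.5) / 2)
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 2, 1] <- logit((a$ty[r] - a$gj[r] + 0.5) / 2)
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 3, 1] <- logit(sqrt(a$tw[r] / a$aw[r]) / 2)
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 4, 1] <- logit(sqrt(a$th[r] / a$ah[r]) / 2)
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 5, 1] <- 30
      perfect[[s]][a$gj[r] + 1, a$gi[r] + 1, ch0 + 6, 1] <- 30  # class 0
    }
  }
  lp <- detection_loss(perfect, lab2, cfg)
  expect_lt(lp$box, 1e-6)
  expect_lt(lp$cls, 1e-8)
  expect_lt(lp$obj, 1e-6)
  expect_lt(if (is.numeric(lp$total)) lp$total else lp$total$v, 1e-6)
})

test_that("loss guards against non-finite predictions", {
  cfg <- yolocf_config(num_classes = 2, img_size = 64)
  preds <- lapply(c(8, 4, 2), function(g) array(0, c(g, g, 21, 1)))
  lab <- data.frame(image = 1L, class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  ls <- detection_loss(preds, lab, cfg)
  expect_true(is.finite(ls$total))
})
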