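# Detection metrics and count analysis.

.mkdet <- function(cx, cy, w, h, class, score)
  data.frame(cx = cx, cy = cy, w = w, h = h, class = class, score = score)

test_that("perfect and empty detections give the boundary P/R values", {
  truth <- .mkdet(c(10, 30), c(10, 30), c(8, 8), c(8, 8), c(0, 1), NA)[, 1:5]
  ev <- evaluate_detections(list(cbind(truth, score = 0.9)), list(truth), 2)
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1); expect_equal(ev$mAP, 1)
  empty <- .mkdet(numeric(), numeric(), numeric(), numeric(), integer(), numeric())
  ev0 <- evaluate_detections(list(empty), list(truth), 2)
  expect_equal(ev0$precision, 0); expect_equal(ev0$recall, 0); expect_equal(ev0$mAP, 0)
})

test_that("greedy matching agrees with exhaustive checking on small cases", {
  set.seed(61)
  for (rep in 1:30) {
    nt <- sample(1:4, 1); nd <- sample(1:5, 1)
    truth <- .mkdet(runif(nt, 5, 35), runif(nt, 5, 35), runif(nt, 4, 12),
                    runif(nt, 4, 12), sample(0:1, nt, TRUE), NA)[, 1:5]
    det <- .mkdet(runif(nd, 5, 35), runif(nd, 5, 35), runif(nd, 4, 12),
                  runif(nd, 4, 12), sample(0:1, nd, TRUE), runif(nd))
    m <- match_detections(det, truth, 0.5)
    # independent re-derivation of the greedy order outcome
    ord <- order(-det$score)
    used <- rep(FALSE, nt); want_tp <- logical(nd)
    for (i in seq_len(nd)) {
      di <- det[ord[i], ]
      best <- 0; bj <- 0
      for (j in seq_len(nt)) {
        if (used[j] || truth$class[j] != di$class) next
        iou <- bf_iou(unlist(di[1, 1:4]), unlist(truth[j, 1:4]))
        if (iou >= 0.5 && iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0) { used[bj] <- TRUE; want_tp[i] <- TRUE }
    }
    expect_equal(m$tp, want_tp, info = paste("rep", rep))
  }
})

test_that("average precision closed forms under 101-point interpolation", {
  expect_equal(average_precision(TRUE, 1), 1)
  # one FP ranked above one TP: direct curve integration — at every knot the
  # best precision at recall >= r is 0.5, so the interpolated AP is 0.5
  ranked_recall <- c(0, 1); ranked_precision <- c(0, 0.5)
  want <- mean(vapply(seq(0, 1, length.out = 101), function(r)
    max(c(0, ranked_precision[ranked_recall >= r])), 0))
  ap <- average_precision(c(FALSE, TRUE), 1)
  expect_equal(ap, want, tolerance = 1e-12)
  expect_equal(ap, 0.5)
  expect_equal(average_precision(logical(0), 0), NA_real_)
  expect_equal(average_precision(logical(0), 2), 0)
})

test_that("mAP is the unweighted class mean, ignoring unseen classes", {
  truth1 <- .mkdet(10, 10, 8, 8, 0, NA)[, 1:5]
  truth2 <- .mkdet(10, 10, 8, 8, 1, NA)[, 1:5]
  det1 <- cbind(truth1, score = 0.9)                 # class 0 perfect
  det2 <- .mkdet(100, 100, 8, 8, 1, 0.8)            # class 1 all wrong
  ev <- evaluate_detections(list(det1, det2), list(truth1, truth2), 3)
  expect_equal(ev$mAP, 0.5)                         # classes 0 and 1 only
  expect_true(is.na(ev$per_class$ap[3]))
})

test_that("adding a false positive never increases AP", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    tp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    nt <- max(1L, sum(tp))
    base <- average_precision(tp, nt)
    at <- sample(0:n, 1)
    with_fp <- append(tp, FALSE, after = at)
    expect_lte(average_precision(with_fp, nt), base + 1e-12)
  }
})

test_that("count analysis reproduces hand-computed values and errors", {
  ca <- count_analysis(c(3, 5, 2), c(2, 5, 4))
  expect_equal(ca$mae, 1)
  expect_equal(ca$rmse, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(ca$r2, 1 - 5 / (14 / 3), tolerance = 1e-12)  # negative R^2
  exact <- count_analysis(c(3, 5, 2), c(3, 5, 2))
  expect_equal(c(exact$mae, exact$rmse, exact$r2), c(0, 0, 1))
  ybar <- count_analysis(c(3, 5, 2), rep(10 / 3, 3))
  expect_equal(ybar$r2, 0, tolerance = 1e-12)
  expect_error(count_analysis(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_error(count_analysis(1, 1), "two images")
})

test_that("MAE <= RMSE always; R^2 invariant to joint permutation", {
  set.seed(63)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    y <- rpois(n, 6); if (var(y) == 0) y[1] <- y[1] + 1L
    yh <- pmax(0, y + sample(-3:3, n, replace = TRUE))
    ca <- count_analysis(y, yh)
    expect_lte(ca$mae, ca$rmse + 1e-12)
    p <- sample(n)
    expect_equal(count_analysis(y[p], yh[p])$r2, ca$r2, tolerance = 1e-12)
  }
})

test_that("detection counts pool or split by class", {
  dl <- list(.mkdet(c(1, 2, 3), c(1, 2, 3), 1, 1, c(0, 0, 1), c(0.9, 0.1, 0.5)))
  expect_equal(detection_counts(dl, conf = 0.25), 2L)
  expect_equal(detection_counts(dl, conf = 0.25, per_class = TRUE)[, 1], c(1L, 1L))
})
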