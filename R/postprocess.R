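# ---------------------------------------------------------------------------
# Decoding raw grids into detections, confidence filtering, class-aware
# greedy NMS, letterboxing, and the timing decomposition.
# ---------------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode raw head outputs into detections
#'
#' Applies the grid transforms (`xy = 2*sigmoid - 0.5 + cell`,
#' `wh = (2*sigmoid)^2 * anchor`) per anchor and cell, forms
#' `score = sigmoid(obj) * sigmoid(cls)`, takes the best class per anchor
#' position and drops detections below `conf`.
#'
#' @param preds List of three raw per-scale outputs for a single image
#'   (`(H,W,3*(5+nc),1)` or `(H,W,3*(5+nc))` arrays).
#' @param config The model's [yolocf_config()].
#' @param conf Confidence threshold.
#' @return Data frame `cx, cy, w, h` (pixels at network input scale),
#'   `class` (0-based), `score`.
#' @export
decode_predictions <- function(preds, config, conf = 0.25) {
  nc <- config$num_classes; na_ <- 5L + nc
  out <- list()
  for (s in 1:3) {
    p <- preds[[s]]
    d <- dim(p)
    if (length(d) == 4L) { if (d[4] != 1L) stop("decode expects a single image"); dim(p) <- d[1:3] }
    d <- dim(p)
    gh <- d[1]; gw <- d[2]
    stride <- config$img_size / gh
    anc <- config$anchors[[s]]
    cell_x <- rep(0:(gw - 1L), each = gh)
    cell_y <- rep(0:(gh - 1L), times = gw)
    for (a in 1:3) {
      ch0 <- (a - 1L) * na_
      tx <- sigmoid(as.vector(p[, , ch0 + 1L]))
      ty <- sigmoid(as.vector(p[, , ch0 + 2L]))
      tw <- sigmoid(as.vector(p[, , ch0 + 3L]))
      th <- sigmoid(as.vector(p[, , ch0 + 4L]))
      obj <- sigmoid(as.vector(p[, , ch0 + 5L]))
      cls <- matrix(sigmoid(as.vector(p[, , (ch0 + 6L):(ch0 + 5L + nc)])), ncol = nc)
      best <- max.col(cls, ties.method = "first")
      score <- obj * cls[cbind(seq_along(best), best)]
      keep <- score >= conf
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        cx = ((tx * 2 - 0.5)[keep] + cell_x[keep]) * stride,
        cy = ((ty * 2 - 0.5)[keep] + cell_y[keep]) * stride,
        w = (tw * 2)[keep]^2 * anc[a, 1],
        h = (th * 2)[keep]^2 * anc[a, 2],
        class = best[keep] - 1L,
        score = score[keep])
    }
  }
  if (length(out) == 0)
    data.frame(cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
               class = integer(), score = numeric())
  else do.call(rbind, out)
}

# pairwise IoU between two sets of center-format boxes (matrix n x 4)
box_iou_xywh <- function(a, b) {
  al <- a[, 1] - a[, 3] / 2; ar <- a[, 1] + a[, 3] / 2
  at <- a[, 2] - a[, 4] / 2; ab <- a[, 2] + a[, 4] / 2
  bl <- b[, 1] - b[, 3] / 2; br <- b[, 1] + b[, 3] / 2
  bt <- b[, 2] - b[, 4] / 2; bb <- b[, 2] + b[, 4] / 2
  iw <- outer(ar, br, pmin) - outer(al, bl, pmax)
  ih <- outer(ab, bb, pmin) - outer(at, bt, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  aa <- a[, 3] * a[, 4]; ba <- b[, 3] * b[, 4]
  inter / (outer(aa, ba, "+") - inter + 1e-7)
}

#' Class-aware greedy non-maximum suppression
#'
#' Detections are taken in decreasing score order; a detection is suppressed
#' when a same-class survivor overlaps it with IoU above `iou_thr`.
#' Ties break by score, then box area, then input order.
#'
#' @param detections Data frame as returned by [decode_predictions()].
#' @param iou_thr IoU threshold (0.45 default).
#' @return The surviving subset, score-descending.
#' @export
nms <- function(detections, iou_thr = 0.45) {
  n <- nrow(detections)
  if (n == 0) return(detections)
  area <- detections$w * detections$h
  ord <- order(-detections$score, -area, seq_len(n))
  d <- detections[ord, , drop = FALSE]
  boxes <- as.matrix(d[, c("cx", "cy", "w", "h")])
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == n) break
    rest <- which(alive & seq_len(n) > i)
    if (length(rest) == 0) break
    iou <- box_iou_xywh(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])[1, ]
    kill <- rest[iou > iou_thr & d$class[rest] == d$class[i]]
    alive[kill] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' Letterbox an image to the network input size
#'
#' Aspect-preserving nearest-neighbour resize padded with gray (114/255) to
#' `new_size` x `new_size`.
#'
#' @param img `(H,W,3)` array in `[0,1]`.
#' @param new_size Target side length.
#' @return List `img` (letterboxed array), `scale`, `pad = c(top, left)` for
#'   mapping coordinates back.
#' @export
letterbox <- function(img, new_size = 640L) {
  d <- dim(img)
  r <- min(new_size / d[1], new_size / d[2])
  nh <- round(d[1] * r); nw <- round(d[2] * r)
  ih <- pmin(pmax(ceiling((1:nh) / r), 1L), d[1])
  iw <- pmin(pmax(ceiling((1:nw) / r), 1L), d[2])
  resized <- img[ih, iw, , drop = FALSE]
  out <- array(114 / 255, c(new_size, new_size, 3L))
  top <- (new_size - nh) %/% 2L; left <- (new_size - nw) %/% 2L
  out[top + (1:nh), left + (1:nw), ] <- resized
  list(img = out, scale = r, pad = c(top, left))
}

#' Run detection on one image
#'
#' Letterboxes, runs the network, decodes, applies NMS, and maps boxes back
#' to the original pixel space.
#'
#' @param object A [yolocf()] model.
#' @param newdata `(H,W,3)` array in `[0,1]`, or a PNG file path.
#' @param conf,iou_thr Confidence and NMS thresholds.
#' @param ... Unused.
#' @return Data frame of detections in original-image pixels.
#' @export
predict.yolocf <- function(object, newdata, conf = 0.25, iou_thr = 0.45, ...) {
  img <- if (is.character(newdata)) read_image(newdata) else newdata
  lb <- letterbox(img, object$config$img_size)
  x <- lb$img; dim(x) <- c(dim(x), 1L)
  preds <- yolocf_forward(object, x)
  det <- nms(decode_predictions(preds, object$config, conf), iou_thr)
  det$cx <- (det$cx - lb$pad[2]) / lb$scale
  det$cy <- (det$cy - lb$pad[1]) / lb$scale
  det$w <- det$w / lb$scale
  det$h <- det$h / lb$scale
  det
}

#' Timing decomposition of one inference
#'
#' Mean wall-clock milliseconds of preprocessing (letterbox), network
#' forward, and postprocessing (decode + NMS), with
#' `fps = 1000 / (t_pre + t_infer + t_post)`. Hardware-dependent by nature.
#'
#' @param model A [yolocf()] model.
#' @param img `(H,W,3)` array.
#' @param repeats Timed repetitions (after one warm-up).
#' @export
time_inference <- function(model, img, repeats = 3L) {
  ms <- function(expr) 1000 * system.time(expr)[["elapsed"]]
  lb <- letterbox(img, model$config$img_size)  # warm-up pre
  x <- lb$img; dim(x) <- c(dim(x), 1L)
  invisible(yolocf_forward(model, x))          # warm-up infer
  t_pre <- t_inf <- t_post <- numeric(repeats)
  for (i in seq_len(repeats)) {
    t_pre[i] <- ms(lb <- letterbox(img, model$config$img_size))
    x <- lb$img; dim(x) <- c(dim(x), 1L)
    t_inf[i] <- ms(preds <- yolocf_forward(model, x))
    t_post[i] <- ms(nms(decode_predictions(preds, model$config, 0.25), 0.45))
  }
  tp <- mean(t_pre); ti <- mean(t_inf); to <- mean(t_post)
  structure(list(t_pre = tp, t_infer = ti, t_post = to,
                 fps = 1000 / (tp + ti + to)), class = "ycf_timing")
}

#' @export
print.ycf_timing <- function(x, ...) {
  cat(sprintf("pre %.2f ms | infer %.2f ms | post %.2f ms | %.1f fps\n",
              x$t_pre, x$t_infer, x$t_post, x$fps))
  invisible(x)
}

#' Write detections to file
#'
#' JSON-lines (one detection object per line) or YOLO-format text with an
#' appended score column, chosen by extension (`.jsonl` vs `.txt`).
#'
#' @param detections Detection data frame (original-image pixels).
#' @param path Output file.
#' @param img_dim `c(H, W)` of the image, required for the normalized
#'   YOLO text format.
#' @export
write_detections <- function(detections, path, img_dim = NULL) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(detections)))
      writeLines(jsonlite::toJSON(as.list(detections[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    if (is.null(img_dim)) stop("img_dim required for YOLO text output")
    lines <- sprintf("%d %.6f %.6f %.6f %.6f %.4f", detections$class,
                     detections$cx / img_dim[2], detections$cy / img_dim[1],
                     detections$w / img_dim[2], detections$h / img_dim[1],
                     detections$score)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an image file
#'
#' @param path PNG file.
#' @return `(H,W,3)` array in `[0,1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Render detections onto an image
#'
#' Draws box outlines (one color per class) directly into the pixel array —
#' a quick visual check of detector output.
#'
#' @param img `(H,W,3)` array.
#' @param detections Detection data frame in pixels of `img`.
#' @param path Optional PNG output path.
#' @return The annotated array (invisibly when written to `path`).
#' @export
render_detections <- function(img, detections, path = NULL) {
  d <- dim(img)
  cols <- grDevices::col2rgb(grDevices::hcl.colors(max(detections$class + 1L, 1L),
                                                   "Dark 3")) / 255
  for (i in seq_len(nrow(detections))) {
    b <- detections[i, ]
    x1 <- max(1L, round(b$cx - b$w / 2)); x2 <- min(d[2], round(b$cx + b$w / 2))
    y1 <- max(1L, round(b$cy - b$h / 2)); y2 <- min(d[1], round(b$cy + b$h / 2))
    cl <- cols[, b$class + 1L]
    for (c in 1:3) {
      img[y1:y2, c(x1, x2), c] <- cl[c]
      img[c(y1, y2), x1:x2, c] <- cl[c]
    }
  }
  if (!is.null(path)) { png::writePNG(img, path); return(invisible(img)) }
  img
}
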