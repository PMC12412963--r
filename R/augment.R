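# ---------------------------------------------------------------------------
# Training-time augmentation: 2x2 mosaic, random scale/translate affine,
# HSV color jitter. All label geometry is center-format normalized.
# ---------------------------------------------------------------------------

# vectorized RGB<->HSV on (H,W,3) arrays, h/s/v in [0,1]
.rgb2hsv_arr <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  array(hsv, d)
}
.hsv2rgb_arr <- function(hsv) {
  d <- dim(hsv)
  h <- as.vector(hsv[, , 1]) * 6; s <- as.vector(hsv[, , 2]); v <- as.vector(hsv[, , 3])
  i <- floor(h) %% 6; f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  sel <- cbind(seq_along(i), i + 1L)         # sector lookup, one pick per pixel
  r <- cbind(v, q, p, p, t, v)[sel]
  g <- cbind(t, v, v, q, p, p)[sel]
  b <- cbind(p, p, t, v, v, q)[sel]
  array(c(r, g, b), d)
}

#' HSV color augmentation
#'
#' Random hue shift, saturation and value gains within the given fractions;
#' labels are unaffected. Draws three uniforms from the current RNG stream.
#'
#' @param img `(H,W,3)` array in `[0,1]`.
#' @param gains `c(h, s, v)` maximal fractional perturbations
#'   (0.015/0.7/0.4 by default).
#' @return Augmented image, clipped to `[0,1]`.
#' @export
hsv_augment <- function(img, gains = c(0.015, 0.7, 0.4)) {
  r <- stats::runif(3, -1, 1) * gains
  if (all(r == 0)) return(img)
  hsv <- .rgb2hsv_arr(img)
  hsv[, , 1] <- (hsv[, , 1] + r[1]) %% 1
  hsv[, , 2] <- pmin(pmax(hsv[, , 2] * (1 + r[2]), 0), 1)
  hsv[, , 3] <- pmin(pmax(hsv[, , 3] * (1 + r[3]), 0), 1)
  .hsv2rgb_arr(hsv)
}

# nearest-neighbour resize of an (H,W,3) array
.resize_nn <- function(img, nh, nw) {
  d <- dim(img)
  img[pmin(pmax(round(seq(1, d[1], length.out = nh)), 1), d[1]),
      pmin(pmax(round(seq(1, d[2], length.out = nw)), 1), d[2]), , drop = FALSE]
}

# clip normalized center boxes to [0,1]; drop boxes thinner than min_px
.clip_labels <- function(lab, size_px, min_px = 2) {
  if (nrow(lab) == 0) return(lab)
  x1 <- pmax(lab$cx - lab$w / 2, 0); x2 <- pmin(lab$cx + lab$w / 2, 1)
  y1 <- pmax(lab$cy - lab$h / 2, 0); y2 <- pmin(lab$cy + lab$h / 2, 1)
  keep <- (x2 - x1) * size_px >= min_px & (y2 - y1) * size_px >= min_px
  data.frame(class = lab$class[keep], cx = ((x1 + x2) / 2)[keep],
             cy = ((y1 + y2) / 2)[keep], w = (x2 - x1)[keep], h = (y2 - y1)[keep])
}

#' Mosaic augmentation
#'
#' Assembles four samples into a 2x2 collage around a jittered center on a
#' double-size canvas, remaps and clips their labels, drops degenerate
#' clipped boxes, and scales the canvas back to the sample size.
#'
#' @param samples List of four `list(image, labels)` with equal square
#'   images and normalized labels.
#' @param jitter Center jitter as a fraction of the image size (0 places the
#'   center exactly in the middle, making each quadrant an affine copy).
#' @return `list(image, labels)` of the collage.
#' @export
mosaic_augment <- function(samples, jitter = 0.3) {
  if (length(samples) < 4L) stop("mosaic needs four samples")
  s <- dim(samples[[1]]$image)[1]
  S <- 2L * s
  cx <- round(s * (1 + stats::runif(1, -jitter, jitter)))
  cy <- round(s * (1 + stats::runif(1, -jitter, jitter)))
  canvas <- array(114 / 255, c(S, S, 3))
  lab <- list()
  # regions: TL, TR, BL, BR relative to (cy, cx)
  regions <- list(c(1, cy, 1, cx), c(1, cy, cx + 1, S),
                  c(cy + 1, S, 1, cx), c(cy + 1, S, cx + 1, S))
  for (q in 1:4) {
    rg <- regions[[q]]
    rh <- rg[2] - rg[1] + 1L; rw <- rg[4] - rg[3] + 1L
    if (rh < 1 || rw < 1) next
    im <- samples[[q]]$image
    # align the image toward the mosaic center: take the matching corner crop
    rows <- if (q %in% c(1, 2)) (s - min(rh, s) + 1):s else 1:min(rh, s)
    cols <- if (q %in% c(1, 3)) (s - min(rw, s) + 1):s else 1:min(rw, s)
    tr <- if (q %in% c(1, 2)) rg[2] - length(rows) + 1L else rg[1]
    tc <- if (q %in% c(1, 3)) rg[4] - length(cols) + 1L else rg[3]
    canvas[tr:(tr + length(rows) - 1L), tc:(tc + length(cols) - 1L), ] <-
      im[rows, cols, , drop = FALSE]
    lq <- samples[[q]]$labels
    if (nrow(lq) > 0) {
      # pixel offset of the original image origin on the canvas
      offy <- tr - rows[1]; offx <- tc - cols[1]
      px <- lq$cx * s + offx; py <- lq$cy * s + offy
      lab[[length(lab) + 1L]] <- data.frame(
        class = lq$class, cx = px / S, cy = py / S,
        w = lq$w * s / S, h = lq$h * s / S)
    }
  }
  labels <- if (length(lab)) do.call(rbind, lab)
            else data.frame(class = integer(), cx = numeric(), cy = numeric(),
                            w = numeric(), h = numeric())
  labels <- .clip_labels(labels, S)
  list(image = .resize_nn(canvas, s, s), labels = labels)
}

#' Random scale/translate affine augmentation
#'
#' Scales the image about its center by a factor in `[1-scale, 1+scale]`
#' and shifts it by up to `translate` of the size, padding with gray;
#' labels are remapped, clipped and pruned.
#'
#' @param sample `list(image, labels)`.
#' @param scale,translate Augmentation magnitudes.
#' @export
affine_augment <- function(sample, scale = 0.5, translate = 0.1) {
  img <- sample$image; lab <- sample$labels
  s <- dim(img)[1]
  f <- stats::runif(1, 1 - scale, 1 + scale)
  tx <- stats::runif(1, -translate, translate) * s
  ty <- stats::runif(1, -translate, translate) * s
  out <- array(114 / 255, dim(img))
  # destination pixel (y, x) samples source ((y - ty - c)/f + c)
  ctr <- (s + 1) / 2
  sy <- round((seq_len(s) - ty - ctr) / f + ctr)
  sx <- round((seq_len(s) - tx - ctr) / f + ctr)
  vy <- which(sy >= 1 & sy <= s); vx <- which(sx >= 1 & sx <= s)
  out[vy, vx, ] <- img[sy[vy], sx[vx], , drop = FALSE]
  if (nrow(lab) > 0) {
    lab$cx <- ((lab$cx * s - ctr) * f + ctr + tx) / s
    lab$cy <- ((lab$cy * s - ctr) * f + ctr + ty) / s
    lab$w <- lab$w * f; lab$h <- lab$h * f
    lab <- .clip_labels(lab, s)
  }
  list(image = out, labels = lab)
}
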