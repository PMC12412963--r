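# Shared fixtures: tiny inputs, independent per-layer parameter/FLOPs
# oracles, and a brute-force box-geometry toolkit. The oracles here are
# deliberately written from first principles (textbook conv arithmetic),
# not by calling the package's own counters.

rand_input <- function(h, w, c = 3L, n = 1L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(h * w * c * n), c(h, w, c, n))
}

# conv parameter count: i*(k*k)*o (+o bias) plus 2o batch-norm affine terms
conv_pars <- function(ci, co, k, bias = FALSE)
  k * k * ci * co + if (bias) co else 2 * co

# Independent per-layer summation oracles for every block kind, written
# straight from the block definitions (entry/branch/exit unit lists).
oracle_block_params <- function(kind, cin, cout, n = 1L) {
  h <- cout / 2
  switch(kind,
    CBS  = conv_pars(cin, cout, 3),
    MPC  = conv_pars(cin, cout, 1) + conv_pars(cout, cout / 2, 3) +
           conv_pars(cin, cout / 2, 1),
    C4   = {
      c <- cin
      conv_pars(c, c, 1) + 2 * conv_pars(c / 2, c, 3) + conv_pars(2 * c, c, 1)
    },
    C2fR = conv_pars(cin, cout, 1) + n * oracle_block_params("C4", h, h) +
           conv_pars((n + 2) * h, cout, 1),
    C2f  = conv_pars(cin, cout, 1) + n * 2 * conv_pars(h, h, 3) +
           conv_pars((n + 2) * h, cout, 1),
    C3   = 2 * conv_pars(cin, h, 1) + n * (conv_pars(h, h, 1) + conv_pars(h, h, 3)) +
           conv_pars(2 * h, cout, 1),
    SPPR = conv_pars(cin, cin, 1) + conv_pars(2 * cin, cout, 1),
    SPPF = conv_pars(cin, cin / 2, 1) + conv_pars(2 * cin, cout, 1))
}

# brute-force IoU between two center-format boxes
bf_iou <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ax2 <- a[1] + a[3] / 2
  ay1 <- a[2] - a[4] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; bx2 <- b[1] + b[3] / 2
  by1 <- b[2] - b[4] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# brute-force greedy class-aware NMS, O(n^2), independent of the package
bf_nms <- function(det, thr) {
  ord <- order(-det$score, -(det$w * det$h), seq_len(nrow(det)))
  d <- det[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j]) next
      if (d$class[j] == d$class[i] &&
          bf_iou(unlist(d[i, c("cx", "cy", "w", "h")]),
                 unlist(d[j, c("cx", "cy", "w", "h")])) > thr)
        keep[j] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

# brute-force anchor assignment: enumerate every (target, anchor, cell)
# triple and apply the ratio + neighbour rule directly
bf_assign <- function(labels, anchors, grid_shapes, img_size, thr = 4) {
  lapply(seq_along(anchors), function(s) {
    gs <- grid_shapes[[s]]
    anc <- anchors[[s]] / (img_size / gs[1])
    rows <- list()
    for (t in seq_len(nrow(labels))) {
      gx <- labels$cx[t] * gs[2]; gy <- labels$cy[t] * gs[1]
      tw <- labels$w[t] * gs[2]; th <- labels$h[t] * gs[1]
      gi0 <- floor(gx); gj0 <- floor(gy)
      cells <- list(c(gi0, gj0))
      fx <- gx - gi0; fy <- gy - gj0
      if (fx < 0.5 && gi0 > 0) cells <- c(cells, list(c(gi0 - 1, gj0)))
      if (fx >= 0.5 && gi0 < gs[2] - 1) cells <- c(cells, list(c(gi0 + 1, gj0)))
      if (fy < 0.5 && gj0 > 0) cells <- c(cells, list(c(gi0, gj0 - 1)))
      if (fy >= 0.5 && gj0 < gs[1] - 1) cells <- c(cells, list(c(gi0, gj0 + 1)))
      for (a in seq_len(nrow(anc))) {
        rw <- tw / anc[a, 1]; rh <- th / anc[a, 2]
        if (max(rw, 1 / rw) >= thr || max(rh, 1 / rh) >= thr) next
        for (cl in cells)
          rows[[length(rows) + 1L]] <- data.frame(
            image = labels$image[t], anchor = a, gi = cl[1], gj = cl[2],
            class = labels$class[t])
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(image = integer(), anchor = integer(), gi = numeric(),
                    gj = numeric(), class = integer())
  })
}

# canonical sort for assignment comparison
sort_assign <- function(a)
  a[order(a$image, a$anchor, a$gi, a$gj, a$class), , drop = FALSE]
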