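# ---------------------------------------------------------------------------
# Anchor estimation: IoU-distance k-means over training-set box sizes, with
# fallback to the stock anchor table when it does not improve the fit.
# ---------------------------------------------------------------------------

# co-centered IoU between box sizes (n x 2) and anchor sizes (k x 2)
.wh_iou <- function(wh, anc) {
  iw <- outer(wh[, 1], anc[, 1], pmin)
  ih <- outer(wh[, 2], anc[, 2], pmin)
  inter <- iw * ih
  inter / (outer(wh[, 1] * wh[, 2], anc[, 1] * anc[, 2], "+") - inter)
}

# anchor fitness: mean best size-ratio quality over boxes (ratio rule)
.anchor_fitness <- function(wh, anc, thr = 4) {
  r1 <- outer(wh[, 1], anc[, 1], "/"); r2 <- outer(wh[, 2], anc[, 2], "/")
  x <- pmin(pmin(r1, 1 / r1), pmin(r2, 1 / r2))
  best <- apply(x, 1, max)
  mean(best * (best > 1 / thr))
}

#' Estimate anchors from a label set
#'
#' Runs k-means with a 1-IoU distance (boxes treated as co-centered) on the
#' training-set box dimensions. With `k = 9` the anchors are grouped into
#' three scales by area and compared against the stock anchor table: when
#' the estimated set does not improve the size-ratio fitness, the stock
#' table is returned (attribute `fallback = TRUE`).
#'
#' @param labels Data frame with normalized `w`, `h` columns.
#' @param k Number of anchors (9 for a 3-scale detector).
#' @param img_size Pixel scale of the returned anchors.
#' @param iters Lloyd iterations.
#' @return For `k = 9` an anchor list as [default_anchors()]; otherwise a
#'   `k x 2` matrix of (w, h) pixels sorted by area.
#' @export
autoanchor <- function(labels, k = 9L, img_size = 640L, iters = 30L) {
  wh <- cbind(labels$w, labels$h) * img_size
  if (nrow(wh) < k) stop("need at least ", k, " boxes, got ", nrow(wh))
  uni <- unique(wh)
  if (nrow(uni) < k) {
    cent <- uni[rep(seq_len(nrow(uni)), length.out = k), , drop = FALSE]
  } else {
    cent <- stats::kmeans(log(wh), centers = k, nstart = 5)$centers
    cent <- exp(cent)
    for (it in seq_len(iters)) {
      assign <- max.col(.wh_iou(wh, cent))
      for (j in seq_len(k)) {
        sel <- assign == j
        if (any(sel)) cent[j, ] <- colMeans(wh[sel, , drop = FALSE])
      }
    }
  }
  cent <- cent[order(cent[, 1] * cent[, 2]), , drop = FALSE]
  dimnames(cent) <- list(NULL, c("w", "h"))
  if (k != 9L) return(cent)
  est <- list(p3 = cent[1:3, ], p4 = cent[4:6, ], p5 = cent[7:9, ])
  def <- default_anchors()
  def_m <- do.call(rbind, def)
  if (.anchor_fitness(wh, cent) <= .anchor_fitness(wh, def_m) + 1e-4) {
    attr(def, "fallback") <- TRUE
    return(def)
  }
  attr(est, "fallback") <- FALSE
  est
}
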