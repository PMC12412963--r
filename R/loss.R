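# ---------------------------------------------------------------------------
# Composite detection loss: CIoU box regression, BCE objectness and
# classification, anchor-based target assignment (ratio rule + neighbour
# cells). All arithmetic goes through the autodiff primitives, so the same
# code computes values on plain vectors and gradients on taped nodes.
# ---------------------------------------------------------------------------

.EPS <- 1e-7

# CIoU loss on center-format boxes given as parallel vectors (numeric or ag).
.ciou_xywh <- function(px, py, pw, ph, gx, gy, gw, gh) {
  pl <- px - pw / 2; pr <- px + pw / 2; pt <- py - ph / 2; pb <- py + ph / 2
  gl <- gx - gw / 2; gr <- gx + gw / 2; gt <- gy - gh / 2; gb <- gy + gh / 2
  iw <- ag_pmax(ag_pmin(pr, gr) - ag_pmax(pl, gl), 0)
  ih <- ag_pmax(ag_pmin(pb, gb) - ag_pmax(pt, gt), 0)
  inter <- iw * ih
  union <- pw * ph + gw * gh - inter + .EPS
  iou <- inter / union
  cw <- ag_pmax(pr, gr) - ag_pmin(pl, gl)          # enclosing box
  chh <- ag_pmax(pb, gb) - ag_pmin(pt, gt)
  c2 <- cw * cw + chh * chh + .EPS
  rho2 <- (gx - px) * (gx - px) + (gy - py) * (gy - py)
  v <- (4 / pi^2) * (atan(gw / (gh + .EPS)) - atan(pw / (ph + .EPS)))^2
  # alpha is treated as a constant (no gradient), as in the reference
  iou_v <- if (is_ag(iou)) iou$v else iou
  v_v <- if (is_ag(v)) v$v else v
  alpha <- v_v / (1 - iou_v + v_v + .EPS)
  list(iou = iou, loss = 1 - iou + rho2 / c2 + v * alpha)
}

#' Complete-IoU loss between two boxes
#'
#' `1 - IoU + rho^2/c^2 + alpha*v`: the overlap term is complemented by a
#' normalized center-distance penalty (squared center distance over squared
#' enclosing-box diagonal) and an aspect-ratio penalty
#' `v = (4/pi^2)(atan(wg/hg) - atan(w/h))^2` weighted by
#' `alpha = v/((1-IoU)+v)`. Zero iff the boxes coincide; always at least
#' `1 - IoU`.
#'
#' @param pred,gt Boxes in center format: vectors `c(cx, cy, w, h)` or
#'   matrices with those four columns (any consistent units; rows pair up).
#' @return Numeric loss, one value per box pair.
#' @examples
#' ciou_loss(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 0
#' @export
ciou_loss <- function(pred, gt) {
  p <- if (is.matrix(pred)) pred else matrix(pred, ncol = 4, byrow = FALSE)
  g <- if (is.matrix(gt)) gt else matrix(gt, ncol = 4, byrow = FALSE)
  if (is.null(dim(pred))) p <- matrix(pred, ncol = 4)
  if (is.null(dim(gt))) g <- matrix(gt, ncol = 4)
  if (any(p[, 3:4] <= 0) || any(g[, 3:4] <= 0)) stop("box dimensions must be positive")
  .ciou_xywh(p[, 1], p[, 2], p[, 3], p[, 4], g[, 1], g[, 2], g[, 3], g[, 4])$loss
}

#' Binary cross-entropy on probabilities
#'
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))` with an epsilon guard on the
#' logs. Probabilities are expected post-sigmoid, in (0, 1).
#'
#' @param labels 0/1 vector.
#' @param probabilities Vector of the same length.
#' @export
bce_loss <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) stop("length mismatch")
  p <- pmin(pmax(probabilities, .EPS), 1 - .EPS)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Anchor-based target assignment
#'
#' Matches every ground-truth box to every anchor whose width and height
#' ratios to the box are within `[1/ratio_thr, ratio_thr]`, in the box's
#' grid cell plus its two nearest neighbour cells (offset 0.5).
#'
#' @param labels Data frame with columns `image` (1-based index within the
#'   batch), `class` (0-based), `cx`, `cy`, `w`, `h` (normalized).
#' @param anchors Anchor list as [default_anchors()], pixels at the network
#'   input size.
#' @param grid_shapes List of `c(H, W)` per scale (img_size / stride).
#' @param img_size Network input size in pixels.
#' @param ratio_thr Anchor/box ratio threshold (4 by default).
#' @return List per scale of data frames with columns `image`, `anchor`
#'   (1..3), `gi`, `gj` (0-based cell), `tx`, `ty`, `tw`, `th` (grid units),
#'   `class`, `aw`, `ah` (matched anchor, grid units).
#' @export
assign_targets <- function(labels, anchors, grid_shapes, img_size,
                           ratio_thr = 4) {
  lapply(seq_along(anchors), function(s) {
    gs <- grid_shapes[[s]]
    stride <- img_size / gs[1]
    anc <- anchors[[s]] / stride              # grid units
    out <- list()
    if (nrow(labels) > 0) {
      for (a in seq_len(nrow(anc))) {
        tw <- labels$w * gs[2]; th <- labels$h * gs[1]
        rw <- tw / anc[a, 1]; rh <- th / anc[a, 2]
        keep <- pmax(rw, 1 / rw) < ratio_thr & pmax(rh, 1 / rh) < ratio_thr
        if (!any(keep)) next
        lb <- labels[keep, , drop = FALSE]
        gx <- lb$cx * gs[2]; gy <- lb$cy * gs[1]
        gi0 <- floor(gx); gj0 <- floor(gy)
        offs <- list(c(0, 0))
        fx <- gx - gi0; fy <- gy - gj0
        cand <- data.frame(img = lb$image, cls = lb$class, gx = gx, gy = gy,
                           tw = tw[keep], th = th[keep])
        rows <- list(cbind(cand, gi = gi0, gj = gj0))
        left <- fx < 0.5 & gi0 > 0;     rows <- c(rows, list(cbind(cand, gi = gi0 - 1, gj = gj0)[left, ]))
        up <- fy < 0.5 & gj0 > 0;       rows <- c(rows, list(cbind(cand, gi = gi0, gj = gj0 - 1)[up, ]))
        right <- fx >= 0.5 & gi0 < gs[2] - 1
        rows <- c(rows, list(cbind(cand, gi = gi0 + 1, gj = gj0)[right, ]))
        down <- fy >= 0.5 & gj0 < gs[1] - 1
        rows <- c(rows, list(cbind(cand, gi = gi0, gj = gj0 + 1)[down, ]))
        m <- do.call(rbind, rows)
        rownames(m) <- NULL
        if (nrow(m) > 0)
          out[[length(out) + 1L]] <- data.frame(
            image = m$img, anchor = a, gi = m$gi, gj = m$gj,
            tx = m$gx, ty = m$gy, tw = m$tw, th = m$th, class = m$cls,
            aw = anc[a, 1], ah = anc[a, 2])
      }
    }
    if (length(out) == 0)
      data.frame(image = integer(), anchor = integer(), gi = numeric(),
                 gj = numeric(), tx = numeric(), ty = numeric(), tw = numeric(),
                 th = numeric(), class = integer(), aw = numeric(), ah = numeric())
    else do.call(rbind, out)
  })
}

# flat (column-major) indices into an (H,W,C,N) array
.flat_idx <- function(d, h, w, c, n) 1 + h + d[1] * (w + d[2] * (c + d[3] * (n - 1)))

#' Composite detection loss
#'
#' Box loss is the mean CIoU loss over assigned anchor/target pairs (boxes
#' decoded with the grid transforms `xy = 2*sigmoid - 0.5 + cell`,
#' `wh = (2*sigmoid)^2 * anchor`); classification is BCE over assigned class
#' one-hots; objectness is BCE over every cell with the (detached) CIoU of
#' assigned pairs as positive target, balanced per scale.
#'
#' @param preds List of three raw per-scale head outputs (arrays or taped
#'   nodes), channels anchor-major `(x, y, w, h, obj, classes...)`.
#' @param labels Label data frame (see [assign_targets()]).
#' @param config The model's [yolocf_config()].
#' @param weights Loss weights `box`, `obj`, `cls` and per-scale objectness
#'   balance.
#' @return A `ycf_loss` list: `box`, `obj`, `cls` (values), `total`
#'   (ag node when training), assignment count `n_assigned`.
#' @export
detection_loss <- function(preds, labels, config,
                           weights = list(box = 0.05, obj = 1.0, cls = 0.5,
                                          balance = c(4.0, 1.0, 0.4))) {
  nc <- config$num_classes
  na_ <- 5L + nc
  dims <- lapply(preds, function(p) if (is_ag(p)) dim(p$v) else dim(p))
  grid_shapes <- lapply(dims, function(d) d[1:2])
  asg <- assign_targets(labels, config$anchors, grid_shapes, config$img_size)
  lbox <- 0; lcls <- 0; lobj <- 0; n_asg <- 0L
  for (s in 1:3) {
    p <- preds[[s]]; d <- dims[[s]]
    a <- asg[[s]]
    obj_t <- array(0, c(d[1], d[2], 3L, d[4]))
    if (nrow(a) > 0) {
      n_asg <- n_asg + nrow(a)
      ch0 <- (a$anchor - 1L) * na_
      ix <- function(cc) .flat_idx(d, a$gj, a$gi, ch0 + cc, a$image)
      tx_ <- ag_sigmoid(ag_gather(p, ix(0L))) * 2 - 0.5
      ty_ <- ag_sigmoid(ag_gather(p, ix(1L))) * 2 - 0.5
      tw_ <- ag_sigmoid(ag_gather(p, ix(2L))) * 2
      th_ <- ag_sigmoid(ag_gather(p, ix(3L))) * 2
      pw <- tw_ * tw_ * a$aw; ph <- th_ * th_ * a$ah
      px <- tx_ + a$gi; py <- ty_ + a$gj
      ci <- .ciou_xywh(px, py, pw, ph, a$tx, a$ty, a$tw, a$th)
      lbox <- lbox + ag_mean(ci$loss)
      iou_d <- if (is_ag(ci$iou)) ci$iou$v else ci$iou
      # positive objectness target = clamped detached CIoU-free IoU
      tgt <- pmax(iou_d, 0)
      oidx <- .flat_idx(c(d[1], d[2], 3L, d[4]), a$gj, a$gi, a$anchor - 1L, a$image)
      # later assignments of the same cell overwrite earlier ones
      obj_t[oidx] <- tgt
      if (nc > 1L) {
        cls_idx <- unlist(lapply(0:(nc - 1L), function(k) ix(5L + k)))
        one_hot <- as.numeric(rep(0:(nc - 1L), each = nrow(a)) == rep(a$class, nc))
        lcls <- lcls + ag_mean(bce_with_logits(ag_gather(p, cls_idx), one_hot))
      }
    }
    obj_ch <- as.vector(vapply(1:3, function(ai)
      .flat_idx(d, rep(0:(d[1] - 1L), times = d[2]),
                rep(0:(d[2] - 1L), each = d[1]),
                (ai - 1L) * na_ + 4L, 1L), numeric(d[1] * d[2])))
    if (d[4] > 1L)
      obj_ch <- as.vector(vapply(1:d[4], function(n)
        obj_ch + (n - 1L) * prod(d[1:3]), numeric(length(obj_ch))))
    lobj <- lobj + weights$balance[s] *
      ag_mean(bce_with_logits(ag_gather(p, obj_ch), as.vector(obj_t)))
  }
  if (is.numeric(lbox) && n_asg == 0L) lbox <- 0
  total <- weights$box * lbox + weights$obj * lobj +
    if (n_asg > 0L) weights$cls * lcls else 0
  structure(list(
    box = if (is_ag(lbox)) lbox$v else lbox,
    obj = if (is_ag(lobj)) lobj$v else lobj,
    cls = if (is_ag(lcls)) lcls$v else lcls,
    total = total, n_assigned = n_asg), class = "ycf_loss")
}

#' @export
print.ycf_loss <- function(x, ...) {
  tv <- if (is_ag(x$total)) x$total$v else x$total
  cat(sprintf("detection loss: total %.4f (box %.4f | obj %.4f | cls %.4f; %d assigned)\n",
              tv, x$box, x$obj, x$cls, x$n_assigned))
  invisible(x)
}
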