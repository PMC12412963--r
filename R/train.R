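# ---------------------------------------------------------------------------
# Training: SGD with momentum and weight decay, linear warmup + cosine
# schedule, mosaic/affine/HSV augmentation, per-epoch validation losses and
# detection metrics. Fully seeded.
# ---------------------------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults follow the usual anchor-based detector recipe: SGD momentum
#' 0.937, initial lr 0.01 cosine-annealed to `lr0*lrf`, 3 warmup epochs,
#' hue/saturation/value jitter 0.015/0.7/0.4, translate 0.1, scale 0.5,
#' mosaic probability 1.0.
#'
#' @param epochs,batch Training length and batch size.
#' @param img_size Square training resolution (divisible by 32).
#' @param lr0,lrf,momentum,weight_decay Optimizer settings.
#' @param warmup_epochs Linear warmup span.
#' @param hsv_h,hsv_s,hsv_v,translate,scale,mosaic Augmentation magnitudes.
#' @param seed RNG seed governing everything (shuffling, augmentation,
#'   weight init).
#' @param autoanchor Re-estimate anchors from the training labels before
#'   training (adaptive-anchor input stage); falls back to the stock table
#'   when the estimate does not improve the fit.
#' @param target_map Optional early stop: end training once validation
#'   mAP@0.5 reaches this value.
#' @export
yolocf_hyp <- function(epochs = 200L, batch = 16L, img_size = 640L,
                       lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                       weight_decay = 5e-4, warmup_epochs = 3,
                       hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                       translate = 0.1, scale = 0.5, mosaic = 1.0,
                       seed = 0L, autoanchor = FALSE, target_map = NULL) {
  stopifnot(img_size %% 32L == 0L, mosaic >= 0, mosaic <= 1)
  as.list(environment())
}

# deep copy of the current weights (list of plain lists)
.snapshot <- function(model)
  lapply(model$params, function(p)
    mget(intersect(c("w", "b", "gamma", "beta", "rmean", "rvar"), names(p)), envir = p))
.restore <- function(model, snap) {
  for (i in seq_along(model$params))
    for (f in names(snap[[i]])) model$params[[i]][[f]] <- snap[[i]][[f]]
  invisible(model)
}

# one SGD step over the parameter environments touched by the tape
.sgd_step <- function(ctx, lr, momentum, weight_decay) {
  for (p in ctx$params) {
    nd <- p$.nodes
    for (f in names(nd)) {
      g <- nd[[f]]$g
      if (is.null(g)) next
      if (f == "w") g <- g + weight_decay * p$w
      buf <- paste0(".v_", f)
      v <- if (is.null(p[[buf]])) g else momentum * p[[buf]] + g
      p[[buf]] <- v
      p[[f]] <- p[[f]] - lr * v
    }
  }
}

#' Train a YOLOcF detector
#'
#' Runs seeded SGD training on a dataset in YOLO layout and returns a
#' fit object carrying the trained model, the per-epoch log (validation
#' box/objectness/classification losses, precision, recall, mAP@0.5) and
#' the best-mAP weights.
#'
#' @param model A [yolocf()] model (its `img_size` should equal
#'   `hyp$img_size`).
#' @param dataset Path to a dataset YAML ([write_dataset()]) or a list with
#'   `train` and `val` elements, each `list(images=, labels=)` where images
#'   may be file paths or arrays.
#' @param hyp Hyperparameters from [yolocf_hyp()].
#' @param verbose Print one line per epoch.
#' @return An object of class `yolocf_fit`.
#' @export
yolocf_train <- function(model, dataset, hyp = yolocf_hyp(), verbose = TRUE) {
  set.seed(hyp$seed)
  reinit_weights(model, hyp$seed)
  if (is.character(dataset)) {
    tr <- load_dataset(dataset, "train"); va <- load_dataset(dataset, "val")
  } else { tr <- dataset$train; va <- dataset$val }
  if (length(tr$images) == 0) stop("empty training set")
  nclab <- max(unlist(lapply(c(tr$labels, va$labels), function(l) l$class)), -1L) + 1L
  if (nclab > model$config$num_classes)
    stop("dataset has more classes than the model (", nclab, " > ",
         model$config$num_classes, ")")
  s <- hyp$img_size
  get_img <- function(x) {
    img <- if (is.character(x)) read_image(x) else x
    if (dim(img)[1] != s) img <- .resize_nn(img, s, s)
    img
  }
  cat_v <- function(...) if (verbose) cat(sprintf(...))
  train_imgs <- lapply(tr$images, get_img)      # cache in memory
  val_imgs <- lapply(va$images, get_img)
  if (isTRUE(hyp$autoanchor)) {
    all_lab <- do.call(rbind, tr$labels)
    if (nrow(all_lab) >= 9) {
      a <- autoanchor(all_lab, k = 9L, img_size = s)
      model$config$anchors <- a[c("p3", "p4", "p5")]
      cat_v("autoanchor: %s\n",
            if (isTRUE(attr(a, "fallback"))) "kept stock anchors"
            else "re-estimated anchors from training boxes")
    }
  }
  n_tr <- length(train_imgs)
  steps_per_epoch <- max(1L, ceiling(n_tr / hyp$batch))
  warmup_steps <- hyp$warmup_epochs * steps_per_epoch
  log <- NULL; best <- list(map = -Inf, snap = NULL, epoch = 0L)
  step <- 0L
  for (epoch in seq_len(hyp$epochs)) {
    cos_lr <- hyp$lr0 * ((1 - hyp$lrf) *
      (1 + cos(pi * (epoch - 1) / hyp$epochs)) / 2 + hyp$lrf)
    ord <- sample.int(n_tr)
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * hyp$batch + 1L):min(b * hyp$batch, n_tr)]
      batch_imgs <- vector("list", length(idx)); batch_lab <- list()
      for (j in seq_along(idx)) {
        if (stats::runif(1) < hyp$mosaic) {
          pick <- c(idx[j], sample.int(n_tr, 3L, replace = TRUE))
          sm <- mosaic_augment(lapply(pick, function(i)
            list(image = train_imgs[[i]], labels = tr$labels[[i]])))
        } else {
          sm <- affine_augment(list(image = train_imgs[[idx[j]]],
                                    labels = tr$labels[[idx[j]]]),
                               hyp$scale, hyp$translate)
        }
        sm$image <- hsv_augment(sm$image, c(hyp$hsv_h, hyp$hsv_s, hyp$hsv_v))
        batch_imgs[[j]] <- sm$image
        if (nrow(sm$labels) > 0)
          batch_lab[[length(batch_lab) + 1L]] <- cbind(image = j, sm$labels)
      }
      x <- array(unlist(batch_imgs), c(s, s, 3L, length(idx)))
      labels <- if (length(batch_lab)) do.call(rbind, batch_lab)
                else data.frame(image = integer(), class = integer(),
                                cx = numeric(), cy = numeric(),
                                w = numeric(), h = numeric())
      step <- step + 1L
      lr <- if (step <= warmup_steps) cos_lr * step / warmup_steps else cos_lr
      ctx <- ycf_ctx(training = TRUE)
      xin <- ag_leaf(x, ctx$tape)
      preds <- yolocf_forward(model, xin, ctx)
      ls <- detection_loss(preds, labels, model$config)
      if (!is.finite(if (is_ag(ls$total)) ls$total$v else ls$total))
        stop("non-finite loss at epoch ", epoch, " step ", b)
      if (is_ag(ls$total)) {
        ag_backward(ls$total)
        .sgd_step(ctx, lr, hyp$momentum, hyp$weight_decay)
      }
    }
    ev <- yolocf_validate(model, val_imgs, va$labels)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 val_box = ev$loss$box, val_obj = ev$loss$obj,
                                 val_cls = ev$loss$cls, precision = ev$metrics$precision,
                                 recall = ev$metrics$recall, map50 = ev$metrics$mAP))
    cat_v("epoch %3d | lr %.4f | val box %.4f obj %.4f cls %.4f | P %.3f R %.3f mAP50 %.3f\n",
          epoch, lr, ev$loss$box, ev$loss$obj, ev$loss$cls,
          ev$metrics$precision, ev$metrics$recall, ev$metrics$mAP)
    if (!is.na(ev$metrics$mAP) && ev$metrics$mAP > best$map)
      best <- list(map = ev$metrics$mAP, snap = .snapshot(model), epoch = epoch)
    if (!is.null(hyp$target_map) && !is.na(ev$metrics$mAP) &&
        ev$metrics$mAP >= hyp$target_map) break
  }
  if (!is.null(best$snap)) .restore(model, best$snap)
  structure(list(model = model, log = log, hyp = hyp,
                 best_epoch = best$epoch, best_map = best$map),
            class = "yolocf_fit")
}

#' Validate a model on a set of images
#'
#' Computes evaluation-mode detection losses and mAP@0.5 (decode at
#' confidence 0.001, NMS 0.45).
#'
#' @param model A [yolocf()] model.
#' @param images List of `(H,W,3)` arrays at the model's input size.
#' @param labels List of normalized label data frames.
#' @return List `loss` (box/obj/cls) and `metrics` ([evaluate_detections()]).
#' @export
yolocf_validate <- function(model, images, labels, batch = 8L) {
  s <- model$config$img_size
  n_img <- length(images)
  det_list <- vector("list", n_img)
  truth_list <- vector("list", n_img)
  lb <- lo <- lc <- 0; nb <- 0L
  for (b0 in seq(1L, n_img, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n_img)
    x <- array(unlist(images[idx]), c(s, s, 3L, length(idx)))
    preds <- yolocf_forward(model, x)
    lab <- do.call(rbind, lapply(seq_along(idx), function(j)
      cbind(image = j, labels[[idx[j]]])))
    ls <- detection_loss(preds, lab, model$config)
    lb <- lb + ls$box; lo <- lo + ls$obj; lc <- lc + ls$cls; nb <- nb + 1L
    for (j in seq_along(idx)) {
      pj <- lapply(preds, function(p) p[, , , j, drop = FALSE])
      det <- decode_predictions(pj, model$config, 0.001)
      if (nrow(det) > 1000) det <- det[order(-det$score)[1:1000], ]  # pre-NMS cap
      det <- nms(det, 0.45)
      if (nrow(det) > 300) det <- det[1:300, ]                       # post-NMS cap
      det_list[[idx[j]]] <- det
    }
  }
  for (i in seq_len(n_img)) {
    lab <- labels[[i]]
    truth_list[[i]] <- data.frame(cx = lab$cx * s, cy = lab$cy * s,
                                  w = lab$w * s, h = lab$h * s, class = lab$class)
  }
  nb <- max(nb, 1L)
  list(loss = list(box = lb / nb, obj = lo / nb, cls = lc / nb),
       metrics = evaluate_detections(det_list, truth_list,
                                     model$config$num_classes))
}

#' @export
print.yolocf_fit <- function(x, ...) {
  cat(sprintf("yolocf fit: %d epochs | best mAP@0.5 %.3f (epoch %d)\n",
              nrow(x$log), x$best_map, x$best_epoch))
  invisible(x)
}

#' @export
summary.yolocf_fit <- function(object, ...) {
  cat("Training log:\n")
  print(object$log, row.names = FALSE)
  print(object)
  invisible(object$log)
}

#' Loss and mAP curves of a fit
#' @param x A `yolocf_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.yolocf_fit <- function(x, ...) {
  lg <- x$log
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(lg$epoch, cbind(lg$val_box, lg$val_cls), type = "l",
                    lty = 1, xlab = "epoch", ylab = "validation loss", ...)
  graphics::legend("topright", c("box", "cls"), lty = 1, col = 1:2)
  graphics::plot(lg$epoch, lg$map50, type = "l", xlab = "epoch",
                 ylab = "mAP@0.5")
  invisible(x)
}

#' @export
predict.yolocf_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)
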