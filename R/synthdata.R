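# ---------------------------------------------------------------------------
# Procedural generator of annotated fruit scenes. Scenes emulate orchard
# imaging conditions: seven visually distinct fruit classes, clusters and
# overlap, leaf/branch occluders drawn over the fruit, illumination
# variants, and earth / fruit-similar / sky backgrounds. Boxes annotate the
# full (amodal) fruit extent; a visible-area floor keeps targets learnable.
# ---------------------------------------------------------------------------

.fruit_classes <- c("bitter-melon", "cucumber", "cherry", "jujube",
                    "melon-boyang", "muskmelon", "strawberry")

# class proportions of the reference fruit collection (training-set shares)
.class_props <- c(532, 532, 374, 821, 588, 324, 785) / 3956

# per-class rendering style: base RGB color, aspect (h/w), relative size,
# surface texture amplitude
.class_styles <- list(
  list(col = c(0.55, 0.75, 0.35), aspect = 2.6, size = 0.16, tex = 0.10), # bitter-melon
  list(col = c(0.20, 0.45, 0.15), aspect = 3.2, size = 0.16, tex = 0.05), # cucumber
  list(col = c(0.75, 0.10, 0.12), aspect = 1.0, size = 0.07, tex = 0.03), # cherry
  list(col = c(0.60, 0.25, 0.15), aspect = 1.3, size = 0.08, tex = 0.03), # jujube
  list(col = c(0.80, 0.85, 0.55), aspect = 1.2, size = 0.18, tex = 0.04), # melon-boyang
  list(col = c(0.72, 0.60, 0.40), aspect = 1.1, size = 0.22, tex = 0.12), # muskmelon
  list(col = c(0.85, 0.15, 0.20), aspect = 1.4, size = 0.07, tex = 0.08)) # strawberry

#' Scene specification
#'
#' Parameters of the procedural scene generator. The defaults reproduce the
#' mixed "cfruit_like" conditions; see [difficulty_presets()].
#'
#' @param n_classes Number of fruit classes (at most 7).
#' @param image_size Square canvas side in pixels.
#' @param objects_range Inclusive range of objects per scene.
#' @param occluder_density Expected occluders per object (leaves/branches).
#' @param cluster_prob Probability that a scene groups its fruit in clusters.
#' @param illuminations Conditions sampled per scene.
#' @param backgrounds Backgrounds sampled per scene.
#' @param size_jitter Multiplicative size spread (log-uniform half-range).
#' @param visible_floor Minimum visible-area fraction of every fruit.
#' @param class_probs Sampling weights of the classes (`NULL` = uniform).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_classes = 7L, image_size = 320L,
                       objects_range = c(2L, 12L), occluder_density = 0.5,
                       cluster_prob = 0.4,
                       illuminations = c("high_light", "low_light",
                                         "backlight", "side_light"),
                       backgrounds = c("earth", "foliage_similar", "sky"),
                       size_jitter = 0.45, visible_floor = 0.25,
                       class_probs = .class_props[seq_len(n_classes)]) {
  stopifnot(n_classes >= 1L, n_classes <= 7L, image_size >= 64L,
            objects_range[1] >= 0L, objects_range[2] >= objects_range[1])
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 objects_range = as.integer(objects_range),
                 occluder_density = occluder_density,
                 cluster_prob = cluster_prob, illuminations = illuminations,
                 backgrounds = backgrounds, size_jitter = size_jitter,
                 visible_floor = visible_floor,
                 class_probs = class_probs / sum(class_probs)),
            class = "scene_spec")
}

#' Difficulty presets
#'
#' `easy`: few large fruit, no occluders, uniform high light, earth
#' background — for training smoke tests. `cfruit_like`: the mixed orchard
#' conditions. `hard`: dense clusters under heavy occlusion.
#'
#' @param image_size Canvas side passed through to [scene_spec()].
#' @return Named list of three `scene_spec`s.
#' @export
difficulty_presets <- function(image_size = 320L) {
  list(
    easy = scene_spec(image_size = image_size, objects_range = c(1L, 3L),
                      occluder_density = 0, cluster_prob = 0,
                      illuminations = "high_light", backgrounds = "earth",
                      size_jitter = 0.2, class_probs = rep(1, 7)),
    cfruit_like = scene_spec(image_size = image_size),
    hard = scene_spec(image_size = image_size, objects_range = c(8L, 20L),
                      occluder_density = 1.2, cluster_prob = 0.7,
                      size_jitter = 0.6))
}

# rotated-ellipse mask on the pixel grid; returns logical matrix
.ellipse_mask <- function(n, cx, cy, rx, ry, theta) {
  xs <- matrix(rep(seq_len(n), each = n), n) - cx   # columns = x
  ys <- matrix(rep(seq_len(n), times = n), n) - cy  # rows = y
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  (xr / rx)^2 + (yr / ry)^2 <= 1
}

.draw_background <- function(n, kind) {
  img <- array(0, c(n, n, 3))
  noise <- matrix(stats::runif(n * n, -0.05, 0.05), n)
  base <- switch(kind,
    earth = c(0.45, 0.33, 0.22),
    foliage_similar = c(0.30, 0.50, 0.20),
    sky = c(0.65, 0.78, 0.92))
  for (c in 1:3) img[, , c] <- base[c] + noise
  if (kind == "foliage_similar") {
    for (i in seq_len(18)) {   # leafy blobs close to fruit hues
      m <- .ellipse_mask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                         stats::runif(1, n / 16, n / 6), stats::runif(1, n / 20, n / 8),
                         stats::runif(1, 0, pi))
      tint <- c(stats::runif(1, 0.25, 0.6), stats::runif(1, 0.45, 0.8),
                stats::runif(1, 0.1, 0.35))
      for (c in 1:3) { ch <- img[, , c]; ch[m] <- tint[c]; img[, , c] <- ch }
    }
  }
  if (kind == "sky") {
    grad <- matrix(rep(seq(0.12, -0.04, length.out = n), times = n), n)
    for (c in 1:3) img[, , c] <- img[, , c] + grad
  }
  img
}

.apply_illumination <- function(img, kind) {
  n <- dim(img)[1]
  switch(kind,
    high_light = pmin(img * 1.15 + 0.05, 1),
    low_light = img * 0.55,
    backlight = {
      grad <- matrix(rep(seq(1.35, 0.45, length.out = n), times = n), n)
      for (c in 1:3) img[, , c] <- img[, , c] * grad
      pmin(img, 1)
    },
    side_light = {
      grad <- matrix(rep(seq(1.25, 0.55, length.out = n), each = n), n)
      for (c in 1:3) img[, , c] <- img[, , c] * grad
      pmin(img, 1)
    })
}

#' Generate one annotated scene
#'
#' Renders fruit as textured rotated ellipses (elongated classes become
#' capsule-like), optionally grouped into clusters, draws leaf and branch
#' occluders over them, applies a global illumination transform, and returns
#' the exact amodal bounding boxes of the fruit.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer; the same `(spec, seed)` pair reproduces the scene
#'   bitwise.
#' @param n_objects Override the sampled object count.
#' @return List: `image` `(H,W,3)` in `[0,1]`; `labels` data frame
#'   `class, cx, cy, w, h` (normalized); `masks` list of logical instance
#'   masks (pre-occlusion); `meta` list of realized conditions.
#' @export
generate_scene <- function(spec, seed = 1L, n_objects = NULL) {
  set.seed(as.integer(seed %% 2147483647))
  n <- spec$image_size
  bg_kind <- sample(spec$backgrounds, 1L)
  illum <- sample(spec$illuminations, 1L)
  img <- .draw_background(n, bg_kind)
  cls <- sample.int(spec$n_classes, 1L, prob = spec$class_probs) # one class per scene
  sty <- .class_styles[[cls]]
  k <- if (is.null(n_objects))
    sample(spec$objects_range[1]:spec$objects_range[2], 1L) else as.integer(n_objects)
  clustered <- stats::runif(1) < spec$cluster_prob && k >= 3L
  centers <- matrix(numeric(0), ncol = 2)
  if (clustered) {
    n_cl <- max(1L, round(k / 4))
    ccent <- cbind(stats::runif(n_cl, 0.2 * n, 0.8 * n),
                   stats::runif(n_cl, 0.2 * n, 0.8 * n))
  }
  labels <- NULL; masks <- list(); boxes <- list(); dropped <- 0L
  own <- matrix(0L, n, n)      # instance ownership (occluders = -1)
  sizes <- numeric(0)
  for (i in seq_len(k)) {
    base_r <- sty$size * n / 2
    r <- base_r * exp(stats::runif(1, -spec$size_jitter, spec$size_jitter))
    rx <- r; ry <- r * sty$aspect
    theta <- stats::runif(1, -pi / 5, pi / 5)
    placed <- FALSE
    for (try in 1:20) {
      if (clustered) {
        ci <- sample.int(nrow(ccent), 1L)
        cx <- stats::rnorm(1, ccent[ci, 1], r * 1.6)
        cy <- stats::rnorm(1, ccent[ci, 2], r * 1.6)
      } else {
        cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
      }
      ex <- abs(rx * cos(theta)) + abs(ry * sin(theta))
      ey <- abs(rx * sin(theta)) + abs(ry * cos(theta))
      if (cx - ex < 1 || cx + ex > n || cy - ey < 1 || cy + ey > n) next
      m <- .ellipse_mask(n, cx, cy, rx, ry, theta)
      # keep every earlier fruit visible above the floor
      ok <- TRUE
      if (length(masks) > 0) {
        for (j in seq_along(masks)) {
          vis <- sum(own == j & !m) / sum(masks[[j]])
          if (vis < spec$visible_floor) { ok <- FALSE; break }
        }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) { dropped <- dropped + 1L; next }
    id <- length(masks) + 1L
    masks[[id]] <- m
    own[m] <- id
    sizes <- c(sizes, r)
    # render: base color + radial shading + texture
    ij <- which(m, arr.ind = TRUE)
    dx <- (ij[, 2] - cx) / max(rx, ry); dy <- (ij[, 1] - cy) / max(rx, ry)
    shade <- 1 - 0.35 * (dx^2 + dy^2) + 0.15 * (-dx - dy)
    texn <- sty$tex * sin(ij[, 1] / 2.1) * cos(ij[, 2] / 2.7) +
      stats::rnorm(nrow(ij), 0, sty$tex / 3)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[ij] <- pmin(pmax(sty$col[c] * shade + texn, 0), 1)
      img[, , c] <- ch
    }
    xs <- range(ij[, 2]); ys <- range(ij[, 1])
    boxes[[id]] <- c(cls - 1L, mean(xs) / n, mean(ys) / n,
                     (diff(xs) + 1) / n, (diff(ys) + 1) / n)
  }
  # occluders: leaves (green ellipses) and branches (thin brown ellipses)
  n_occ <- stats::rpois(1, spec$occluder_density * max(length(masks), 1L))
  occ_kinds <- character(0)
  for (o in seq_len(n_occ)) {
    kind <- sample(c("leaf", "branch"), 1L, prob = c(0.7, 0.3))
    r1 <- stats::runif(1, n / 18, n / 7)
    m <- if (kind == "leaf")
      .ellipse_mask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                    r1, r1 * stats::runif(1, 0.35, 0.6), stats::runif(1, 0, pi))
    else
      .ellipse_mask(n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                    r1 * 2.5, r1 * 0.15, stats::runif(1, 0, pi))
    ok <- TRUE
    for (j in seq_along(masks)) {
      vis <- sum(own == j & !m) / sum(masks[[j]])
      if (vis < spec$visible_floor) { ok <- FALSE; break }
    }
    if (!ok) next
    col <- if (kind == "leaf")
      c(stats::runif(1, 0.15, 0.35), stats::runif(1, 0.4, 0.65), stats::runif(1, 0.1, 0.25))
    else c(0.35, 0.25, 0.15)
    ij <- which(m, arr.ind = TRUE)
    for (c in 1:3) { ch <- img[, , c]; ch[ij] <- col[c]; img[, , c] <- ch }
    own[m] <- -1L
    occ_kinds <- c(occ_kinds, kind)
  }
  img <- .apply_illumination(img, illum)
  labels <- if (length(boxes))
    stats::setNames(as.data.frame(do.call(rbind, boxes)),
                    c("class", "cx", "cy", "w", "h"))
  else data.frame(class = integer(), cx = numeric(), cy = numeric(),
                  w = numeric(), h = numeric())
  conds <- c(
    if (clustered) "cluster",
    if ("leaf" %in% occ_kinds) "leaf_occlusion",
    if ("branch" %in% occ_kinds) "branch_occlusion",
    if (length(masks) >= 2 && any(box_overlaps(labels) > 0.05)) "overlap",
    if (length(masks) >= 8) "dense_targets",
    if (length(sizes) >= 2 && max(sizes) / min(sizes) > 1.5) "size_variation",
    if (illum == "backlight") "backlight",
    if (illum == "side_light") "side_light",
    if (illum == "low_light") "low_light",
    if (illum == "high_light") "high_light",
    paste0(bg_kind, "_background"))
  list(image = img, labels = labels, masks = masks,
       meta = list(class = cls - 1L, illumination = illum, background = bg_kind,
                   conditions = conds, n_requested = k, n_dropped = dropped))
}

# max pairwise IoU among normalized label boxes
box_overlaps <- function(labels) {
  if (nrow(labels) < 2) return(0)
  b <- as.matrix(labels[, c("cx", "cy", "w", "h")])
  iou <- box_iou_xywh(b, b)
  diag(iou) <- 0
  max(iou)
}

#' Write a dataset in YOLO layout
#'
#' Generates scenes, writes `images/{train,val}/*.png` and
#' `labels/{train,val}/*.txt` (one `class cx cy w h` line per object,
#' normalized, no header), and a dataset config YAML with `path`, `train`,
#' `val` and the class `names`.
#'
#' @param root Output directory.
#' @param spec A [scene_spec()].
#' @param n_train,n_val Split sizes.
#' @param seed Base seed; scene `i` derives its own stream from it.
#' @param overwrite Allow writing into an existing non-empty `root`.
#' @return Path of the dataset YAML (invisibly a list with per-image counts
#'   as attribute `meta`).
#' @export
write_dataset <- function(root, spec, n_train, n_val, seed = 0L,
                          overwrite = FALSE) {
  if (dir.exists(root) && length(dir(root)) > 0 && !overwrite)
    stop("refusing to write into non-empty directory: ", root)
  for (d in c("images/train", "images/val", "labels/train", "labels/val"))
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (i in seq_len(n_train + n_val)) {
    split <- if (i <= n_train) "train" else "val"
    sc <- generate_scene(spec, seed = seed + i * 10007L)
    stem <- sprintf("scene_%05d", i)
    png::writePNG(sc$image, file.path(root, "images", split, paste0(stem, ".png")))
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", sc$labels$class, sc$labels$cx,
                       sc$labels$cy, sc$labels$w, sc$labels$h),
               file.path(root, "labels", split, paste0(stem, ".txt")))
    meta[[i]] <- sc$meta
  }
  cfg <- file.path(root, "dataset.yaml")
  yaml::write_yaml(list(path = normalizePath(root), train = "images/train",
                        val = "images/val",
                        names = .fruit_classes[seq_len(spec$n_classes)]), cfg)
  attr(cfg, "meta") <- meta
  invisible(cfg)
}

#' Read YOLO-format labels
#'
#' @param path Label `.txt` file (possibly empty).
#' @return Data frame `class, cx, cy, w, h`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  m <- as.matrix(utils::read.table(path))
  stats::setNames(data.frame(as.integer(m[, 1]), m[, 2], m[, 3], m[, 4], m[, 5]),
                  c("class", "cx", "cy", "w", "h"))
}

#' Load a dataset written by [write_dataset()]
#'
#' @param yaml_path The dataset config file.
#' @param split `"train"` or `"val"`.
#' @return List with `images` (file paths), `labels` (list of data frames)
#'   and `names`.
#' @export
load_dataset <- function(yaml_path, split = "train") {
  cfg <- yaml::read_yaml(yaml_path)
  img_dir <- file.path(cfg$path, cfg[[split]])
  imgs <- sort(dir(img_dir, pattern = "\\.png$", full.names = TRUE))
  labs <- lapply(imgs, function(p)
    read_labels(sub("images", "labels", sub("\\.png$", ".txt", p))))
  list(images = imgs, labels = labs, names = cfg$names)
}
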