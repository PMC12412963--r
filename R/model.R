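# ---------------------------------------------------------------------------
# Model assembly: scaled backbone, PAFPN neck, coupled head; ablation
# variants cf1..cf5 differ only in which block family fills the four
# backbone C-slots.
# ---------------------------------------------------------------------------

#' Default anchor set (YOLOv5 COCO anchors)
#'
#' Three anchors per scale at strides 8/16/32, (width, height) in pixels of
#' the network input, sorted by area within each scale.
#' @export
default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

.strides <- c(8L, 16L, 32L)

make_divisible <- function(x, d = 8L) max(d, as.integer(round(x / d)) * d)

# Structural repeat count after depth scaling: round(n * depth), at least 1.
scale_depth <- function(n, depth) max(1L, as.integer(round(n * depth)))

# Base repeat ladders (before depth scaling) for the four backbone C-slots,
# per block family. C2f keeps single units in every slot; C3 and C2fR
# follow the 3/6/6/3 ladder. These ladders, like the block
# internals, were fixed by calibrating the assembled variants against the
# published per-variant parameter/GFLOPs table (see the methods vignette).
.slot_base_repeats <- list(
  C2f  = c(3, 3, 3, 3),
  C3   = c(3, 6, 6, 3),
  C2fR = c(3, 6, 6, 3))

.variant_slots <- list(
  cf1 = c("C2f", "C2f", "C2f", "C2f"),
  cf2 = c("C3", "C2f", "C3", "C2f"),
  cf3 = c("C3", "C2fR", "C3", "C2fR"),
  cf4 = c("C3", "C3", "C3", "C3"),
  cf5 = c("C2fR", "C2fR", "C2fR", "C2fR"))

#' Model configuration
#'
#' @param num_classes Number of object classes (7 for the fruit set).
#' @param variant One of `"cf1"`..`"cf5"`; `"cf5"` is the full YOLOcF.
#' @param depth_multiple,width_multiple Compound scaling factors.
#' @param img_size Network input size, divisible by 32.
#' @param anchors 3-scale anchor list as [default_anchors()].
#' @return A `yolocf_config` list.
#' @export
yolocf_config <- function(num_classes = 7L, variant = "cf5",
                          depth_multiple = 0.33, width_multiple = 0.25,
                          img_size = 640L, anchors = default_anchors()) {
  variant <- match.arg(variant, names(.variant_slots))
  if (img_size %% 32L != 0L) stop("img_size must be divisible by 32")
  if (num_classes < 1L) stop("num_classes must be positive")
  structure(list(num_classes = as.integer(num_classes), variant = variant,
                 depth_multiple = depth_multiple, width_multiple = width_multiple,
                 img_size = as.integer(img_size), anchors = anchors),
            class = "yolocf_config")
}

# Build the declarative layer table; each row knows its inputs by index
# (0 = image). The same table drives execution, complexity accounting and
# the YAML dump.
.build_layers <- function(cfg) {
  wm <- cfg$width_multiple; dm <- cfg$depth_multiple
  ch <- vapply(c(64, 128, 256, 512, 1024), function(c) make_divisible(c * wm), 0L)
  slots <- .variant_slots[[cfg$variant]]
  slot_block <- function(i, cin, cout) {
    kind <- slots[i]
    n <- scale_depth(.slot_base_repeats[[kind]][i], dm)
    switch(kind, C2f = make_c2f(cin, cout, n), C3 = make_c3(cin, cout, n),
           C2fR = make_c2fr(cin, cout, n))
  }
  nr <- scale_depth(3, dm)  # neck repeat
  no <- 3L * (5L + cfg$num_classes)
  head_conv <- function(cin) make_cbs(cin, no, 1L, act = FALSE, bias = TRUE)
  L <- list(
    list(name = "stem",      from = 0L,        block = make_cbs(3L, ch[1], 6L, 2L)),
    list(name = "down1",     from = 1L,        block = make_mpc(ch[1], ch[2])),
    list(name = "slot1",     from = 2L,        block = slot_block(1L, ch[2], ch[2])),
    list(name = "down2",     from = 3L,        block = make_mpc(ch[2], ch[3])),
    list(name = "slot2",     from = 4L,        block = slot_block(2L, ch[3], ch[3])),
    list(name = "down3",     from = 5L,        block = make_mpc(ch[3], ch[4])),
    list(name = "slot3",     from = 6L,        block = slot_block(3L, ch[4], ch[4])),
    list(name = "down4",     from = 7L,        block = make_mpc(ch[4], ch[5])),
    list(name = "slot4",     from = 8L,        block = slot_block(4L, ch[5], ch[5])),
    list(name = "sppr",      from = 9L,        block = make_sppr(ch[5], ch[5])),
    list(name = "up1",       from = 10L,       op = "upsample"),
    list(name = "cat_p4",    from = c(11L, 7L), op = "concat"),
    list(name = "neck_p4td", from = 12L,       block = make_c2fr(ch[5] + ch[4], ch[4], nr)),
    list(name = "up2",       from = 13L,       op = "upsample"),
    list(name = "cat_p3",    from = c(14L, 5L), op = "concat"),
    list(name = "neck_p3",   from = 15L,       block = make_c2fr(ch[4] + ch[3], ch[3], nr)),
    list(name = "down_p3",   from = 16L,       block = make_cbs(ch[3], ch[3], 3L, 2L)),
    list(name = "cat_p4b",   from = c(17L, 13L), op = "concat"),
    list(name = "neck_p4",   from = 18L,       block = make_c2fr(ch[3] + ch[4], ch[4], nr)),
    list(name = "down_p4",   from = 19L,       block = make_cbs(ch[4], ch[4], 3L, 2L)),
    list(name = "cat_p5",    from = c(20L, 10L), op = "concat"),
    list(name = "neck_p5",   from = 21L,       block = make_c2fr(ch[4] + ch[5], ch[5], nr)),
    list(name = "head_p3",   from = 16L,       block = head_conv(ch[3])),
    list(name = "head_p4",   from = 19L,       block = head_conv(ch[4])),
    list(name = "head_p5",   from = 22L,       block = head_conv(ch[5])))
  attr(L, "head_idx") <- c(23L, 24L, 25L)
  L
}

#' Build a YOLOcF detector
#'
#' Assembles the scaled backbone (stem CBS, MPC downsamples, four C-slots
#' filled per variant, SPPR), the PAFPN neck with C2fR fusion blocks, and
#' the coupled single-convolution head emitting `3*(5+num_classes)` channels
#' at strides 8/16/32.
#'
#' @param config A [yolocf_config()], or arguments passed on to it.
#' @param ... Passed to [yolocf_config()] when `config` is missing.
#' @return An object of class `yolocf`.
#' @examples
#' m <- yolocf(variant = "cf5", num_classes = 7)
#' print(m)
#' @export
yolocf <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) yolocf_config(...) else config
  layers <- .build_layers(cfg)
  params <- list()
  for (l in layers) if (!is.null(l$block)) params <- c(params, block_params(l$block))
  m <- structure(list(config = cfg, layers = layers, params = params,
                      head_idx = attr(layers, "head_idx")),
                 class = "yolocf")
  init_head_bias(m)
  m
}

#' Forward pass
#'
#' Runs the network on a batch. For an `(H,W,3,N)` array returns the three
#' raw head grids (pre-sigmoid logits), each `(Hs,Ws,3*(5+nc),N)` at strides
#' 8/16/32.
#'
#' @param model A [yolocf()] model.
#' @param x Input batch `(H,W,3,N)`, H and W divisible by 32; also accepts an
#'   autodiff node or shape tensor.
#' @param ctx Evaluation context ([ycf_ctx()]).
#' @return List of three per-scale outputs.
#' @export
yolocf_forward <- function(model, x, ctx = ycf_ctx()) {
  if (is.array(x)) {
    d <- dim(x)
    if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
    if (d[3] != 3L) stop("input must have 3 channels, got ", d[3])
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
      stop("input spatial dims must be divisible by 32")
  }
  outs <- vector("list", length(model$layers))
  get_in <- function(fr) if (fr == 0L) x else outs[[fr]]
  slog <- if (inherits(x, "ycf_shape")) x$log
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (!is.null(slog)) slog$layer <- l$name
    outs[[i]] <- if (!is.null(l$block)) {
      block_forward(l$block, get_in(l$from), ctx)
    } else if (l$op == "upsample") {
      upsample2(get_in(l$from))
    } else {
      concat_c(lapply(l$from, get_in))
    }
  }
  outs[model$head_idx]
}

#' @export
print.yolocf <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("YOLOcF detector (variant %s)\n", cfg$variant))
  cat(sprintf("  classes: %d | img %dx%d | depth %.2f width %.2f\n",
              cfg$num_classes, cfg$img_size, cfg$img_size,
              cfg$depth_multiple, cfg$width_multiple))
  np <- count_params(x)
  cat(sprintf("  layers: %d | parameters: %s (%.1fM)\n", length(x$layers),
              format(np, big.mark = ","), np / 1e6))
  invisible(x)
}

#' @export
summary.yolocf <- function(object, input_hw = NULL, ...) {
  ih <- if (is.null(input_hw)) rep(object$config$img_size, 2L) else rep(input_hw, length.out = 2L)
  rep_ <- complexity_report(object, ih)
  class(rep_) <- c("summary.yolocf", class(rep_))
  rep_
}

#' Serialize the layer table as YAML
#'
#' Writes a human-readable description of every layer (kind, channels,
#' kernel, stride, repeats, wiring) — the architecture, not the weights.
#' @param model A [yolocf()] model.
#' @param path Output file; when `NULL` the YAML text is returned.
#' @export
model_yaml <- function(model, path = NULL) {
  rows <- lapply(seq_along(model$layers), function(i) {
    l <- model$layers[[i]]
    r <- list(index = i, name = l$name, from = as.integer(l$from))
    if (!is.null(l$block)) {
      b <- l$block
      r <- c(r, list(kind = b$kind, in_channels = b$cin, out_channels = b$cout,
                     kernel = b$k, stride = b$stride, repeats = b$repeats))
    } else r <- c(r, list(kind = l$op))
    r
  })
  doc <- list(variant = model$config$variant,
              num_classes = model$config$num_classes,
              img_size = model$config$img_size, layers = rows)
  if (is.null(path)) yaml::as.yaml(doc) else { yaml::write_yaml(doc, path); invisible(path) }
}

#' Save / load model weights
#'
#' Weights (and batch-norm running moments) are stored with R's native
#' serialization; the architecture is rebuilt from the stored configuration.
#' @param model A [yolocf()] model.
#' @param path Checkpoint file.
#' @export
save_weights <- function(model, path) {
  state <- lapply(model$params, function(p)
    mget(intersect(c("w", "b", "gamma", "beta", "rmean", "rvar"), names(p)), envir = p))
  saveRDS(list(config = model$config, state = state), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  ck <- readRDS(path)
  model <- yolocf(ck$config)
  if (length(model$params) != length(ck$state))
    stop("checkpoint does not match the architecture")
  for (i in seq_along(model$params))
    for (f in names(ck$state[[i]])) model$params[[i]][[f]] <- ck$state[[i]][[f]]
  model
}

# deterministic re-initialization of all weights from a seed
reinit_weights <- function(model, seed) {
  set.seed(seed)
  for (p in model$params) {
    d <- dim(p$w)
    fan_in <- d[1] * d[2] * d[3]
    p$w <- array(stats::rnorm(prod(d), 0, sqrt(2) / sqrt(fan_in)), dim = d)
    if (!is.null(p$b)) p$b <- numeric(d[4])
    if (!is.null(p$gamma)) {
      p$gamma <- rep(1, d[4]); p$beta <- numeric(d[4])
      p$rmean <- numeric(d[4]); p$rvar <- rep(1, d[4])
    }
  }
  init_head_bias(model)
  invisible(model)
}

# prior-aware head bias: start objectness near the expected object density
# and class scores near uniform, which stabilizes the first epochs
init_head_bias <- function(model) {
  cfg <- model$config
  nc <- cfg$num_classes; na_ <- 5L + nc
  for (s in 1:3) {
    l <- model$layers[[model$head_idx[s]]]
    p <- l$block$params$cv
    grid <- cfg$img_size / .strides[s]
    b <- p$b
    for (a in 0:2) {
      b[a * na_ + 5L] <- log(8 / grid^2)
      b[a * na_ + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99))
    }
    p$b <- b
  }
  invisible(model)
}
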