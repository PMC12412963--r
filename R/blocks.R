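# ---------------------------------------------------------------------------
# Network building blocks.
#
# A block is a list of class "ycf_block": kind, channel contract, child
# blocks, and parameter environments. block_forward() runs a block on
#   * a plain (H,W,C,N) array        -> inference values,
#   * an "ag" autodiff node          -> taped values for training,
#   * a "ycf_shape" symbolic tensor  -> shape propagation that logs every
#     convolution (the basis of the analytic parameter/FLOPs accounting).
# The same forward code serves all three, so the counted architecture is by
# construction the executed architecture.
# ---------------------------------------------------------------------------

autopad <- function(k) if (k == 6L) 2L else k %/% 2L

new_param_conv <- function(cin, cout, k, bias = FALSE, gain = sqrt(2)) {
  p <- new.env(parent = emptyenv())
  fan_in <- k * k * cin
  p$w <- array(stats::rnorm(k * k * cin * cout, 0, gain / sqrt(fan_in)),
               dim = c(k, k, cin, cout))
  if (bias) {
    p$b <- numeric(cout)
  } else {
    p$gamma <- rep(1, cout); p$beta <- numeric(cout)
    p$rmean <- numeric(cout); p$rvar <- rep(1, cout)
  }
  p
}

# wrap parameters of env `p` as autodiff leaves, once per tape
.wrap_params <- function(p, ctx) {
  if (!is.null(p$.tp) && identical(p$.tp, ctx$tape)) return(p$.nodes)
  nm <- intersect(c("w", "b", "gamma", "beta"), names(p))
  nodes <- lapply(nm, function(f) ag_leaf(p[[f]], ctx$tape))
  names(nodes) <- nm
  p$.tp <- ctx$tape; p$.nodes <- nodes
  ctx$params <- c(ctx$params, list(p))
  nodes
}

# --- symbolic shape tensor --------------------------------------------------

shape_tensor <- function(h, w, c) {
  s <- new.env(parent = emptyenv())
  s$h <- h; s$w <- w; s$c <- c
  s$log <- new.env(parent = emptyenv()); s$log$rows <- list()
  class(s) <- "ycf_shape"
  s
}
.shape_child <- function(s, h, w, c) {
  o <- new.env(parent = emptyenv())
  o$h <- h; o$w <- w; o$c <- c; o$log <- s$log
  class(o) <- "ycf_shape"
  o
}
.shape_log <- function(s, k, cin, cout, ho, wo, bias) {
  s$log$rows[[length(s$log$rows) + 1L]] <- list(
    layer = s$log$layer %||% "", k = k, cin = cin, cout = cout, ho = ho, wo = wo,
    params = k * k * cin * cout + if (bias) cout else 2L * cout,
    flops = 2 * k * k * cin * cout * ho * wo)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
conv2d.ycf_shape <- function(x, w, stride = 1L, pad = 0L) {
  d <- dim(w)
  if (d[3] != x$c) stop("shape trace: channel mismatch (", d[3], " vs ", x$c, ")")
  ho <- (x$h + 2 * pad - d[1]) %/% stride + 1L
  wo <- (x$w + 2 * pad - d[1]) %/% stride + 1L
  .shape_log(x, d[1], d[3], d[4], ho, wo, bias = FALSE)
  .shape_child(x, ho, wo, d[4])
}
#' @export
silu.ycf_shape <- function(x) x
#' @export
bn_ch.ycf_shape <- function(x, gamma, beta, p, training, momentum = 0.03, eps = 1e-5) x
#' @export
bias_ch.ycf_shape <- function(x, b) {
  # conv2d already logged without bias; amend the last row
  n <- length(x$log$rows)
  r <- x$log$rows[[n]]
  x$log$rows[[n]]$params <- r$params - 2L * r$cout + r$cout
  x
}
#' @export
maxpool2d.ycf_shape <- function(x, k, stride, pad = 0L)
  .shape_child(x, (x$h + 2 * pad - k) %/% stride + 1L,
               (x$w + 2 * pad - k) %/% stride + 1L, x$c)
#' @export
upsample2.ycf_shape <- function(x) .shape_child(x, 2L * x$h, 2L * x$w, x$c)
#' @export
concat_c.ycf_shape <- function(xs)
  .shape_child(xs[[1]], xs[[1]]$h, xs[[1]]$w, sum(vapply(xs, function(s) s$c, 0)))
#' @export
slice_c.ycf_shape <- function(x, from, to) .shape_child(x, x$h, x$w, to - from + 1L)

# --- block constructors -----------------------------------------------------

new_block <- function(kind, cin, cout, k = 1L, stride = 1L, repeats = 1L,
                      sub = list(), params = list(), extra = list()) {
  structure(c(list(kind = kind, cin = cin, cout = cout, k = k, stride = stride,
                   repeats = repeats, sub = sub, params = params), extra),
            class = "ycf_block")
}

.chk_pos <- function(...) {
  v <- c(...)
  if (any(v <= 0 | v != round(v))) stop("channel/kernel/stride values must be positive integers")
}

#' Convolution–batch-norm–SiLU unit (CBS)
#'
#' The elementary unit of the detector: a 2-D convolution without bias,
#' batch normalization with trainable affine parameters, and the SiLU
#' activation. Stride-1 CBS preserves spatial size; stride-2 halves it
#' (even input sizes). The 6x6 stride-2 stem uses padding 2.
#'
#' @param cin,cout Input/output channels.
#' @param k Kernel size (odd, or 6 for the stem).
#' @param stride 1 or 2.
#' @param act Apply the SiLU activation (the coupled head uses `act = FALSE`
#'   together with `bias = TRUE` and no batch norm).
#' @param bias Use a plain conv bias instead of batch norm.
#' @return A block object usable with [block_forward()].
#' @export
make_cbs <- function(cin, cout, k = 1L, stride = 1L, act = TRUE, bias = FALSE) {
  .chk_pos(cin, cout, k, stride)
  if (!stride %in% c(1L, 2L)) stop("unsupported stride: ", stride)
  if (k %% 2L == 0L && k != 6L) stop("kernel must be odd (or 6 for the stem)")
  new_block("CBS", cin, cout, k, stride,
            params = list(cv = new_param_conv(cin, cout, k, bias = bias)),
            extra = list(act = act, bias = bias))
}

#' Maxpool+conv downsampling block (MPC)
#'
#' Two-branch stride-2 downsampler: a leading 1x1 CBS widens the input to
#' `cout`, a 3x3 stride-2 CBS then reduces it to `cout/2`; in parallel a
#' 2x2 stride-2 maxpool of the input feeds a 1x1 CBS to `cout/2`. The two
#' branches are concatenated, halving the spatial size and ending at `cout`
#' channels.
#'
#' @inheritParams make_cbs
#' @export
make_mpc <- function(cin, cout) {
  .chk_pos(cin, cout)
  if (cout %% 2L != 0L) stop("MPC requires even out_channels")
  new_block("MPC", cin, cout, stride = 2L, sub = list(
    lead = make_cbs(cin, cout, 1L),
    conv_br = make_cbs(cout, cout %/% 2L, 3L, 2L),
    pool_br = make_cbs(cin, cout %/% 2L, 1L)))
}

#' Four-convolution split/concat unit (C4)
#'
#' The unit repeated inside C2fR: an entry 1x1 CBS, a channel split into two
#' halves, a 3x3 CBS on each half restoring full width, concatenation of the
#' two expanded halves, and an exit 1x1 CBS back to `channels`. No residual
#' addition. Shape preserving.
#'
#' @param channels Even channel count.
#' @export
make_c4 <- function(channels) {
  .chk_pos(channels)
  if (channels %% 2L != 0L) stop("C4 requires even channels")
  h <- channels %/% 2L
  new_block("C4", channels, channels, sub = list(
    entry = make_cbs(channels, channels, 1L),
    br1 = make_cbs(h, channels, 3L),
    br2 = make_cbs(h, channels, 3L),
    exit = make_cbs(2L * channels, channels, 1L)))
}

#' Cross-stage feature block with C4 units (C2fR)
#'
#' Split–transform–merge block: an entry 1x1 CBS produces two half-width
#' streams; one stream passes through `n` chained [make_c4()] units, every
#' intermediate output being retained; all retained streams are concatenated
#' and fused by an exit 1x1 CBS.
#'
#' @param cin,cout Channels; `cout` even.
#' @param n Number of chained C4 units (structural repeats, >= 1).
#' @export
make_c2fr <- function(cin, cout, n = 1L) {
  .chk_pos(cin, cout, n)
  if (cout %% 2L != 0L) stop("C2fR requires even out_channels")
  h <- cout %/% 2L
  new_block("C2fR", cin, cout, repeats = n, sub = c(
    list(entry = make_cbs(cin, cout, 1L)),
    stats::setNames(lapply(seq_len(n), function(i) make_c4(h)), paste0("c4_", seq_len(n))),
    list(exit = make_cbs((n + 2L) * h, cout, 1L))))
}

#' YOLOv5 C3 block (reference)
#'
#' Faithful C3: two parallel entry 1x1 CBS to half width, `n` residual
#' bottlenecks (1x1 then 3x3 CBS with identity shortcut) on one stream,
#' concatenation, and an exit 1x1 CBS.
#' @inheritParams make_c2fr
#' @export
make_c3 <- function(cin, cout, n = 1L) {
  .chk_pos(cin, cout, n)
  if (cout %% 2L != 0L) stop("C3 requires even out_channels")
  h <- cout %/% 2L
  bns <- lapply(seq_len(n), function(i)
    list(cv1 = make_cbs(h, h, 1L), cv2 = make_cbs(h, h, 3L)))
  new_block("C3", cin, cout, repeats = n, sub = list(
    cv1 = make_cbs(cin, h, 1L), cv2 = make_cbs(cin, h, 1L),
    exit = make_cbs(2L * h, cout, 1L)), extra = list(bottlenecks = bns))
}

#' YOLOv8 C2f block (reference)
#'
#' Faithful C2f: entry 1x1 CBS to `cout`, split in two half-width streams,
#' `n` residual bottlenecks (two 3x3 CBS with identity shortcut) with all
#' intermediate outputs retained, concatenation, exit 1x1 CBS.
#' @inheritParams make_c2fr
#' @export
make_c2f <- function(cin, cout, n = 1L) {
  .chk_pos(cin, cout, n)
  if (cout %% 2L != 0L) stop("C2f requires even out_channels")
  h <- cout %/% 2L
  bns <- lapply(seq_len(n), function(i)
    list(cv1 = make_cbs(h, h, 3L), cv2 = make_cbs(h, h, 3L)))
  new_block("C2f", cin, cout, repeats = n, sub = list(
    entry = make_cbs(cin, cout, 1L),
    exit = make_cbs((n + 2L) * h, cout, 1L)), extra = list(bottlenecks = bns))
}

#' Reduced spatial pyramid pooling (SPPR)
#'
#' An entry 1x1 CBS, concatenation of its output with a single 5x5 stride-1
#' maxpool of that output, and an exit 1x1 CBS — a lighter replacement for
#' SPPF, which chains three pools.
#' @inheritParams make_cbs
#' @export
make_sppr <- function(cin, cout) {
  .chk_pos(cin, cout)
  new_block("SPPR", cin, cout, sub = list(
    entry = make_cbs(cin, cin, 1L),
    exit = make_cbs(2L * cin, cout, 1L)))
}

#' YOLOv5 SPPF block (reference)
#' @inheritParams make_cbs
#' @export
make_sppf <- function(cin, cout) {
  .chk_pos(cin, cout)
  h <- cin %/% 2L
  new_block("SPPF", cin, cout, sub = list(
    entry = make_cbs(cin, h, 1L),
    exit = make_cbs(4L * h, cout, 1L)))
}

# --- forward ----------------------------------------------------------------

#' Run a block
#'
#' @param b Block from one of the `make_*` constructors.
#' @param x Input: an `(H,W,C,N)` array, an autodiff node, or a shape tensor.
#' @param ctx Evaluation context from [ycf_ctx()].
#' @return Output in the same representation as `x`.
#' @export
block_forward <- function(b, x, ctx = ycf_ctx()) {
  switch(b$kind,
    CBS = .fwd_cbs(b, x, ctx),
    MPC = {
      lead <- .fwd_cbs(b$sub$lead, x, ctx)
      a <- .fwd_cbs(b$sub$pool_br, maxpool2d(x, 2L, 2L), ctx)
      bb <- .fwd_cbs(b$sub$conv_br, lead, ctx)
      concat_c(list(a, bb))
    },
    C4 = {
      y <- .fwd_cbs(b$sub$entry, x, ctx)
      h <- b$cin %/% 2L
      y1 <- .fwd_cbs(b$sub$br1, slice_c(y, 1L, h), ctx)
      y2 <- .fwd_cbs(b$sub$br2, slice_c(y, h + 1L, 2L * h), ctx)
      .fwd_cbs(b$sub$exit, concat_c(list(y1, y2)), ctx)
    },
    C2fR = {
      y <- .fwd_cbs(b$sub$entry, x, ctx)
      h <- b$cout %/% 2L
      streams <- list(slice_c(y, 1L, h), slice_c(y, h + 1L, 2L * h))
      for (i in seq_len(b$repeats))
        streams[[i + 2L]] <- block_forward(b$sub[[paste0("c4_", i)]],
                                           streams[[i + 1L]], ctx)
      .fwd_cbs(b$sub$exit, concat_c(streams), ctx)
    },
    C3 = {
      y1 <- .fwd_cbs(b$sub$cv1, x, ctx)
      for (bn in b$bottlenecks)
        y1 <- .fwd_cbs(bn$cv2, .fwd_cbs(bn$cv1, y1, ctx), ctx) + y1
      y2 <- .fwd_cbs(b$sub$cv2, x, ctx)
      .fwd_cbs(b$sub$exit, concat_c(list(y1, y2)), ctx)
    },
    C2f = {
      y <- .fwd_cbs(b$sub$entry, x, ctx)
      h <- b$cout %/% 2L
      streams <- list(slice_c(y, 1L, h), slice_c(y, h + 1L, 2L * h))
      for (i in seq_along(b$bottlenecks)) {
        bn <- b$bottlenecks[[i]]
        prev <- streams[[i + 1L]]
        streams[[i + 2L]] <- .fwd_cbs(bn$cv2, .fwd_cbs(bn$cv1, prev, ctx), ctx) + prev
      }
      .fwd_cbs(b$sub$exit, concat_c(streams), ctx)
    },
    SPPR = {
      y <- .fwd_cbs(b$sub$entry, x, ctx)
      .fwd_cbs(b$sub$exit, concat_c(list(y, maxpool2d(y, 5L, 1L, 2L))), ctx)
    },
    SPPF = {
      y <- .fwd_cbs(b$sub$entry, x, ctx)
      p1 <- maxpool2d(y, 5L, 1L, 2L)
      p2 <- maxpool2d(p1, 5L, 1L, 2L)
      p3 <- maxpool2d(p2, 5L, 1L, 2L)
      .fwd_cbs(b$sub$exit, concat_c(list(y, p1, p2, p3)), ctx)
    },
    stop("unknown block kind: ", b$kind))
}

# shared "+" for plain arrays / shape tensors used by the residual blocks
#' @export
`+.ycf_shape` <- function(e1, e2) e1

.fwd_cbs <- function(b, x, ctx) {
  p <- b$params$cv
  pad <- autopad(b$k)
  if (is_ag(x)) {
    nd <- .wrap_params(p, ctx)
    y <- conv2d(x, nd$w, b$stride, pad)
    y <- if (b$bias) bias_ch(y, nd$b)
         else bn_ch(y, nd$gamma, nd$beta, p, training = TRUE)
  } else {
    y <- conv2d(x, p$w, b$stride, pad)
    y <- if (b$bias) bias_ch(y, p$b)
         else bn_ch(y, p$gamma, p$beta, p, training = FALSE)
  }
  if (b$act) silu(y) else y
}

#' Evaluation context
#'
#' @param training Build an autodiff tape (used internally by the trainer).
#' @export
ycf_ctx <- function(training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training
  if (training) { ctx$tape <- ag_tape(); ctx$params <- list() }
  ctx
}

# collect all conv parameter environments of a block (training/optimizer use)
block_params <- function(b) {
  out <- list()
  if (!is.null(b$params$cv)) out <- c(out, list(b$params$cv))
  for (s in b$sub) out <- c(out, block_params(s))
  for (bn in b$bottlenecks %||% list())
    for (s in bn) out <- c(out, block_params(s))
  out
}
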