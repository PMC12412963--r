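#' @useDynLib yolocf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation over numeric arrays.
#
# A graph ("tape") is an environment collecting nodes in creation order; a
# node is an environment of class "ag" with fields
#   v  : value (numeric vector/array)
#   g  : accumulated gradient (NULL until backward touches it)
#   bw : function(g) -> list of parent gradients (NULL for leaves)
#   pr : list of parent nodes
# Backward walks the tape in reverse creation order, which is a valid
# topological order because nodes are only built from existing nodes.
# Inference takes a separate plain-array path through the same generic
# primitives, so the forward logic is written once (see generics below).
# ---------------------------------------------------------------------------

#' Create an autodiff tape
#'
#' @return An empty tape environment collecting nodes in creation order.
#' @export
ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(v, tape, bw = NULL, pr = list()) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$bw <- bw; nd$pr <- pr; nd$tp <- tape
  class(nd) <- "ag"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

#' @export
print.ag <- function(x, ...) {
  d <- dim(x$v)
  cat("<ag node", if (is.null(d)) paste0("len ", length(x$v)) else paste(d, collapse = "x"),
      if (is.null(x$bw)) "(leaf)" else "", ">\n")
  invisible(x)
}

#' Wrap a value as a leaf node on a tape
#' @param v Numeric vector or array.
#' @param tape A tape from [ag_tape()].
#' @export
ag_leaf <- function(v, tape) ag_node(v, tape)

#' Is an object an autodiff node?
#' @param x Any object.
#' @export
is_ag <- function(x) inherits(x, "ag")

ag_accum <- function(nd, g) {
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
}

# Backpropagate from scalar (or seeded) root through the tape.
#' Backpropagate through a tape
#'
#' Seeds the root gradient and walks the tape in reverse creation order,
#' accumulating gradients into every reachable node's `g` field.
#' @param root The output node (typically a scalar loss).
#' @param seed Gradient seed (1 by default).
#' @export
ag_backward <- function(root, seed = 1) {
  root$g <- if (length(root$v) == 1L) seed else array(seed, dim(root$v))
  rv <- root$v
  tape <- root$tp
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$bw)) next
    gs <- nd$bw(nd$g)
    for (j in seq_along(gs)) if (!is.null(gs[[j]])) ag_accum(nd$pr[[j]], gs[[j]])
    # a consumed interior node will not be read again: release its buffers
    # eagerly to keep the live set (and GC cost) small; leaves keep `g`
    nd$bw <- NULL; nd$pr <- list(); nd$g <- NULL; nd$v <- NULL
    tape$nodes[i] <- list(NULL)
  }
  root$v <- rv
  invisible(root)
}

# --- generic primitives: array method = plain forward, ag method = taped ----

#' 2-D convolution (no bias)
#'
#' @param x `(H,W,C,N)` array, autodiff node, or shape tensor.
#' @param w `(k,k,C,O)` kernel array (autodiff node on the taped path).
#' @param stride,pad Convolution geometry.
#' @export
conv2d <- function(x, w, stride = 1L, pad = 0L) UseMethod("conv2d")
#' @export
conv2d.default <- function(x, w, stride = 1L, pad = 0L) .conv2d_fw(x, w, stride, pad)
#' @export
conv2d.ag <- function(x, w, stride = 1L, pad = 0L) {
  stopifnot(is_ag(w))
  xv <- x$v; wv <- w$v
  if (dim(wv)[1] > 1L) {
    # keep the im2col buffer from the forward for the adjoint GEMMs
    r <- .conv2d_fw_cache(xv, wv, stride, pad)
    colbuf <- r$col; xd <- dim(xv)
    return(ag_node(r$y, x$tp, pr = list(x, w), bw = function(g) {
      b <- .conv2d_bw_cache(colbuf, wv, g, xd, stride, pad, TRUE)
      list(b$gx, b$gw)
    }))
  }
  y <- .conv2d_fw(xv, wv, stride, pad)
  ag_node(y, x$tp, pr = list(x, w), bw = function(g) {
    r <- .conv2d_bw(xv, wv, g, stride, pad, TRUE)
    list(r$gx, r$gw)
  })
}

#' SiLU activation `x * sigmoid(x)`
#' @param x Array, node or shape tensor.
#' @export
silu <- function(x) UseMethod("silu")
#' @export
silu.default <- function(x) if (is.array(x)) .silu_fw(x) else x * (1 / (1 + exp(-x)))
#' @export
silu.ag <- function(x) {
  xv <- x$v
  r <- .silu_fw2(xv)
  sg <- r$s
  ag_node(r$y, x$tp, pr = list(x),
          bw = function(g) list(.silu_bw2(xv, sg, g)))
}

#' 2-D max pooling
#' @param x Array, node or shape tensor.
#' @param k,stride,pad Pooling geometry (padding is `-Inf`-valued).
#' @export
maxpool2d <- function(x, k, stride, pad = 0L) UseMethod("maxpool2d")
#' @export
maxpool2d.default <- function(x, k, stride, pad = 0L) .maxpool_fw(x, k, stride, pad)$y
#' @export
maxpool2d.ag <- function(x, k, stride, pad = 0L) {
  r <- .maxpool_fw(x$v, k, stride, pad)
  xd <- dim(x$v)
  ag_node(r$y, x$tp, pr = list(x),
          bw = function(g) list(.maxpool_bw(r$idx, g, xd)))
}

#' Nearest-neighbour 2x upsampling
#' @param x Array, node or shape tensor.
#' @export
upsample2 <- function(x) UseMethod("upsample2")
#' @export
upsample2.default <- function(x) .upsample2_fw(x)
#' @export
upsample2.ag <- function(x)
  ag_node(.upsample2_fw(x$v), x$tp, pr = list(x),
          bw = function(g) list(.upsample2_bw(g)))

# Concatenate feature maps along the channel axis (3rd of H,W,C,N).
#' Concatenate along the channel axis
#' @param xs List of `(H,W,C,N)` inputs with equal H, W, N.
#' @export
concat_c <- function(xs) UseMethod("concat_c", xs[[1]])
.cat_arrays <- function(vs) {
  d <- dim(vs[[1]]); cs <- vapply(vs, function(v) dim(v)[3], 0)
  hw <- d[1] * d[2]; n <- d[4]
  mats <- lapply(vs, function(v) { dim(v) <- c(hw * dim(v)[3], n); v })
  y <- do.call(rbind, mats)
  dim(y) <- c(d[1], d[2], sum(cs), n)
  y
}
#' @export
concat_c.default <- function(xs) .cat_arrays(xs)
#' @export
concat_c.ag <- function(xs) {
  vs <- lapply(xs, function(x) x$v)
  cs <- vapply(vs, function(v) dim(v)[3], 0)
  ends <- cumsum(cs); starts <- ends - cs + 1
  ag_node(.cat_arrays(vs), xs[[1]]$tp, pr = xs, bw = function(g) {
    lapply(seq_along(cs), function(i) {
      gi <- g[, , starts[i]:ends[i], , drop = FALSE]
      gi
    })
  })
}

#' Select a channel range
#' @param x `(H,W,C,N)` input.
#' @param from,to 1-based inclusive channel bounds.
#' @export
slice_c <- function(x, from, to) UseMethod("slice_c")
#' @export
slice_c.default <- function(x, from, to) x[, , from:to, , drop = FALSE]
#' @export
slice_c.ag <- function(x, from, to) {
  xd <- dim(x$v)
  ag_node(x$v[, , from:to, , drop = FALSE], x$tp, pr = list(x), bw = function(g) {
    gx <- array(0, xd)
    gx[, , from:to, ] <- g
    list(gx)
  })
}

# Batch normalization with SiLU-friendly channel layout. `p` is the parameter
# environment holding gamma, beta and running moments; in training mode batch
# statistics are used and the running moments are updated in place.
#' Channel batch normalization
#'
#' Training mode (taped input) normalizes by batch statistics and updates
#' the running moments held in `p`; inference mode uses the running moments.
#' @param x `(H,W,C,N)` input.
#' @param gamma,beta Per-channel affine parameters (nodes on the taped path).
#' @param p Parameter environment holding `rmean`, `rvar`.
#' @param training Unused (the input representation decides the mode).
#' @param momentum Running-moment update rate.
#' @param eps Variance floor.
#' @export
bn_ch <- function(x, gamma, beta, p, training, momentum = 0.03, eps = 1e-5)
  UseMethod("bn_ch")
ch_rep <- function(v, d) rep(rep(v, each = d[1] * d[2]), d[4])
#' @export
bn_ch.default <- function(x, gamma, beta, p, training, momentum = 0.03, eps = 1e-5) {
  sc <- gamma / sqrt(p$rvar + eps)
  .bn_infer(x, sc, beta - p$rmean * sc)
}
#' @export
bn_ch.ag <- function(x, gamma, beta, p, training, momentum = 0.03, eps = 1e-5) {
  d <- dim(x$v); m <- d[1] * d[2] * d[4]
  r <- .bn_train_fw(x$v, gamma$v, beta$v, eps)
  va <- 1 / r$istd^2 - eps
  p$rmean <- (1 - momentum) * p$rmean + momentum * r$mu
  p$rvar  <- (1 - momentum) * p$rvar + momentum * va * m / max(m - 1, 1)
  xv <- x$v; gv <- gamma$v
  ag_node(r$y, x$tp, pr = list(x, gamma, beta), bw = function(g) {
    b <- .bn_train_bw(xv, gv, r$mu, r$istd, g)
    list(b$gx, b$dgamma, b$dbeta)
  })
}

# Add channel-wise bias (head convolutions carry a bias, no batch norm).
#' Add a per-channel bias
#' @param x `(H,W,C,N)` input.
#' @param b Length-C bias.
#' @export
bias_ch <- function(x, b) UseMethod("bias_ch")
#' @export
bias_ch.default <- function(x, b) {
  d <- dim(x); y <- x + ch_rep(b, d); dim(y) <- d; y
}
#' @export
bias_ch.ag <- function(x, b) {
  d <- dim(x$v)
  y <- x$v + ch_rep(b$v, d); dim(y) <- d
  ag_node(y, x$tp, pr = list(x, b), bw = function(g) {
    gm <- g; dim(gm) <- c(d[1] * d[2], d[3], d[4])
    list(g, rowSums(colSums(gm)))
  })
}

# --- elementwise algebra on nodes (for the loss head) ----------------------

#' @export
Ops.ag <- function(e1, e2) {
  op <- .Generic
  if (op %in% c("+", "-", "*", "/")) {
    a_ag <- is_ag(e1); b_ag <- if (missing(e2)) FALSE else is_ag(e2)
    if (missing(e2)) {  # unary +/-
      if (op == "-") return(ag_node(-e1$v, e1$tp, pr = list(e1), bw = function(g) list(-g)))
      return(e1)
    }
    av <- if (a_ag) e1$v else e1
    bv <- if (b_ag) e2$v else e2
    tp <- if (a_ag) e1$tp else e2$tp
    v <- switch(op, "+" = av + bv, "-" = av - bv, "*" = av * bv, "/" = av / bv)
    bw <- switch(op,
      "+" = function(g) list(if (a_ag) .unbc(g, av), if (b_ag) .unbc(g, bv)),
      "-" = function(g) list(if (a_ag) .unbc(g, av), if (b_ag) .unbc(-g, bv)),
      "*" = function(g) list(if (a_ag) .unbc(g * bv, av), if (b_ag) .unbc(g * av, bv)),
      "/" = function(g) list(if (a_ag) .unbc(g / bv, av),
                             if (b_ag) .unbc(-g * av / (bv * bv), bv)))
    pr <- list(); if (a_ag) pr <- c(pr, list(e1)); if (b_ag) pr <- c(pr, list(e2))
    nd <- ag_node(v, tp, pr = pr, bw = function(g) Filter(Negate(is.null), bw(g)))
    return(nd)
  }
  if (op == "^") {
    stopifnot(is_ag(e1), is.numeric(e2))
    v <- e1$v^e2; xv <- e1$v
    return(ag_node(v, e1$tp, pr = list(e1), bw = function(g) list(g * e2 * xv^(e2 - 1))))
  }
  stop("unsupported op for ag nodes: ", op)
}

# collapse a broadcast gradient back to the operand's length (scalar case)
.unbc <- function(g, v) if (length(v) == 1L && length(g) > 1L) sum(g) else g

#' @export
Math.ag <- function(x, ...) {
  xv <- x$v
  switch(.Generic,
    exp  = ag_node(exp(xv), x$tp, pr = list(x), bw = function(g) list(g * exp(xv))),
    log  = ag_node(log(xv), x$tp, pr = list(x), bw = function(g) list(g / xv)),
    sqrt = { s <- sqrt(xv); ag_node(s, x$tp, pr = list(x), bw = function(g) list(g / (2 * s))) },
    atan = ag_node(atan(xv), x$tp, pr = list(x), bw = function(g) list(g / (1 + xv * xv))),
    abs  = ag_node(abs(xv), x$tp, pr = list(x), bw = function(g) list(g * sign(xv))),
    stop("unsupported Math op for ag nodes: ", .Generic))
}

#' Sigmoid
#' @param x Numeric vector or node.
#' @export
ag_sigmoid <- function(x) UseMethod("ag_sigmoid")
#' @export
ag_sigmoid.default <- function(x) 1 / (1 + exp(-x))
#' @export
ag_sigmoid.ag <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, x$tp, pr = list(x), bw = function(g) list(g * s * (1 - s)))
}

# elementwise min/max with subgradient to the winning operand (ties -> first)
#' Elementwise min/max with subgradient to the winner
#' @param a,b Numeric vectors or nodes.
#' @export
ag_pmin <- function(a, b) {
  if (!is_ag(a) && !is_ag(b)) return(pmin(a, b))
  av <- if (is_ag(a)) a$v else a; bv <- if (is_ag(b)) b$v else b
  take_a <- av <= bv
  tp <- if (is_ag(a)) a$tp else b$tp
  pr <- list(); if (is_ag(a)) pr <- c(pr, list(a)); if (is_ag(b)) pr <- c(pr, list(b))
  ag_node(pmin(av, bv), tp, pr = pr, bw = function(g) {
    out <- list()
    if (is_ag(a)) out <- c(out, list(.unbc(g * take_a, av)))
    if (is_ag(b)) out <- c(out, list(.unbc(g * !take_a, bv)))
    out
  })
}
#' @rdname ag_pmin
#' @export
ag_pmax <- function(a, b) {
  if (!is_ag(a) && !is_ag(b)) return(pmax(a, b))
  av <- if (is_ag(a)) a$v else a; bv <- if (is_ag(b)) b$v else b
  take_a <- av >= bv
  tp <- if (is_ag(a)) a$tp else b$tp
  pr <- list(); if (is_ag(a)) pr <- c(pr, list(a)); if (is_ag(b)) pr <- c(pr, list(b))
  ag_node(pmax(av, bv), tp, pr = pr, bw = function(g) {
    out <- list()
    if (is_ag(a)) out <- c(out, list(.unbc(g * take_a, av)))
    if (is_ag(b)) out <- c(out, list(.unbc(g * !take_a, bv)))
    out
  })
}

#' Sum / mean reduction
#' @param x Numeric vector or node.
#' @export
ag_sum <- function(x) UseMethod("ag_sum")
#' @export
ag_sum.default <- function(x) sum(x)
#' @export
ag_sum.ag <- function(x) {
  n <- length(x$v); d <- dim(x$v)
  ag_node(sum(x$v), x$tp, pr = list(x),
          bw = function(g) list(if (is.null(d)) rep(g, n) else array(g, d)))
}

#' @rdname ag_sum
#' @export
ag_mean <- function(x) UseMethod("ag_mean")
#' @export
ag_mean.default <- function(x) mean(x)
#' @export
ag_mean.ag <- function(x) {
  n <- length(x$v); d <- dim(x$v)
  ag_node(mean(x$v), x$tp, pr = list(x),
          bw = function(g) list(if (is.null(d)) rep(g / n, n) else array(g / n, d)))
}

# select elements by flat index; adjoint is scatter-add
#' Gather elements by flat index (adjoint: scatter-add)
#' @param x Array or node.
#' @param idx 1-based flat indices.
#' @export
ag_gather <- function(x, idx) UseMethod("ag_gather")
#' @export
ag_gather.default <- function(x, idx) x[idx]
#' @export
ag_gather.ag <- function(x, idx) {
  n <- length(x$v); d <- dim(x$v)
  ag_node(x$v[idx], x$tp, pr = list(x), bw = function(g) {
    gx <- numeric(n)
    # accumulate duplicates correctly
    acc <- rowsum(g, idx)
    gx[as.numeric(rownames(acc))] <- acc
    if (!is.null(d)) dim(gx) <- d
    list(gx)
  })
}

# Numerically stable binary cross-entropy from logits, elementwise.
#' Numerically stable elementwise binary cross-entropy from logits
#' @param x Logits (vector or node).
#' @param target 0/1 targets.
#' @export
bce_with_logits <- function(x, target) UseMethod("bce_with_logits")
#' @export
bce_with_logits.default <- function(x, target)
  pmax(x, 0) - x * target + log1p(exp(-abs(x)))
#' @export
bce_with_logits.ag <- function(x, target) {
  xv <- x$v
  v <- pmax(xv, 0) - xv * target + log1p(exp(-abs(xv)))
  ag_node(v, x$tp, pr = list(x),
          bw = function(g) list(g * (1 / (1 + exp(-xv)) - target)))
}
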