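# ---------------------------------------------------------------------------
# Analytic parameter and FLOPs accounting. Parameters are counted by
# enumerating the actual weight arrays; FLOPs come from a symbolic shape
# trace through the same forward code that executes the network, so the
# counted and executed architectures cannot drift apart.
# ---------------------------------------------------------------------------

#' Total trainable parameter count
#'
#' Enumerates every weight array of the model: convolution kernels,
#' conv biases (head), and batch-norm affine parameters. Batch-norm running
#' moments are not trainable and are not counted.
#'
#' @param model A [yolocf()] model or a single block.
#' @return Integer scalar.
#' @export
count_params <- function(model) {
  ps <- if (inherits(model, "ycf_block")) block_params(model) else model$params
  sum(vapply(ps, function(p) {
    n <- length(p$w)
    if (!is.null(p$b)) n <- n + length(p$b)
    if (!is.null(p$gamma)) n <- n + length(p$gamma) + length(p$beta)
    n
  }, 0))
}

# shape-trace a model (or block) at a given input size; returns the conv log
.trace <- function(model, input_hw, cin = 3L) {
  hw <- rep(input_hw, length.out = 2L)
  s <- shape_tensor(hw[1], hw[2], cin)
  if (inherits(model, "ycf_block")) block_forward(model, s) else yolocf_forward(model, s)
  s$log$rows
}

#' FLOPs of one forward pass
#'
#' Counts floating-point operations for a single image at the given input
#' size under one of two conventions:
#' \describe{
#'   \item{`mac2_standard`}{two operations per multiply–accumulate over all
#'     convolutions (the convention of the usual network profilers);
#'     pooling, activations, concatenation and upsampling are ignored.}
#'   \item{`eq7_paper`}{layer-wise output-area times layer parameters, the
#'     parameters taken as `k^2*ci*co + co` (conv with bias term);
#'     documentation-grade rendering of the textbook formula.}
#' }
#'
#' @param model A [yolocf()] model or a single block.
#' @param input_hw Input size (scalar or `c(H, W)`), divisible by 32 for a
#'   full model.
#' @param convention `"mac2_standard"` (default) or `"eq7_paper"`.
#' @param cin Input channels when profiling a bare block.
#' @return FLOPs in units of GFLOPs (1e9 operations).
#' @export
count_flops <- function(model, input_hw = NULL, convention = c("mac2_standard", "eq7_paper"),
                        cin = 3L) {
  convention <- match.arg(convention)
  if (is.null(input_hw)) input_hw <- model$config$img_size
  if (inherits(model, "yolocf") && any(rep(input_hw, 2L)[1:2] %% 32L != 0L))
    stop("input size must be divisible by 32")
  rows <- .trace(model, input_hw, cin)
  tot <- sum(vapply(rows, function(r) {
    if (convention == "mac2_standard") r$flops
    else r$ho * r$wo * (r$k^2 * r$cin * r$cout + r$cout)
  }, 0))
  tot / 1e9
}

#' Per-layer complexity report
#'
#' @param model A [yolocf()] model.
#' @param input_hw Input size, default the configured image size.
#' @return A `ycf_complexity` object: per-layer data frame plus totals
#'   (params and GFLOPs under both conventions).
#' @export
complexity_report <- function(model, input_hw = NULL) {
  if (is.null(input_hw)) input_hw <- model$config$img_size
  rows <- .trace(model, input_hw)
  layer <- vapply(rows, function(r) r$layer, "")
  par_r <- vapply(rows, function(r) r$params, 0)
  flo_r <- vapply(rows, function(r) r$flops, 0)
  eq7_r <- vapply(rows, function(r) r$ho * r$wo * (r$k^2 * r$cin * r$cout + r$cout), 0)
  per_layer <- data.frame(
    layer = vapply(model$layers, function(l) l$name, ""),
    kind = vapply(model$layers, function(l) if (is.null(l$block)) l$op else l$block$kind, ""),
    params = vapply(model$layers, function(l) {
      if (is.null(l$block)) 0 else sum(par_r[layer == l$name])
    }, 0),
    gflops = vapply(model$layers, function(l) sum(flo_r[layer == l$name]) / 1e9, 0))
  structure(list(per_layer = per_layer,
                 params = count_params(model),
                 gflops = sum(flo_r) / 1e9,
                 gflops_eq7 = sum(eq7_r) / 1e9,
                 input_hw = rep(input_hw, length.out = 2L),
                 variant = model$config$variant),
            class = "ycf_complexity")
}

#' @export
print.ycf_complexity <- function(x, ...) {
  cat(sprintf("Complexity of variant %s at %dx%d\n", x$variant,
              x$input_hw[1], x$input_hw[2]))
  pl <- x$per_layer
  pl$params <- format(pl$params, big.mark = ",")
  pl$gflops <- sprintf("%.4f", pl$gflops)
  print(pl, row.names = FALSE)
  cat(sprintf("Totals: %s params (%.1fM) | %.3f GFLOPs (2/MAC) | %.3f GFLOPs (area x params)\n",
              format(x$params, big.mark = ","), x$params / 1e6, x$gflops, x$gflops_eq7))
  invisible(x)
}

#' Export a complexity report
#'
#' @param report A [complexity_report()].
#' @param path Output `.csv` or `.json` file (chosen by extension).
#' @export
write_complexity <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(variant = report$variant,
                              input_hw = report$input_hw,
                              params = report$params,
                              gflops = report$gflops,
                              gflops_eq7 = report$gflops_eq7,
                              per_layer = report$per_layer),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$per_layer, path, row.names = FALSE)
  }
  invisible(path)
}
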