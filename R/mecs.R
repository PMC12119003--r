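# Median-enhanced channel and spatial attention (MECS).
#
# Channel stage: global average, max and median pooling feed one shared
# two-layer 1x1-conv MLP (C -> C/r, ReLU, C/r -> C); each branch output is
# passed through a sigmoid and the three sigmoided branches are SUMMED, so
# the channel gate Fc lies strictly in (0, 3). The gate multiplies the input.
# Spatial stage: a 5x5 depthwise conv extracts a base map; separable strip
# depthwise branches (1xk then kx1) at several k extract multi-scale context;
# base and branch outputs are summed, projected by a 1x1 conv, and the result
# multiplies the channel-weighted features.

#' MECS attention block constructor
#'
#' @param c channel count of the feature map the block attends over.
#' @param r reduction ratio of the shared channel MLP (`c/r` hidden units).
#' @param kernels integer vector of strip kernel lengths for the multi-scale
#'   spatial branches (each `k` yields a separable 1xk then kx1 depthwise
#'   pair applied to the 5x5 base output).
#' @param name block name used in profiler reports.
#' @return a module; apply with [forward()] or [mecs_forward()].
#' @export
mecs_block <- function(c, r = 4, kernels = c(7, 11, 21), name = "mecs") {
  hid <- max(1L, c %/% r)
  ch <- list(
    mlp1 = conv_block(c, hid, k = 1, act = FALSE, bn = FALSE, bias = TRUE,
                      name = "mlp1"),
    mlp2 = conv_block(hid, c, k = 1, act = FALSE, bn = FALSE, bias = TRUE,
                      name = "mlp2"),
    base = conv_block(c, c, k = 5, g = c, act = FALSE, bn = FALSE, bias = TRUE,
                      name = "base5")
  )
  for (i in seq_along(kernels)) {
    k <- kernels[i]
    ch[[paste0("dh", i)]] <- conv_block(c, c, k = c(1L, k), g = c, act = FALSE,
                                        bn = FALSE, bias = TRUE,
                                        name = paste0("d", k, "h"))
    ch[[paste0("dv", i)]] <- conv_block(c, c, k = c(k, 1L), g = c, act = FALSE,
                                        bn = FALSE, bias = TRUE,
                                        name = paste0("d", k, "v"))
  }
  ch$proj <- conv_block(c, c, k = 1, act = FALSE, bn = FALSE, bias = TRUE,
                        name = "proj")
  new_module("mecs", name, ch = ch,
             hyper = list(c = c, r = r, kernels = kernels,
                          n_branches = length(kernels)))
}

#' Global pooling statistics of a feature map
#'
#' Average, maximum and median over all `H*W` positions of each channel.
#' For an even pixel count the median is the mean of the two middle order
#' statistics.
#'
#' @param x feature map `(batch, channel, row, col)` (array or tensor).
#' @return list with elements `avg`, `max`, `median`, each a tensor of shape
#'   `(batch, channel, 1, 1)` (plain arrays if `x` was a plain array).
#' @export
global_pool_stats <- function(x) {
  plain <- !inherits(x, "bgm_tensor") && !is_shape(x)
  xt <- tz(x)
  out <- list(avg = t_gpool(xt, "avg"), max = t_gpool(xt, "max"),
              median = t_gpool(xt, "median"))
  if (plain) lapply(out, tz_value) else out
}

#' Channel attention gate of an MECS block
#'
#' Computes `Fc = sigma(MLP(avg)) + sigma(MLP(max)) + sigma(MLP(median))`
#' with one shared MLP, so every entry lies strictly in `(0, n_stats)`.
#'
#' @param m an [mecs_block()].
#' @param x feature map with `cfg$c` channels.
#' @param stats which pooled statistics to use; the default is the full
#'   three-branch gate. `c("avg", "max")` degrades the block to a
#'   CBAM-style gate bounded in (0, 2).
#' @return tensor `(batch, C, 1, 1)`, broadcastable over `x`.
#' @export
channel_attention <- function(m, x, stats = c("avg", "max", "median")) {
  x <- tz(x)
  pooled <- global_pool_stats(x)[stats]
  branches <- lapply(pooled, function(p) {
    t_sigmoid(forward(m$ch$mlp2, t_relu(forward(m$ch$mlp1, p))))
  })
  Reduce(t_add, branches)
}

#' Apply a channel gate to a feature map
#'
#' Elementwise (broadcast) product `F' = Fc (*) F`.
#'
#' @param x feature map.
#' @param fc channel gate from [channel_attention()].
#' @return gated feature map.
#' @export
apply_channel <- function(x, fc) t_mul(tz(x), tz(fc))

#' Spatial attention stage of an MECS block
#'
#' 5x5 depthwise base conv; multi-scale separable depthwise branches applied
#' to the base output; base and branch outputs summed; 1x1 projection; the
#' projected map multiplies the input. Shape preserving.
#'
#' @param m an [mecs_block()].
#' @param x channel-weighted feature map `F'`.
#' @return output feature map `F''` of the same shape.
#' @export
spatial_attention <- function(m, x) {
  x <- tz(x)
  base <- forward(m$ch$base, x)
  acc <- base
  for (i in seq_len(m$hyper$n_branches)) {
    bi <- forward(m$ch[[paste0("dv", i)]],
                  forward(m$ch[[paste0("dh", i)]], base))
    acc <- t_add(acc, bi)
  }
  t_mul(forward(m$ch$proj, acc), x)
}

#' Full MECS forward pass
#'
#' `F'' = spatial_attention(channel_attention(F) (*) F)`; shape preserving.
#'
#' @param m an [mecs_block()].
#' @param x input feature map with `m$hyper$c` channels.
#' @return attended feature map of the same shape.
#' @export
mecs_forward <- function(m, x) forward(m, x)

#' @export
forward.mod_mecs <- function(m, x, ...) {
  prof_push(m$name)
  fc <- channel_attention(m, x)
  y <- spatial_attention(m, apply_channel(x, fc))
  prof_pop()
  y
}
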