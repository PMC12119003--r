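# Multi-scale feature fusion with softmax-normalized channel and spatial
# weights (BFM). Two same-shape feature maps are each passed through shared
# multi-scale convolutions (3x3, 5x5, 7x7, summed); channel descriptors
# (global avg / max / std / min pooling, concatenated, projected by a shared
# 1x1 conv) and spatial descriptors (channel-wise avg and max maps through a
# shared 2-D conv) yield per-channel and per-pixel logits for each input.
# A two-way softmax across the input axis guarantees the weights of the two
# inputs sum to one per channel and per pixel; the output is
# `y = ws1*wc1*t1 + ws2*wc2*t2`. All weight paths are shared between the two
# inputs, so fusing a map with itself yields weights of exactly 0.5.

#' BFM fusion block constructor
#'
#' @param c channel count of the two maps to fuse.
#' @param ms_kernels kernel sizes of the multi-scale extraction convs.
#' @param ms_groupw channels per group of the multi-scale convs (1 =
#'   depthwise); a width knob for the block's capacity.
#' @param spatial_k kernel size of the shared spatial-weight conv.
#' @param desc_hidden hidden width of the channel-descriptor projection as a
#'   multiple of `c`; 0 uses a single `4C -> C` conv, otherwise
#'   `4C -> desc_hidden*C -> C` with a ReLU between.
#' @param name block name used in profiler reports.
#' @return a module; apply with [forward()] on `list(t1, t2)` or use
#'   [bfm_fuse()].
#' @export
bfm_block <- function(c, ms_kernels = c(3, 5, 7), ms_groupw = 1L,
                      spatial_k = 7L, desc_hidden = 0, name = "bfm") {
  stopifnot(c %% ms_groupw == 0)
  ch <- list()
  for (k in ms_kernels) {
    ch[[paste0("ms", k)]] <- conv_block(c, c, k = k, g = c %/% ms_groupw,
                                        act = FALSE, bn = FALSE, bias = TRUE,
                                        name = paste0("ms", k))
  }
  if (desc_hidden > 0) {
    hid <- max(1L, as.integer(round(desc_hidden * c)))
    ch$desc1 <- conv_block(4L * c, hid, k = 1, act = FALSE, bn = FALSE,
                           bias = TRUE, name = "desc1")
    ch$desc <- conv_block(hid, c, k = 1, act = FALSE, bn = FALSE, bias = TRUE,
                          name = "desc2")
  } else {
    ch$desc <- conv_block(4L * c, c, k = 1, act = FALSE, bn = FALSE,
                          bias = TRUE, name = "desc")
  }
  ch$spw <- conv_block(2L, 1L, k = spatial_k, act = FALSE, bn = FALSE,
                       bias = TRUE, name = "spw")
  new_module("bfm", name, ch = ch,
             hyper = list(c = c, ms_kernels = ms_kernels,
                          ms_groupw = ms_groupw, spatial_k = spatial_k,
                          desc_hidden = desc_hidden))
}

#' Multi-scale feature extraction of a BFM block
#'
#' Applies the block's same-padded 3x3/5x5/7x7 convolutions and combines the
#' results by elementwise sum, preserving shape and channel count.
#'
#' @param m a [bfm_block()].
#' @param x feature map with `m$hyper$c` channels.
#' @return feature map of the same shape.
#' @export
multiscale_features <- function(m, x) {
  x <- tz(x)
  outs <- lapply(m$hyper$ms_kernels, function(k) {
    forward(m$ch[[paste0("ms", k)]], x)
  })
  Reduce(t_add, outs)
}

#' Channel descriptor of a BFM block
#'
#' Global average, max, standard-deviation (population convention) and
#' minimum pooling of each channel, concatenated to a `4C` vector and
#' projected by the block's shared 1x1 conv to a length-`C` descriptor.
#'
#' @param m a [bfm_block()].
#' @param x feature map.
#' @return tensor of shape `(batch, C, 1, 1)`.
#' @export
channel_descriptor <- function(m, x) {
  x <- tz(x)
  avg <- t_gpool(x, "avg")
  mx <- t_gpool(x, "max")
  mn <- t_scale(t_gpool(t_scale(x, -1), "max"), -1)
  ex2 <- t_gpool(t_mul(x, x), "avg")
  sd_ <- t_sqrt(t_relu(t_sub(ex2, t_mul(avg, avg))), eps = 1e-12)
  st <- t_concat_c(list(avg, mx, sd_, mn))
  if (!is.null(m$ch$desc1)) st <- t_relu(forward(m$ch$desc1, st))
  forward(m$ch$desc, st)
}

spatial_logits <- function(m, x) {
  x <- tz(x)
  forward(m$ch$spw, t_concat_c(list(t_cpool(x, "avg"), t_cpool(x, "max"))))
}

#' Fuse two same-shape feature maps with a BFM block
#'
#' @param m a [bfm_block()].
#' @param t1,t2 feature maps of identical shape (channel count `m$hyper$c`).
#' @param return_weights also return the channel/spatial weight tensors.
#' @return fused feature map of the same shape; if `return_weights`, a list
#'   `(y, wc1, wc2, ws1, ws2)` where `wc1 + wc2 = 1` per channel and
#'   `ws1 + ws2 = 1` per pixel.
#' @export
bfm_fuse <- function(m, t1, t2, return_weights = FALSE) {
  t1 <- tz(t1); t2 <- tz(t2)
  if (!identical(tshape(t1), tshape(t2))) {
    stop("bfm_fuse: inputs must have identical shape")
  }
  m1 <- multiscale_features(m, t1)
  m2 <- multiscale_features(m, t2)
  d1 <- channel_descriptor(m, m1)
  d2 <- channel_descriptor(m, m2)
  # two-way softmax across the input axis == sigmoid of the logit difference
  wc1 <- t_sigmoid(t_sub(d1, d2))
  wc2 <- t_sub(tz(array(1, dim = tshape(wc1) * 0 + 1)), wc1)
  if (is_shape(t1)) wc2 <- wc1
  s1 <- spatial_logits(m, m1)
  s2 <- spatial_logits(m, m2)
  ws1 <- t_sigmoid(t_sub(s1, s2))
  ws2 <- t_sub(tz(array(1, dim = tshape(ws1) * 0 + 1)), ws1)
  if (is_shape(t1)) ws2 <- ws1
  y <- t_add(t_mul(t_mul(ws1, wc1), t1), t_mul(t_mul(ws2, wc2), t2))
  if (return_weights) list(y = y, wc1 = wc1, wc2 = wc2, ws1 = ws1, ws2 = ws2)
  else y
}

#' @export
forward.mod_bfm <- function(m, x, ...) {
  prof_push(m$name)
  y <- bfm_fuse(m, x[[1]], x[[2]])
  prof_pop()
  y
}

# A neck fusion node: project the top-down (deep) input to the fused width
# with a 1x1 conv-BN-SiLU block; the lateral input is likewise projected
# when it is a raw backbone feature (align_lat = TRUE), or enters directly
# when it is already a neck output at the fused width. Then BFM-fuse.
bfm_node_block <- function(c_deep, c_lat, c_out, ms_groupw = 1L,
                           desc_hidden = 0, align_lat = TRUE,
                           name = "bfmnode") {
  if (!align_lat && c_lat != c_out) {
    stop("bfm_node: lateral width must equal the fused width when not aligned")
  }
  ch <- list(align_a = conv_block(c_deep, c_out, k = 1, name = "align_a"))
  if (align_lat) ch$align_b <- conv_block(c_lat, c_out, k = 1, name = "align_b")
  ch$fuse <- bfm_block(c_out, ms_groupw = ms_groupw, desc_hidden = desc_hidden,
                       name = "fuse")
  new_module("bfm_node", name, ch = ch,
             hyper = list(c_out = c_out, align_lat = align_lat))
}

#' @export
forward.mod_bfm_node <- function(m, x, ...) {
  prof_push(m$name)
  a <- forward(m$ch$align_a, x[[1]], ...)
  b <- if (isTRUE(m$hyper$align_lat)) forward(m$ch$align_b, x[[2]], ...)
       else x[[2]]
  y <- bfm_fuse(m$ch$fuse, a, b)
  prof_pop()
  y
}
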