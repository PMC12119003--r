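# Module objects: plain lists carrying parameter environments and children,
# with S3 forward() methods. Every convolution is conv -> batch norm -> SiLU
# unless stated otherwise, matching the YOLOv8 family convention.

new_module <- function(type, name, prm = list(), ch = list(), hyper = list(),
                       bufs = list()) {
  structure(list(type = type, name = name, prm = prm, ch = ch,
                 hyper = hyper, bufs = bufs),
            class = c(paste0("mod_", type), "bgm_module"))
}

#' Apply a module to an input tensor
#' @param m module object.
#' @param x input tensor (see [tz()]), or a list of tensors for fusion blocks.
#' @param ... passed through.
#' @return output tensor.
#' @export
forward <- function(m, x, ...) UseMethod("forward")

#' Number of trainable parameters in a module
#' @param m module object.
#' @return integer count of trainable scalars.
#' @export
n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$v), numeric(1)))
}

#' Collect the parameter environments of a module tree
#' @param m module object.
#' @param prefix internal: path prefix for unique names.
#' @return named list of parameter environments, keyed by module path.
#' @export
collect_params <- function(m, prefix = "") {
  path <- paste0(prefix, m$name)
  out <- list()
  if (length(m$prm)) {
    out <- stats::setNames(m$prm, paste(path, names(m$prm), sep = "."))
  }
  for (ch in m$ch) {
    if (inherits(ch, "bgm_module")) {
      out <- c(out, collect_params(ch, paste0(path, "/")))
    }
  }
  out
}

# Running-statistic buffers (batch-norm), keyed like collect_params.
collect_buffers <- function(m, prefix = "") {
  path <- paste0(prefix, m$name)
  out <- list()
  if (length(m$bufs)) {
    out <- stats::setNames(m$bufs, paste(path, names(m$bufs), sep = "."))
  }
  for (ch in m$ch) {
    if (inherits(ch, "bgm_module")) {
      out <- c(out, collect_buffers(ch, paste0(path, "/")))
    }
  }
  out
}

kaiming <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

autopad <- function(k) as.integer(floor(k / 2))

# Conv -> BN -> SiLU building block. k may be a scalar or c(kh, kw).
conv_block <- function(c1, c2, k = 1, s = 1, g = 1, act = TRUE, bn = TRUE,
                       bias = !bn, p = NULL, name = "conv", bias_init = 0) {
  k <- if (length(k) == 1) c(k, k) else as.integer(k)
  p <- if (is.null(p)) autopad(k) else as.integer(rep(p, length.out = 2))
  cg <- c1 %/% g
  prm <- list(w = new_param(kaiming(c(c2, cg, k[1], k[2]), cg * k[1] * k[2])))
  if (bias) prm$b <- new_param(array(bias_init, dim = c2))
  bufs <- list()
  if (bn) {
    prm$gamma <- new_param(array(1, dim = c(1L, c2, 1L, 1L)))
    prm$beta <- new_param(array(0, dim = c(1L, c2, 1L, 1L)))
    st <- new.env(parent = emptyenv())
    st$rm <- array(0, dim = c(1L, c2, 1L, 1L))
    st$rv <- array(1, dim = c(1L, c2, 1L, 1L))
    bufs$stats <- st
  }
  new_module("conv", name, prm = prm, bufs = bufs,
             hyper = list(c1 = c1, c2 = c2, k = k, s = as.integer(rep(s, 2)),
                          p = p, g = g, act = act, bn = bn))
}

#' @export
forward.mod_conv <- function(m, x, ...) {
  h <- m$hyper
  y <- t_conv2d(x, m$prm$w, m$prm[["b"]], stride = h$s, pad = h$p,
                groups = h$g, name = m$name)
  if (h$bn) {
    y <- t_bn(y, m$prm$gamma, m$prm$beta, m$bufs$stats,
              name = paste0(m$name, ".bn"))
  }
  if (isTRUE(h$act)) y <- t_silu(y)
  y
}

seq_block <- function(children, name = "seq") {
  new_module("seq", name, ch = children)
}

#' @export
forward.mod_seq <- function(m, x, ...) {
  prof_push(m$name)
  for (ch in m$ch) x <- forward(ch, x, ...)
  prof_pop()
  x
}

# ---- channel shuffle --------------------------------------------------------

shuffle_perm <- function(C, groups) {
  if (C %% groups != 0) {
    stop("channel_shuffle: groups (", groups, ") does not divide channels (", C, ")")
  }
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

#' Channel shuffle
#'
#' Permutes the channel planes of a feature map by the reshape-to
#' `(groups, C/groups)`, transpose, flatten rule, mixing information between
#' grouped-convolution branches. Each output plane is an exact copy of one
#' input plane; spatial dimensions are untouched.
#'
#' @param x feature map: numeric array `(batch, channel, row, col)` or tensor.
#' @param groups integer number of groups; must divide the channel count.
#' @return feature map of the same type and shape as `x`.
#' @examples
#' x <- array(rep(1:4, each = 4), dim = c(1, 4, 2, 2))
#' y <- channel_shuffle(x, 2)  # plane order becomes 1, 3, 2, 4
#' @export
channel_shuffle <- function(x, groups) {
  plain <- !inherits(x, "bgm_tensor") && !is_shape(x)
  xt <- tz(x)
  C <- tshape(xt)[2]
  y <- t_take(xt, shuffle_perm(C, groups), axis = 2L)
  if (plain) tz_value(y) else y
}

# ---- GSConv family ----------------------------------------------------------

#' GSConv block constructor
#'
#' Hybrid of standard and depthwise-separable convolution: a standard
#' convolution maps `c1` to `c2/2` channels (with the requested stride), a
#' depthwise convolution of the same kernel size refines that output at
#' stride 1, the two halves are concatenated to `c2` channels, and a
#' channel shuffle with 2 groups mixes the branches.
#'
#' @param c1,c2 input/output channel counts; `c2` must be even.
#' @param k kernel size (both branches).
#' @param s stride of the standard-convolution branch.
#' @param act apply SiLU activations (default TRUE).
#' @param bn apply batch normalization (default TRUE).
#' @param bias add convolution biases (default `!bn`).
#' @param name block name used in profiler reports.
#' @return a module; apply with [forward()].
#' @export
gs_conv_block <- function(c1, c2, k = 3, s = 1, act = TRUE, bn = TRUE,
                          bias = !bn, name = "gsconv") {
  if (c2 %% 2 != 0) stop("gs_conv: output channels must be even, got ", c2)
  ch <- c2 %/% 2L
  new_module("gs_conv", name, ch = list(
    sc = conv_block(c1, ch, k = k, s = s, act = act, bn = bn, bias = bias,
                    name = "sc"),
    dw = conv_block(ch, ch, k = k, s = 1, g = ch, act = act, bn = bn,
                    bias = bias, name = "dw")
  ), hyper = list(c1 = c1, c2 = c2, k = k, s = s))
}

#' @export
forward.mod_gs_conv <- function(m, x, ...) {
  prof_push(m$name)
  a <- forward(m$ch$sc, x, ...)
  b <- forward(m$ch$dw, a, ...)
  y <- channel_shuffle(t_concat_c(list(a, b)), 2L)
  prof_pop()
  y
}

#' GSBottleneck block constructor
#'
#' Two stacked GSConv blocks, `c -> c*e -> c`, with an identity shortcut
#' added when input and output shapes match. Channel count is preserved.
#'
#' @param c channel count (preserved).
#' @param e hidden width ratio of the first GSConv (default 0.5).
#' @param shortcut add the identity shortcut (default TRUE).
#' @param name block name.
#' @return a module.
#' @export
gs_bottleneck_block <- function(c, e = 0.5, shortcut = TRUE, name = "gsb") {
  ch <- max(2L, 2L * as.integer(round(c * e / 2)))
  new_module("gs_bottleneck", name, ch = list(
    g1 = gs_conv_block(c, ch, k = 3, name = "g1"),
    g2 = gs_conv_block(ch, c, k = 3, name = "g2")
  ), hyper = list(c = c, shortcut = shortcut))
}

#' @export
forward.mod_gs_bottleneck <- function(m, x, ...) {
  prof_push(m$name)
  y <- forward(m$ch$g2, forward(m$ch$g1, x, ...), ...)
  if (isTRUE(m$hyper$shortcut)) y <- t_add(y, x)
  prof_pop()
  y
}

# Standard YOLO bottleneck: two 3x3 convs with optional residual.
bottleneck_block <- function(c, shortcut = TRUE, name = "bneck") {
  new_module("bottleneck", name, ch = list(
    cv1 = conv_block(c, c, k = 3, name = "cv1"),
    cv2 = conv_block(c, c, k = 3, name = "cv2")
  ), hyper = list(shortcut = shortcut))
}

#' @export
forward.mod_bottleneck <- function(m, x, ...) {
  prof_push(m$name)
  y <- forward(m$ch$cv2, forward(m$ch$cv1, x, ...), ...)
  if (isTRUE(m$hyper$shortcut)) y <- t_add(y, x)
  prof_pop()
  y
}

#' C2f / GSC2f block constructor
#'
#' CSP-style block: a 1x1 conv to `2*c_h` channels, split into two halves,
#' `n` bottlenecks chained on the second half, concatenation of both halves
#' and every intermediate, and a final 1x1 projection to `c2`. With
#' `gs = TRUE` the bottlenecks are [gs_bottleneck_block()]s (the GSC2f
#' variant); otherwise standard bottlenecks.
#'
#' @param c1,c2 input/output channels.
#' @param n number of bottlenecks (>= 1).
#' @param shortcut residual connections inside the bottlenecks.
#' @param gs substitute GSBottlenecks (GSC2f) for standard bottlenecks.
#' @param gsb_e hidden ratio passed to [gs_bottleneck_block()].
#' @param name block name.
#' @return a module.
#' @export
c2f_block <- function(c1, c2, n = 1, shortcut = FALSE, gs = FALSE,
                      gsb_e = 0.5, name = "c2f") {
  stopifnot(n >= 1)
  ch <- c2 %/% 2L
  mk <- function(i) {
    if (gs) gs_bottleneck_block(ch, e = gsb_e, shortcut = shortcut,
                                name = paste0("m", i))
    else bottleneck_block(ch, shortcut = shortcut, name = paste0("m", i))
  }
  new_module("c2f", name, ch = c(list(
    cv1 = conv_block(c1, 2L * ch, k = 1, name = "cv1"),
    cv2 = conv_block((2L + n) * ch, c2, k = 1, name = "cv2")
  ), stats::setNames(lapply(seq_len(n), mk), paste0("m", seq_len(n)))),
  hyper = list(c1 = c1, c2 = c2, n = n, ch = ch, gs = gs))
}

#' @export
forward.mod_c2f <- function(m, x, ...) {
  prof_push(m$name)
  h <- m$hyper
  y0 <- forward(m$ch$cv1, x, ...)
  a <- t_slice_c(y0, seq_len(h$ch))
  b <- t_slice_c(y0, h$ch + seq_len(h$ch))
  ys <- list(a, b)
  cur <- b
  for (i in seq_len(h$n)) {
    cur <- forward(m$ch[[paste0("m", i)]], cur, ...)
    ys <- c(ys, list(cur))
  }
  y <- forward(m$ch$cv2, t_concat_c(ys), ...)
  prof_pop()
  y
}

# SPPF: 1x1 reduce, three chained 5x5 stride-1 max pools, concat, 1x1.
sppf_block <- function(c1, c2, k = 5, name = "sppf") {
  ch <- c1 %/% 2L
  new_module("sppf", name, ch = list(
    cv1 = conv_block(c1, ch, k = 1, name = "cv1"),
    cv2 = conv_block(ch * 4L, c2, k = 1, name = "cv2")
  ), hyper = list(k = k))
}

#' @export
forward.mod_sppf <- function(m, x, ...) {
  prof_push(m$name)
  k <- m$hyper$k
  y <- forward(m$ch$cv1, x, ...)
  p1 <- t_maxpool(y, k, 1L, autopad(k))
  p2 <- t_maxpool(p1, k, 1L, autopad(k))
  p3 <- t_maxpool(p2, k, 1L, autopad(k))
  out <- forward(m$ch$cv2, t_concat_c(list(y, p1, p2, p3)), ...)
  prof_pop()
  out
}

# Nearest-neighbour 2x upsample as a (parameter-free) module.
upsample_block <- function(name = "up") new_module("upsample", name)

#' @export
forward.mod_upsample <- function(m, x, ...) t_upsample2(x)
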