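# Minimal reverse-mode autodiff over dense NCHW arrays.
#
# Two tensor flavours flow through the same op functions:
#   * numeric tensors (class "bgm_tensor"): value + optional tape node id;
#   * shape tensors  (class "bgm_shape"): dims only. Ops propagate output
#     dims and log parameter/FLOP costs to the active profile collector,
#     so the profiler measures exactly the graph the forward pass runs.
#
# The FLOP convention for a convolution is 2*Ho*Wo*(Cg*Kh*Kw + 1)*Cout
# (two ops per multiply-accumulate plus one per output element), and
# (2I - 1)*O for a fully connected layer; normalization and activation
# layers are costed at zero. See the methods vignette for rationale.

.bgm <- new.env(parent = emptyenv())
.bgm$tape <- NULL
.bgm$profile <- NULL
.bgm$training <- FALSE

`%||%` <- function(a, b) if (is.null(a)) b else a

is_shape <- function(x) inherits(x, "bgm_shape")

new_tensor <- function(v, id = NA_integer_) {
  structure(list(v = v, id = id), class = "bgm_tensor")
}

#' Wrap an array as a constant tensor
#'
#' Coerces a numeric array (or a shape descriptor) into the tensor type used
#' by the block-level forward functions. Constants do not receive gradients.
#'
#' @param v numeric array, typically with `dim = c(batch, channel, row, col)`.
#' @return a tensor object.
#' @export
tz <- function(v) {
  if (inherits(v, "bgm_tensor") || is_shape(v)) return(v)
  if (is.null(dim(v))) v <- array(v, dim = length(v))
  new_tensor(v)
}

#' Shape-only tensor for profiling passes
#' @param dims integer dims, e.g. `c(1, 3, 640, 640)`.
#' @return a shape tensor.
#' @export
tz_shape <- function(dims) structure(list(shape = as.integer(dims)), class = "bgm_shape")

#' Extract the numeric value of a tensor
#' @param x tensor.
#' @return the underlying array.
#' @export
tz_value <- function(x) if (inherits(x, "bgm_tensor")) x$v else x

tshape <- function(x) if (is_shape(x)) x$shape else dim(x$v)

# ---- tape ------------------------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

with_tape <- function(expr) {
  old <- .bgm$tape
  .bgm$tape <- new_tape()
  on.exit(.bgm$tape <- old)
  force(expr)
}

t_node <- function(v, parents, bw = NULL, sink = NULL) {
  tp <- .bgm$tape
  if (is.null(tp)) return(new_tensor(v))
  id <- tp$n + 1L
  tp$n <- id
  tp$nodes[[id]] <- list(parents = parents, bw = bw, sink = sink)
  new_tensor(v, id)
}

pid <- function(x) if (inherits(x, "bgm_tensor")) x$id else NA_integer_

# Parameters are environments so in-place SGD updates persist inside the
# module tree: fields v (value), grad, m (momentum buffer).
new_param <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$grad <- NULL
  p$m <- NULL
  .bgm$uid <- (.bgm$uid %||% 0L) + 1L
  p$.uid <- .bgm$uid
  p
}

# Parameters of modules applied more than once in a forward pass (shared
# weight paths) are costed once; repeated applications log params = 0 but
# still log their FLOPs.
prof_params_once <- function(pr, key, params) {
  if (is.null(pr)) return(params)
  k <- as.character(key)
  if (!is.null(pr$seen[[k]])) return(0)
  pr$seen[[k]] <- TRUE
  params
}

t_param <- function(p) {
  tp <- .bgm$tape
  if (is.null(tp)) return(new_tensor(p$v))
  if (!identical(p$.tape, tp)) {
    t0 <- t_node(p$v, integer(0), sink = function(g) {
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    })
    p$.tape <- tp
    p$.tid <- t0$id
  }
  new_tensor(p$v, p$.tid)
}

#' Run reverse-mode backpropagation from a scalar loss tensor
#'
#' Accumulates gradients into the parameter environments that participated in
#' the recorded forward pass.
#'
#' @param loss scalar tensor recorded on the active tape.
#' @export
tz_backward <- function(loss) {
  tp <- .bgm$tape
  if (is.null(tp) || is.na(loss$id)) stop("no active tape / loss not recorded")
  grads <- vector("list", loss$id)
  g0 <- array(1, dim = dim(loss$v) %||% 1L)
  grads[[loss$id]] <- g0
  for (id in seq.int(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (!is.null(nd$sink)) nd$sink(g)
    if (length(nd$parents) && !is.null(nd$bw)) {
      pg <- nd$bw(g)
      for (j in seq_along(nd$parents)) {
        p <- nd$parents[j]
        if (is.na(p) || is.null(pg[[j]])) next
        grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
      }
    }
    grads[id] <- list(NULL)
  }
  invisible(NULL)
}

# ---- profiling collector ----------------------------------------------------

prof_start <- function() {
  pr <- new.env(parent = emptyenv())
  pr$records <- list()
  pr$stack <- character(0)
  pr$seen <- new.env(parent = emptyenv())
  .bgm$profile <- pr
  pr
}

prof_stop <- function() .bgm$profile <- NULL

prof_push <- function(name) {
  pr <- .bgm$profile
  if (!is.null(pr)) pr$stack <- c(pr$stack, name)
}

prof_pop <- function() {
  pr <- .bgm$profile
  if (!is.null(pr)) pr$stack <- pr$stack[-length(pr$stack)]
}

prof_log <- function(name, type, params, flops) {
  pr <- .bgm$profile
  if (is.null(pr)) return(invisible(NULL))
  full <- paste(c(pr$stack, name), collapse = "/")
  pr$records[[length(pr$records) + 1L]] <-
    list(name = full, type = type, params = params, flops = flops)
  invisible(NULL)
}

# ---- elementwise / broadcast ops -------------------------------------------

bcast <- function(a, b, op) cpp_bcast_bin(a, b, dim(a), dim(b), op)
sum_to <- function(g, dims) {
  if (identical(dim(g), as.integer(dims))) g else cpp_sum_to(g, dim(g), as.integer(dims))
}

t_bin <- function(a, b, op) {
  a <- tz(a); b <- tz(b)
  if (is_shape(a) || is_shape(b)) {
    da <- tshape(a); db <- tshape(b)
    return(tz_shape(pmax(da, db)))
  }
  v <- bcast(a$v, b$v, op)
  da <- dim(a$v); db <- dim(b$v)
  av <- a$v; bv <- b$v
  bw <- switch(as.character(op),
    "0" = function(g) list(sum_to(g, da), sum_to(g, db)),
    "1" = function(g) list(sum_to(g, da), -sum_to(g, db)),
    "2" = function(g) list(sum_to(bcast(g, bv, 2L), da), sum_to(bcast(g, av, 2L), db)),
    "3" = function(g) list(
      sum_to(bcast(g, bv, 3L), da),
      -sum_to(bcast(bcast(g, av, 2L), bcast(bv, bv, 2L), 3L), db)
    )
  )
  t_node(v, c(pid(a), pid(b)), bw)
}

t_add <- function(a, b) t_bin(a, b, 0L)
t_sub <- function(a, b) t_bin(a, b, 1L)
t_mul <- function(a, b) t_bin(a, b, 2L)
t_div <- function(a, b) t_bin(a, b, 3L)

t_scale <- function(x, k) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  v <- x$v * k
  t_node(v, pid(x), function(g) list(g * k))
}

t_shift <- function(x, k) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  t_node(x$v + k, pid(x), function(g) list(g))
}

t_sigmoid <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  s <- 1 / (1 + exp(-x$v))
  t_node(s, pid(x), function(g) list(g * s * (1 - s)))
}

t_silu <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  s <- 1 / (1 + exp(-x$v))
  v <- x$v * s
  xv <- x$v
  t_node(v, pid(x), function(g) list(g * (s * (1 + xv * (1 - s)))))
}

t_relu <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  m <- x$v > 0
  t_node(x$v * m, pid(x), function(g) list(g * m))
}

t_exp <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  v <- exp(x$v)
  t_node(v, pid(x), function(g) list(g * v))
}

t_sqrt <- function(x, eps = 0) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  v <- sqrt(x$v + eps)
  t_node(v, pid(x), function(g) list(g / (2 * v)))
}

t_reshape <- function(x, dims) {
  x <- tz(x)
  dims <- as.integer(dims)
  if (is_shape(x)) return(tz_shape(dims))
  od <- dim(x$v)
  v <- x$v
  dim(v) <- dims
  t_node(v, pid(x), function(g) { dim(g) <- od; list(g) })
}

# ---- convolution, pooling, resize ------------------------------------------

conv_out_hw <- function(hw, k, s, p) c((hw[1] + 2 * p[1] - k[1]) %/% s[1] + 1L,
                                       (hw[2] + 2 * p[2] - k[2]) %/% s[2] + 1L)

# w, b are parameter environments (b may be NULL).
t_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                     groups = 1L, name = "conv") {
  x <- tz(x)
  wd <- dim(w$v)
  if (is_shape(x)) {
    sh <- tshape(x)
    ohw <- conv_out_hw(sh[3:4], wd[3:4], stride, pad)
    cout <- wd[1]
    flops <- 2 * prod(ohw) * (wd[2] * wd[3] * wd[4] + 1) * cout * sh[1]
    params <- length(w$v) + if (!is.null(b)) length(b$v) else 0L
    params <- prof_params_once(.bgm$profile, w$.uid, params)
    prof_log(name, "conv", params, flops)
    return(tz_shape(c(sh[1], cout, ohw)))
  }
  wt <- t_param(w)
  bt <- if (!is.null(b)) t_param(b)
  v <- cpp_conv2d(x$v, wt$v, if (!is.null(bt)) bt$v else NULL,
                  stride[1], stride[2], pad[1], pad[2], groups)
  xv <- x$v; wv <- wt$v
  has_b <- !is.null(bt)
  bw <- function(g) {
    r <- cpp_conv2d_backward(xv, wv, g, has_b,
                             stride[1], stride[2], pad[1], pad[2], groups)
    out <- list(r$dx, r$dw)
    if (has_b) out <- c(out, list(r$db))
    out
  }
  t_node(v, c(pid(x), wt$id, if (has_b) bt$id), bw)
}

t_maxpool <- function(x, k, s, p) {
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x)
    ohw <- conv_out_hw(sh[3:4], c(k, k), c(s, s), c(p, p))
    return(tz_shape(c(sh[1:2], ohw)))
  }
  r <- cpp_maxpool2d(x$v, k, s, p)
  xd <- dim(x$v)
  t_node(r$y, pid(x), function(g) list(cpp_maxpool2d_backward(g, r$idx, xd)))
}

t_upsample2 <- function(x) {
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x)
    return(tz_shape(c(sh[1:2], sh[3] * 2L, sh[4] * 2L)))
  }
  d <- dim(x$v)
  v <- x$v[, , rep(seq_len(d[3]), each = 2), rep(seq_len(d[4]), each = 2), drop = FALSE]
  bw <- function(g) {
    h2 <- seq(1, 2 * d[3], by = 2); w2 <- seq(1, 2 * d[4], by = 2)
    list(g[, , h2, w2, drop = FALSE] + g[, , h2 + 1, w2, drop = FALSE] +
         g[, , h2, w2 + 1, drop = FALSE] + g[, , h2 + 1, w2 + 1, drop = FALSE])
  }
  t_node(v, pid(x), bw)
}

t_concat_c <- function(xs) {
  xs <- lapply(xs, tz)
  if (any(vapply(xs, is_shape, logical(1)))) {
    shs <- lapply(xs, tshape)
    cs <- sum(vapply(shs, function(s) s[2], numeric(1)))
    return(tz_shape(c(shs[[1]][1], cs, shs[[1]][3:4])))
  }
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, function(d) d[2], numeric(1))
  d0 <- ds[[1]]
  out <- array(0, dim = c(d0[1], sum(cs), d0[3], d0[4]))
  at <- 0L
  for (x in xs) {
    dc <- dim(x$v)[2]
    out[, at + seq_len(dc), , ] <- x$v
    at <- at + dc
  }
  offs <- cumsum(c(0, cs))
  bw <- function(g) {
    lapply(seq_along(xs), function(i) {
      g[, offs[i] + seq_len(cs[i]), , , drop = FALSE]
    })
  }
  t_node(out, vapply(xs, pid, integer(1)), bw)
}

t_slice_c <- function(x, idx) {
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x)
    return(tz_shape(c(sh[1], length(idx), sh[3:4])))
  }
  d <- dim(x$v)
  v <- x$v[, idx, , , drop = FALSE]
  bw <- function(g) {
    gx <- array(0, dim = d)
    gx[, idx, , ] <- g
    list(gx)
  }
  t_node(v, pid(x), bw)
}

# Global pooling over (H, W) per (batch, channel) -> (N, C, 1, 1).
# stat: "avg", "max", "median". For even H*W the median is the mean of the
# two middle order statistics; its gradient is split between them.
t_gpool <- function(x, stat = c("avg", "max", "median")) {
  stat <- match.arg(stat)
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x)
    return(tz_shape(c(sh[1:2], 1L, 1L)))
  }
  d <- dim(x$v)
  n <- d[1] * d[2]; m <- d[3] * d[4]
  M <- matrix(x$v, nrow = n)  # rows: (batch, channel) pairs, cols: pixels
  if (stat == "avg") {
    v <- array(rowMeans(M), dim = c(d[1], d[2], 1L, 1L))
    bw <- function(g) {
      gm <- matrix(g, nrow = n)[, 1] / m
      list(array(rep(gm, m), dim = d))
    }
  } else if (stat == "max") {
    j <- max.col(M, ties.method = "first")
    v <- array(M[cbind(seq_len(n), j)], dim = c(d[1], d[2], 1L, 1L))
    bw <- function(g) {
      G <- matrix(0, nrow = n, ncol = m)
      G[cbind(seq_len(n), j)] <- matrix(g, nrow = n)[, 1]
      gx <- G; dim(gx) <- d
      list(gx)
    }
  } else {
    od <- t(apply(M, 1, order))
    if (m %% 2 == 1) {
      jmid <- od[, (m + 1) / 2, drop = FALSE]
      wmid <- 1
    } else {
      jmid <- od[, c(m / 2, m / 2 + 1), drop = FALSE]
      wmid <- 0.5
    }
    vals <- rowMeans(matrix(M[cbind(rep(seq_len(n), ncol(jmid)), as.vector(jmid))],
                            nrow = n))
    v <- array(vals, dim = c(d[1], d[2], 1L, 1L))
    bw <- function(g) {
      G <- matrix(0, nrow = n, ncol = m)
      gv <- matrix(g, nrow = n)[, 1]
      for (k in seq_len(ncol(jmid))) {
        G[cbind(seq_len(n), jmid[, k])] <- G[cbind(seq_len(n), jmid[, k])] + gv * wmid
      }
      gx <- G; dim(gx) <- d
      list(gx)
    }
  }
  t_node(v, pid(x), bw)
}

# Pooling over the channel axis -> (N, 1, H, W). stat: "avg" or "max".
t_cpool <- function(x, stat = c("avg", "max")) {
  stat <- match.arg(stat)
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x)
    return(tz_shape(c(sh[1], 1L, sh[3:4])))
  }
  d <- dim(x$v)
  if (stat == "avg") {
    v <- cpp_sum_to(x$v, d, c(d[1], 1L, d[3], d[4])) / d[2]
    bw <- function(g) list(bcast(g / d[2], array(1, dim = d), 2L))
  } else {
    # argmax over channels
    v <- x$v[, 1, , , drop = FALSE]
    amax <- array(1L, dim = c(d[1], 1L, d[3], d[4]))
    if (d[2] > 1) {
      for (c2 in 2:d[2]) {
        sl <- x$v[, c2, , , drop = FALSE]
        upd <- sl > v
        v[upd] <- sl[upd]
        amax[upd] <- c2
      }
    }
    bw <- function(g) {
      gx <- array(0, dim = d)
      for (c2 in seq_len(d[2])) {
        msk <- amax == c2
        sl <- array(0, dim = c(d[1], 1L, d[3], d[4]))
        sl[msk] <- g[msk]
        gx[, c2, , ] <- sl
      }
      list(gx)
    }
  }
  t_node(v, pid(x), bw)
}

t_mean <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(tz_shape(1L))
  d <- dim(x$v)
  nv <- length(x$v)
  v <- array(mean(x$v), dim = 1L)
  t_node(v, pid(x), function(g) list(array(as.numeric(g)[1] / nv, dim = d)))
}

t_sum_all <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(tz_shape(1L))
  d <- dim(x$v)
  v <- array(sum(x$v), dim = 1L)
  t_node(v, pid(x), function(g) list(array(as.numeric(g)[1], dim = d)))
}

# Softmax along the given axis of an array (numerically stable).
t_softmax <- function(x, axis) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  d <- dim(x$v)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x$v, perm)
  dim(xp) <- c(d[axis], prod(d[-axis]))
  mxv <- apply(xp, 2, max)
  e <- exp(sweep(xp, 2, mxv))
  s <- sweep(e, 2, colSums(e), "/")
  sarr <- array(s, dim = c(d[axis], d[-axis]))
  sarr <- aperm(sarr, order(perm))
  bw <- function(g) {
    gp <- aperm(g, perm); dim(gp) <- dim(s)
    dot <- colSums(gp * s)
    gxp <- s * sweep(gp, 2, dot)
    gx <- array(gxp, dim = c(d[axis], d[-axis]))
    list(aperm(gx, order(perm)))
  }
  t_node(sarr, pid(x), bw)
}

# Select indices along one axis (keeping ndim); backward scatter-adds.
t_take <- function(x, idx, axis) {
  x <- tz(x)
  if (is_shape(x)) {
    sh <- tshape(x); sh[axis] <- length(idx)
    return(tz_shape(sh))
  }
  d <- dim(x$v)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  v <- do.call(`[`, c(list(x$v), args, list(drop = FALSE)))
  bw <- function(g) {
    gx <- array(0, dim = d)
    gx <- do.call(`[<-`, c(list(gx), args, list(value = g)))
    list(gx)
  }
  t_node(v, pid(x), bw)
}

# Detach: value flows, gradient stops.
t_detach <- function(x) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  new_tensor(x$v)
}

t_log <- function(x, eps = 0) {
  x <- tz(x)
  if (is_shape(x)) return(x)
  v <- log(x$v + eps)
  xv <- x$v
  t_node(v, pid(x), function(g) list(g / (xv + eps)))
}

# Sum down to a broadcast-compatible shape (axes with target dim 1 are
# reduced); backward broadcasts the gradient back up.
t_sum_to <- function(x, odims) {
  x <- tz(x)
  odims <- as.integer(odims)
  if (is_shape(x)) return(tz_shape(odims))
  d <- dim(x$v)
  v <- sum_to(x$v, odims)
  t_node(v, pid(x), function(g) list(bcast(g, array(0, dim = d), 0L)))
}

# Binary cross-entropy with logits against constant targets; sum reduction.
# dL/dx = sigmoid(x) - y.
t_bce_logits <- function(x, y) {
  x <- tz(x)
  if (is_shape(x)) return(tz_shape(1L))
  xv <- x$v
  l <- pmax(xv, 0) - xv * y + log1p(exp(-abs(xv)))
  v <- array(sum(l), dim = 1L)
  t_node(v, pid(x), function(g) {
    gs <- as.numeric(g)[1]
    list((1 / (1 + exp(-xv)) - y) * gs)
  })
}

# Complete-IoU loss between predicted and constant target corner boxes.
# pred: (4, P) tensor (x1, y1, x2, y2); gt: (4, P) numeric. Returns the
# per-box loss vector 1 - CIoU as a (1, P) tensor; gradient on pred by
# central finite differences (boxes are few; the loss is piecewise smooth).
ciou_vec <- function(P, G) {
  ix <- pmax(0, pmin(P[3, ], G[3, ]) - pmax(P[1, ], G[1, ]))
  iy <- pmax(0, pmin(P[4, ], G[4, ]) - pmax(P[2, ], G[2, ]))
  inter <- ix * iy
  ap <- pmax(0, P[3, ] - P[1, ]) * pmax(0, P[4, ] - P[2, ])
  ag <- (G[3, ] - G[1, ]) * (G[4, ] - G[2, ])
  un <- ap + ag - inter
  iou <- ifelse(un > 0, inter / un, 0)
  # enclosing box diagonal and center distance
  cw <- pmax(P[3, ], G[3, ]) - pmin(P[1, ], G[1, ])
  chh <- pmax(P[4, ], G[4, ]) - pmin(P[2, ], G[2, ])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- ((P[1, ] + P[3, ]) - (G[1, ] + G[3, ]))^2 / 4 +
    ((P[2, ] + P[4, ]) - (G[2, ] + G[4, ]))^2 / 4
  wp <- pmax(P[3, ] - P[1, ], 1e-9); hp <- pmax(P[4, ] - P[2, ], 1e-9)
  wg <- G[3, ] - G[1, ]; hg <- G[4, ] - G[2, ]
  vv <- (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- vv / (1 - iou + vv + 1e-9)
  iou - rho2 / c2 - alpha * vv
}

t_ciou_loss <- function(pred, gt) {
  pred <- tz(pred)
  if (is_shape(pred)) return(pred)
  Pm <- pred$v
  np <- dim(Pm)[2]
  v <- 1 - ciou_vec(Pm, gt)
  dim(v) <- c(1L, np)
  bw <- function(g) {
    eps <- 1e-3
    gx <- array(0, dim = dim(Pm))
    for (k in 1:4) {
      Pp <- Pm; Pp[k, ] <- Pp[k, ] + eps
      Pn <- Pm; Pn[k, ] <- Pn[k, ] - eps
      dk <- ((1 - ciou_vec(Pp, gt)) - (1 - ciou_vec(Pn, gt))) / (2 * eps)
      gx[k, ] <- as.numeric(g) * dk
    }
    list(gx)
  }
  t_node(v, pid(pred), bw)
}

# Batch normalization over (N, H, W) per channel. gamma/beta are parameter
# environments; rm/rv (running stats) are plain environments updated in
# training mode. Training uses batch statistics with the biased variance.
t_bn <- function(x, gamma, beta, stats, eps = 1e-5, momentum = 0.03,
                 name = "bn") {
  x <- tz(x)
  if (is_shape(x)) {
    params <- prof_params_once(.bgm$profile, gamma$.uid,
                               length(gamma$v) + length(beta$v))
    prof_log(name, "bn", params, 0)
    return(x)
  }
  d <- dim(x$v)
  cd <- c(1L, d[2], 1L, 1L)
  gt <- t_param(gamma); bt <- t_param(beta)
  M <- d[1] * d[3] * d[4]
  if (.bgm$training) {
    mu <- cpp_sum_to(x$v, d, cd) / M
    xc <- bcast(x$v, mu, 1L)
    va <- cpp_sum_to(xc * xc, d, cd) / M
    stats$rm <- (1 - momentum) * stats$rm + momentum * mu
    stats$rv <- (1 - momentum) * stats$rv + momentum * va
  } else {
    mu <- stats$rm
    va <- stats$rv
    xc <- bcast(x$v, mu, 1L)
  }
  sd_ <- sqrt(va + eps)
  xhat <- bcast(xc, sd_, 3L)
  v <- bcast(bcast(xhat, gt$v, 2L), bt$v, 0L)
  training <- .bgm$training
  bw <- function(g) {
    dbeta <- sum_to(g, cd)
    dgamma <- sum_to(g * xhat, cd)
    if (training) {
      mg <- cpp_sum_to(g, d, cd) / M
      mgx <- cpp_sum_to(g * xhat, d, cd) / M
      # inner = g - mean(g) - xhat * mean(g*xhat)
      inner <- bcast(bcast(g, mg, 1L), bcast(xhat, mgx, 2L), 1L)
      dx <- bcast(inner, bcast(gt$v, sd_, 3L), 2L)
    } else {
      dx <- bcast(g, bcast(gt$v, sd_, 3L), 2L)
    }
    list(dx, dgamma, dbeta)
  }
  t_node(v, c(pid(x), gt$id, bt$id), bw)
}
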