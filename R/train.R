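# Desk-scale training: task-aligned assignment, BCE classification loss,
# CIoU + distribution-focal box regression, plain SGD with momentum.
# The published regime (300 epochs, batch 16, SGD lr 1e-4, 640 px) is the
# config default; the smoke profile used by the tests runs a narrow model on
# small images for a few hundred iterations.

#' Training configuration
#'
#' @param epochs training epochs (ignored when `iterations` is given).
#' @param batch_size images per step.
#' @param lr learning rate.
#' @param optimizer `"SGD"` (momentum SGD) is the supported optimizer.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty.
#' @param image_size square input size in pixels (divisible by 32).
#' @param seed RNG seed controlling batching and initialization.
#' @param iterations optional explicit iteration count.
#' @param box_w,cls_w,dfl_w loss-term weights.
#' @param eval_every evaluate on the val split every this many iterations
#'   (0 = never).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 16L, lr = 1e-4,
                         optimizer = "SGD", momentum = 0.9,
                         weight_decay = 0, image_size = 640L, seed = 0L,
                         iterations = NULL, box_w = 7.5, cls_w = 0.5,
                         dfl_w = 1.5, eval_every = 0L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0, image_size %% 32 == 0)
  if (!identical(optimizer, "SGD")) stop("unsupported optimizer: ", optimizer)
  structure(as.list(environment()), class = "train_config")
}

img_resize_nn <- function(img, hw) {
  d <- dim(img)
  if (d[1] == hw[1] && d[2] == hw[2]) return(img)
  ri <- pmin(d[1], pmax(1, round(seq(0.5, d[1] - 0.5, length.out = hw[1]) + 0.5)))
  ci <- pmin(d[2], pmax(1, round(seq(0.5, d[2] - 0.5, length.out = hw[2]) + 0.5)))
  img[ri, ci, , drop = FALSE]
}

load_image_chw <- function(path, size) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  img <- img_resize_nn(img, c(size, size))
  aperm(img, c(3, 1, 2))  # (3, H, W)
}

# Anchor centers (pixels) for the three detection scales.
anchor_grid <- function(size, strides = c(8L, 16L, 32L)) {
  lapply(strides, function(s) {
    n <- size %/% s
    # cell index q (1-based, layout h fastest) -> (row, col)
    gh <- rep(seq_len(n) - 1L, times = n)
    gw <- rep(seq_len(n) - 1L, each = n)
    list(stride = s, n = n,
         cx = (gw + 0.5) * s, cy = (gh + 0.5) * s)
  })
}

# Task-aligned assignment for one image. Returns, per scale, the positive
# cell indices with matched gt index and normalized target scores.
tal_assign <- function(cls_prob, dist_dec, anchors, gt, nc,
                       topk = 10L, alpha = 0.5, beta = 6) {
  # cls_prob: list per scale of (nc, A) prob matrices (detached)
  # dist_dec: list per scale of (4, A) decoded corner boxes (pixels)
  ng <- nrow(gt)
  out <- lapply(anchors, function(a) {
    list(idx = integer(0), gt = integer(0), score = numeric(0))
  })
  if (ng == 0) return(out)
  # flatten across scales
  scl <- integer(0); cell <- integer(0)
  cx <- numeric(0); cy <- numeric(0)
  for (s in seq_along(anchors)) {
    A <- length(anchors[[s]]$cx)
    scl <- c(scl, rep(s, A)); cell <- c(cell, seq_len(A))
    cx <- c(cx, anchors[[s]]$cx); cy <- c(cy, anchors[[s]]$cy)
  }
  metric <- matrix(0, ng, length(scl))
  iou_m <- matrix(0, ng, length(scl))
  for (g in seq_len(ng)) {
    inside <- cx > gt$x1[g] & cx < gt$x2[g] & cy > gt$y1[g] & cy < gt$y2[g]
    cand <- which(inside)
    if (!length(cand)) next
    for (i in cand) {
      s <- scl[i]; q <- cell[i]
      pb <- dist_dec[[s]][, q]
      ib <- iou(pb, c(gt$x1[g], gt$y1[g], gt$x2[g], gt$y2[g]))
      sc <- cls_prob[[s]][gt$class_id[g] + 1L, q]
      iou_m[g, i] <- ib
      metric[g, i] <- sc^alpha * ib^beta
    }
  }
  # top-k per gt, conflicts to the highest metric
  pos_gt <- rep(0L, length(scl))
  pos_metric <- rep(-1, length(scl))
  for (g in seq_len(ng)) {
    cand <- order(metric[g, ], decreasing = TRUE)[seq_len(topk)]
    cand <- cand[metric[g, cand] > 0]
    for (i in cand) {
      if (metric[g, i] > pos_metric[i]) {
        pos_metric[i] <- metric[g, i]
        pos_gt[i] <- g
      }
    }
  }
  # normalized target score per positive (peak iou per gt at peak metric)
  for (g in seq_len(ng)) {
    sel <- which(pos_gt == g)
    if (!length(sel)) next
    mmax <- max(metric[g, sel]); imax <- max(iou_m[g, sel])
    for (i in sel) {
      s <- scl[i]
      tsc <- if (mmax > 0) metric[g, i] / mmax * imax else 0
      out[[s]]$idx <- c(out[[s]]$idx, cell[i])
      out[[s]]$gt <- c(out[[s]]$gt, g)
      out[[s]]$score <- c(out[[s]]$score, tsc)
    }
  }
  out
}

# Forward + loss for one batch. Returns the scalar loss tensor plus the
# numeric components.
detection_loss <- function(model, x, gts, cfg) {
  v <- model$hyper$variant
  nc <- v$num_classes; rm_ <- v$reg_max
  size <- dim(x)[3]
  outs <- forward(model, tz(x))
  anchors <- anchor_grid(size, model$hyper$strides)
  nb <- dim(x)[1]
  bins <- array(0:(rm_ - 1), dim = c(rm_, 1, 1))
  loss_cls <- tz(array(0, 1)); loss_box <- tz(array(0, 1))
  loss_dfl <- tz(array(0, 1))
  total_t <- 0
  for (n in seq_len(nb)) {
    per_cls <- list(); per_box <- list(); per_dec <- list()
    for (s in seq_along(outs)) {
      o <- t_take(outs[[s]], n, axis = 1L)         # (1, C, H, W)
      d <- tshape(o)
      o2 <- t_reshape(o, c(d[2], d[3] * d[4]))     # (C, A)
      per_box[[s]] <- t_take(o2, seq_len(4 * rm_), axis = 1L)
      per_cls[[s]] <- t_take(o2, 4 * rm_ + seq_len(nc), axis = 1L)
      # decoded boxes (detached) for assignment
      db <- tz_value(per_box[[s]])
      A <- ncol(db)
      dim(db) <- c(rm_, 4L, A)
      e <- exp(sweep(db, c(2, 3), apply(db, c(2, 3), max)))
      p <- sweep(e, c(2, 3), apply(e, c(2, 3), sum), "/")
      dist <- apply(sweep(p, 1, 0:(rm_ - 1), "*"), c(2, 3), sum)
      st <- anchors[[s]]$stride
      per_dec[[s]] <- rbind(anchors[[s]]$cx - dist[1, ] * st,
                            anchors[[s]]$cy - dist[2, ] * st,
                            anchors[[s]]$cx + dist[3, ] * st,
                            anchors[[s]]$cy + dist[4, ] * st)
    }
    cls_prob <- lapply(per_cls, function(t) 1 / (1 + exp(-tz_value(t))))
    gt <- gts[[n]]
    asg <- tal_assign(cls_prob, per_dec, anchors, gt, nc)
    for (s in seq_along(outs)) {
      a <- asg[[s]]
      A <- length(anchors[[s]]$cx)
      tgt <- matrix(0, nc, A)
      if (length(a$idx)) {
        tgt[cbind(gt$class_id[a$gt] + 1L, a$idx)] <- a$score
      }
      loss_cls <- t_add(loss_cls, t_bce_logits(per_cls[[s]], tgt))
      if (!length(a$idx)) next
      total_t <- total_t + sum(a$score)
      st <- anchors[[s]]$stride
      # differentiable decode on the positive cells
      bp <- t_take(per_box[[s]], a$idx, axis = 2L)      # (4*rm, P)
      P <- length(a$idx)
      b3 <- t_reshape(bp, c(rm_, 4L, P))
      pr <- t_softmax(b3, axis = 1L)
      dist <- t_reshape(t_sum_to(t_mul(pr, tz(bins)), c(1L, 4L, P)),
                        c(4L, P))
      base <- rbind(anchors[[s]]$cx[a$idx], anchors[[s]]$cy[a$idx],
                    anchors[[s]]$cx[a$idx], anchors[[s]]$cy[a$idx])
      sgn <- matrix(c(-st, -st, st, st), 4, P)
      pred <- t_add(t_mul(dist, tz(sgn)), tz(base))
      gtb <- rbind(gt$x1[a$gt], gt$y1[a$gt], gt$x2[a$gt], gt$y2[a$gt])
      cl <- t_ciou_loss(pred, gtb)                      # (1, P)
      wts <- matrix(a$score, 1, P)
      loss_box <- t_add(loss_box, t_sum_all(t_mul(cl, tz(wts))))
      # distribution-focal loss on the two adjacent bins per side;
      # target distances (left, top, right, bottom) in stride units
      dt <- (base - gtb) * c(1, 1, -1, -1) / st
      dt <- pmin(pmax(dt, 0), rm_ - 1 - 1e-3)
      li <- floor(dt); wr <- dt - li
      Wt <- array(0, dim = c(rm_, 4L, P))
      for (sd_ in 1:4) {
        Wt[cbind(li[sd_, ] + 1, sd_, seq_len(P))] <-
          Wt[cbind(li[sd_, ] + 1, sd_, seq_len(P))] + (1 - wr[sd_, ])
        Wt[cbind(li[sd_, ] + 2, sd_, seq_len(P))] <-
          Wt[cbind(li[sd_, ] + 2, sd_, seq_len(P))] + wr[sd_, ]
      }
      Wt <- sweep(Wt, 3, a$score, "*")
      loss_dfl <- t_add(loss_dfl,
                        t_scale(t_sum_all(t_mul(t_log(pr, eps = 1e-9),
                                                tz(Wt))), -1))
    }
  }
  norm <- max(total_t, 1e-6)
  loss <- t_add(t_scale(loss_cls, cfg$cls_w / norm),
                t_add(t_scale(loss_box, cfg$box_w / norm),
                      t_scale(loss_dfl, cfg$dfl_w / norm)))
  list(loss = loss,
       components = c(cls = as.numeric(tz_value(loss_cls)) * cfg$cls_w / norm,
                      box = as.numeric(tz_value(loss_box)) * cfg$box_w / norm,
                      dfl = as.numeric(tz_value(loss_dfl)) * cfg$dfl_w / norm))
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$v
    p$m <- if (is.null(p$m)) g else momentum * p$m + g
    p$v <- p$v - lr * p$m
    p$grad <- NULL
  }
}

#' Train a detector on a YOLO-convention dataset
#'
#' Deterministic given `cfg$seed` (up to floating-point reduction order).
#' Aborts with a diagnostic on an empty train split or a non-finite loss.
#'
#' @param model a built model (modified in place via its parameter
#'   environments; also returned).
#' @param dataset_dir dataset directory (see [generate_dataset()]).
#' @param cfg a [train_config()].
#' @param checkpoint optional path; when given, the final weights and
#'   variant are saved there.
#' @return list with `model`, `history` (data frame: iter, loss, cls, box,
#'   dfl) and `val` (data frame of periodic val mAP50, possibly empty).
#' @export
train <- function(model, dataset_dir, cfg = train_config(),
                  checkpoint = NULL) {
  ds <- read_dataset(dataset_dir)
  man <- ds$manifest[ds$manifest$split == "train", , drop = FALSE]
  if (!nrow(man)) stop("train: empty train split in ", dataset_dir)
  nimg <- nrow(man)
  size <- cfg$image_size
  imgs <- lapply(man$image, load_image_chw, size = size)
  anns <- lapply(man$label, read_yolo_labels)
  gts <- lapply(anns, function(a) {
    data.frame(class_id = a$class_id,
               x1 = (a$cx - a$w / 2) * size, y1 = (a$cy - a$h / 2) * size,
               x2 = (a$cx + a$w / 2) * size, y2 = (a$cy + a$h / 2) * size)
  })
  iters <- if (!is.null(cfg$iterations)) cfg$iterations else {
    cfg$epochs * max(1L, nimg %/% cfg$batch_size)
  }
  params <- collect_params(model)
  hist <- data.frame(iter = integer(0), loss = numeric(0), cls = numeric(0),
                     box = numeric(0), dfl = numeric(0))
  val <- data.frame(iter = integer(0), mAP50 = numeric(0))
  if (iters == 0) {
    return(list(model = model, history = hist, val = val))
  }
  set.seed(cfg$seed)
  old_training <- .bgm$training
  .bgm$training <- TRUE
  on.exit(.bgm$training <- old_training)
  for (it in seq_len(iters)) {
    sel <- if (nimg <= cfg$batch_size) seq_len(nimg) else {
      sample.int(nimg, cfg$batch_size)
    }
    x <- array(0, dim = c(length(sel), 3L, size, size))
    for (j in seq_along(sel)) x[j, , , ] <- imgs[[sel[j]]]
    res <- with_tape({
      r <- detection_loss(model, x, gts[sel], cfg)
      lv <- as.numeric(tz_value(r$loss))
      if (!is.finite(lv)) {
        stop(sprintf("train: non-finite loss at iteration %d (%s)", it,
                     paste(sprintf("%s=%.4g", names(r$components),
                                   r$components), collapse = ", ")))
      }
      tz_backward(r$loss)
      r
    })
    sgd_step(params, cfg$lr, cfg$momentum, cfg$weight_decay)
    hist <- rbind(hist, data.frame(iter = it,
                                   loss = as.numeric(tz_value(res$loss)),
                                   cls = res$components["cls"],
                                   box = res$components["box"],
                                   dfl = res$components["dfl"]))
    if (cfg$eval_every > 0 && it %% cfg$eval_every == 0) {
      .bgm$training <- FALSE
      ev <- evaluate(model, dataset_dir, split = "val",
                     image_size = cfg$image_size)
      .bgm$training <- TRUE
      val <- rbind(val, data.frame(iter = it,
                                   mAP50 = ev$table$mAP50[1]))
    }
  }
  rownames(hist) <- NULL
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, history = hist, val = val)
}

#' Run the detector on a split and compute the evaluation summary
#'
#' @param model a built model or a checkpoint path.
#' @param dataset_dir dataset directory.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param image_size inference input size (divisible by 32).
#' @param conf_thr,iou_thr decoding thresholds (see [decode_detections()]).
#' @param csv optional path for the per-class CSV report.
#' @return an [eval_summary()] list (with the per-class table and the
#'   confusion matrix).
#' @export
evaluate <- function(model, dataset_dir, split = "val", image_size = 640L,
                     conf_thr = 0.25, iou_thr = 0.45, csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  ds <- read_dataset(dataset_dir)
  man <- ds$manifest[ds$manifest$split == split, , drop = FALSE]
  if (!nrow(man)) stop("evaluate: empty split ", split)
  nc <- model$hyper$variant$num_classes
  if (!is.null(ds$config$nc) && ds$config$nc != nc) {
    stop("evaluate: model has ", nc, " classes but dataset declares ",
         ds$config$nc)
  }
  preds <- list(); gts <- list()
  old_training <- .bgm$training
  .bgm$training <- FALSE
  on.exit(.bgm$training <- old_training)
  for (i in seq_len(nrow(man))) {
    x <- array(0, dim = c(1L, 3L, image_size, image_size))
    x[1, , , ] <- load_image_chw(man$image[i], image_size)
    out <- forward(model, tz(x))
    det <- decode_detections(out, model$hyper$variant,
                             c(image_size, image_size),
                             conf_thr = 0.001, iou_thr = iou_thr)[[1]]
    if (nrow(det)) det$image_id <- i
    preds[[i]] <- det
    a <- read_yolo_labels(man$label[i])
    gts[[i]] <- data.frame(
      class_id = a$class_id,
      x1 = (a$cx - a$w / 2) * image_size,
      y1 = (a$cy - a$h / 2) * image_size,
      x2 = (a$cx + a$w / 2) * image_size,
      y2 = (a$cy + a$h / 2) * image_size,
      image_id = if (nrow(a)) i else integer(0))
  }
  pred_df <- do.call(rbind, preds[vapply(preds, nrow, integer(1)) > 0])
  if (is.null(pred_df)) {
    pred_df <- data.frame(class_id = integer(0), conf = numeric(0),
                          x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                          y2 = numeric(0), image_id = integer(0))
  }
  gt_df <- do.call(rbind, gts[vapply(gts, nrow, integer(1)) > 0])
  if (is.null(gt_df)) {
    gt_df <- data.frame(class_id = integer(0), x1 = numeric(0),
                        y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                        image_id = integer(0))
  }
  cn <- if (!is.null(ds$config$names)) unlist(ds$config$names) else NULL
  summ <- eval_summary(pred_df, gt_df, nc, class_names = cn,
                       conf_thr = conf_thr)
  if (!is.null(csv)) write_eval_csv(summ, csv)
  summ
}
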