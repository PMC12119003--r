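# Assembly of the detector: YOLOv8n-style baseline (stem, four C2f backbone
# stages, SPPF, PAN neck with two top-down and two bottom-up fusions,
# decoupled anchor-free head) plus the three ablation toggles:
#   use_mecs  - MECS attention after each backbone stage output
#   use_bfm   - BFM fusion replacing the neck's concat nodes
#   use_gsc2f - GSC2f replacing the neck's C2f blocks (and GSConv replacing
#               the neck's strided downsample convs)

#' Describe a model variant
#'
#' The eight on/off combinations of the three block toggles correspond to the
#' rows of the ablation study; width/depth multipliers select the model scale
#' (defaults: the "n"-scale family values).
#'
#' @param use_mecs insert MECS attention blocks in the backbone.
#' @param use_bfm replace neck concat-fusion with BFM fusion nodes.
#' @param use_gsc2f replace neck C2f blocks with GSC2f (and the neck's
#'   downsample convs with GSConv).
#' @param width_mult channel width multiplier (> 0).
#' @param depth_mult block depth multiplier (> 0).
#' @param num_classes number of object classes (>= 1).
#' @param reg_max number of bins of the per-side box distribution.
#' @param max_channels channel cap before width scaling.
#' @return a `bgm_variant` list.
#' @export
model_variant <- function(use_mecs = FALSE, use_bfm = FALSE, use_gsc2f = FALSE,
                          width_mult = 0.25, depth_mult = 0.33,
                          num_classes = 15L, reg_max = 16L,
                          max_channels = 1024L) {
  if (width_mult <= 0 || depth_mult <= 0) stop("multipliers must be > 0")
  if (num_classes < 1) stop("num_classes must be >= 1")
  if (reg_max < 2) stop("reg_max must be >= 2")
  structure(list(use_mecs = isTRUE(use_mecs), use_bfm = isTRUE(use_bfm),
                 use_gsc2f = isTRUE(use_gsc2f), width_mult = width_mult,
                 depth_mult = depth_mult, num_classes = as.integer(num_classes),
                 reg_max = as.integer(reg_max),
                 max_channels = as.integer(max_channels)),
            class = "bgm_variant")
}

# Pinned hyperparameters that the source architecture leaves unstated
# (attention reduction ratio and insertion points, BFM widths, GSConv
# bottleneck ratio). Values are fixed against the published parameter/GFLOP
# budgets of the full model; see the methods vignette.
bgm_pins <- function() {
  list(
    mecs_r = 2L,
    mecs_kernels = c(7, 11, 21, 35, 41),
    mecs_stages = c("s2", "s3", "s4", "s5"),
    bfm_cout = "lateral",  # fused width rule: lateral-channel count
    bfm_ms_groupw = 8L,    # channels per group of BFM multi-scale convs
    bfm_desc_hidden = 1.6, # hidden width of the channel-descriptor MLP
    gsb_e = 0.5,
    gs_downsample = TRUE
  )
}

scale_ch <- function(c, v) {
  as.integer(max(8L, round(min(c, v$max_channels) * v$width_mult / 8) * 8))
}

scale_n <- function(n, v) max(1L, as.integer(round(n * v$depth_mult)))

#' Build a detector model
#'
#' Constructs the module tree for a [model_variant()]. With all toggles off
#' this is the YOLOv8n-style baseline; each toggle swaps in the corresponding
#' block. Construction is deterministic apart from weight initialization
#' (driven by the current RNG state); parameter *counts* are fully
#' deterministic given the variant.
#'
#' @param variant a [model_variant()].
#' @param pins internal hyperparameter pins; override only for architecture
#'   exploration.
#' @return a `mod_yolo` module. Apply with [forward()]; input spatial dims
#'   must be divisible by 32.
#' @export
build_model <- function(variant = model_variant(), pins = bgm_pins()) {
  v <- variant
  c1 <- scale_ch(64, v); c2 <- scale_ch(128, v); c3 <- scale_ch(256, v)
  c4 <- scale_ch(512, v); c5 <- scale_ch(1024, v)
  n1 <- scale_n(3, v); n2 <- scale_n(6, v)
  ch <- list(
    stem = conv_block(3, c1, k = 3, s = 2, name = "stem"),
    down2 = conv_block(c1, c2, k = 3, s = 2, name = "down2"),
    c2f_2 = c2f_block(c2, c2, n = n1, shortcut = TRUE, name = "c2f_2"),
    down3 = conv_block(c2, c3, k = 3, s = 2, name = "down3"),
    c2f_3 = c2f_block(c3, c3, n = n2, shortcut = TRUE, name = "c2f_3"),
    down4 = conv_block(c3, c4, k = 3, s = 2, name = "down4"),
    c2f_4 = c2f_block(c4, c4, n = n2, shortcut = TRUE, name = "c2f_4"),
    down5 = conv_block(c4, c5, k = 3, s = 2, name = "down5"),
    c2f_5 = c2f_block(c5, c5, n = n1, shortcut = TRUE, name = "c2f_5"),
    sppf = sppf_block(c5, c5, name = "sppf")
  )
  if (v$use_mecs) {
    mc <- c(s2 = c2, s3 = c3, s4 = c4, s5 = c5)
    for (st in pins$mecs_stages) {
      ch[[paste0("mecs_", st)]] <- mecs_block(mc[[st]], r = pins$mecs_r,
                                              kernels = pins$mecs_kernels,
                                              name = paste0("mecs_", st))
    }
  }
  up <- upsample_block()
  fuse_ch <- function(c_deep, c_lat, name, align_lat = TRUE) {
    if (v$use_bfm) {
      c_out <- if (identical(pins$bfm_cout, "lateral")) c_lat
               else as.integer(pins$bfm_cout)
      list(node = bfm_node_block(c_deep, c_lat, c_out,
                                 ms_groupw = pins$bfm_ms_groupw,
                                 desc_hidden = pins$bfm_desc_hidden,
                                 align_lat = align_lat, name = name),
           c_out = c_out)
    } else {
      list(node = NULL, c_out = c_deep + c_lat)
    }
  }
  # top-down laterals are raw backbone features (projected); bottom-up
  # laterals are neck outputs already at the fused width (direct)
  f1 <- fuse_ch(c5, c4, "fuse_td1", align_lat = TRUE)
  f2 <- fuse_ch(c4, c3, "fuse_td2", align_lat = TRUE)
  f3 <- fuse_ch(c3, c4, "fuse_bu1", align_lat = FALSE)
  f4 <- fuse_ch(c4, c5, "fuse_bu2", align_lat = FALSE)
  neck_c2f <- function(cin, cout, name) {
    c2f_block(cin, cout, n = n1, shortcut = FALSE, gs = v$use_gsc2f,
              gsb_e = pins$gsb_e, name = name)
  }
  neck_down <- function(cin, cout, name) {
    if (v$use_gsc2f && isTRUE(pins$gs_downsample)) {
      gs_conv_block(cin, cout, k = 3, s = 2, name = name)
    } else {
      conv_block(cin, cout, k = 3, s = 2, name = name)
    }
  }
  ch <- c(ch, list(
    up = up,
    fuse_td1 = f1$node,
    n_td1 = neck_c2f(f1$c_out, c4, "n_td1"),
    fuse_td2 = f2$node,
    n_td2 = neck_c2f(f2$c_out, c3, "n_td2"),
    down_bu1 = neck_down(c3, c3, "down_bu1"),
    fuse_bu1 = f3$node,
    n_bu1 = neck_c2f(f3$c_out, c4, "n_bu1"),
    down_bu2 = neck_down(c4, c4, "down_bu2"),
    fuse_bu2 = f4$node,
    n_bu2 = neck_c2f(f4$c_out, c5, "n_bu2"),
    head = detect_head_block(c(c3, c4, c5), v$num_classes, v$reg_max)
  ))
  ch <- ch[!vapply(ch, is.null, logical(1))]
  new_module("yolo", "model", ch = ch,
             hyper = list(variant = v, pins = pins, strides = c(8L, 16L, 32L),
                          ch_out = c(c3, c4, c5)))
}

#' @export
forward.mod_yolo <- function(m, x, ...) {
  x <- tz(x)
  hw <- tshape(x)[3:4]
  if (any(hw %% 32L != 0)) {
    stop("input spatial dims must be divisible by 32, got ",
         paste(hw, collapse = "x"))
  }
  v <- m$hyper$variant
  att <- function(t, st) {
    blk <- m$ch[[paste0("mecs_", st)]]
    if (!is.null(blk)) forward(blk, t, ...) else t
  }
  t <- forward(m$ch$stem, x, ...)
  t <- forward(m$ch$down2, t, ...)
  p2 <- att(forward(m$ch$c2f_2, t, ...), "s2")
  t <- forward(m$ch$down3, p2, ...)
  p3 <- att(forward(m$ch$c2f_3, t, ...), "s3")
  t <- forward(m$ch$down4, p3, ...)
  p4 <- att(forward(m$ch$c2f_4, t, ...), "s4")
  t <- forward(m$ch$down5, p4, ...)
  t <- forward(m$ch$c2f_5, t, ...)
  p5 <- att(forward(m$ch$sppf, t, ...), "s5")

  fuse <- function(node_name, deep, lat) {
    if (v$use_bfm) forward(m$ch[[node_name]], list(deep, lat), ...)
    else t_concat_c(list(deep, lat))
  }
  u1 <- forward(m$ch$up, p5, ...)
  td1 <- forward(m$ch$n_td1, fuse("fuse_td1", u1, p4), ...)
  u2 <- forward(m$ch$up, td1, ...)
  td2 <- forward(m$ch$n_td2, fuse("fuse_td2", u2, p3), ...)   # P3 out
  d1 <- forward(m$ch$down_bu1, td2, ...)
  bu1 <- forward(m$ch$n_bu1, fuse("fuse_bu1", d1, td1), ...)  # P4 out
  d2 <- forward(m$ch$down_bu2, bu1, ...)
  bu2 <- forward(m$ch$n_bu2, fuse("fuse_bu2", d2, p5), ...)   # P5 out
  forward(m$ch$head, list(td2, bu1, bu2), ...)
}

# Decoupled anchor-free head: per scale, a 2-conv box branch emitting
# 4*reg_max distribution logits and a 2-conv class branch emitting
# num_classes logits; outputs concatenated channel-wise (box first).
detect_head_block <- function(chs, nc, reg_max, name = "head") {
  c2h <- max(16L, chs[1] %/% 4L, 4L * reg_max)
  c3h <- max(chs[1], min(nc, 100L))
  ch <- list()
  for (i in seq_along(chs)) {
    ch[[paste0("box", i)]] <- seq_block(list(
      conv_block(chs[i], c2h, k = 3, name = "b1"),
      conv_block(c2h, c2h, k = 3, name = "b2"),
      conv_block(c2h, 4L * reg_max, k = 1, act = FALSE, bn = FALSE,
                 bias = TRUE, bias_init = 1, name = "b3")
    ), name = paste0("box", i))
    ch[[paste0("cls", i)]] <- seq_block(list(
      conv_block(chs[i], c3h, k = 3, name = "c1"),
      conv_block(c3h, c3h, k = 3, name = "c2"),
      conv_block(c3h, nc, k = 1, act = FALSE, bn = FALSE, bias = TRUE,
                 bias_init = log(0.01 / 0.99), name = "c3")
    ), name = paste0("cls", i))
  }
  new_module("detect", name, ch = ch,
             hyper = list(nc = nc, reg_max = reg_max, nscale = length(chs)))
}

#' @export
forward.mod_detect <- function(m, x, ...) {
  prof_push(m$name)
  outs <- lapply(seq_len(m$hyper$nscale), function(i) {
    b <- forward(m$ch[[paste0("box", i)]], x[[i]], ...)
    k <- forward(m$ch[[paste0("cls", i)]], x[[i]], ...)
    t_concat_c(list(b, k))
  })
  prof_pop()
  outs
}

#' Decode raw detector output into detections
#'
#' Box sides come from the expectation of the softmaxed `reg_max`-bin
#' distribution per side, scaled by the stride; the class is the argmax of
#' the sigmoided class logits; greedy per-class non-maximum suppression is
#' applied at `iou_thr`; boxes are clipped to the image.
#'
#' @param out list of per-scale output tensors from a model [forward()].
#' @param variant the [model_variant()] the model was built with.
#' @param img_hw input image height/width in pixels.
#' @param conf_thr confidence threshold in `[0, 1]`.
#' @param iou_thr NMS IoU threshold in `[0, 1]`.
#' @param max_det keep at most this many detections per image.
#' @return list (one element per batch item) of data frames with columns
#'   `class_id` (0-based), `conf`, `x1`, `y1`, `x2`, `y2` (pixels).
#' @export
decode_detections <- function(out, variant, img_hw, conf_thr = 0.25,
                              iou_thr = 0.45, max_det = 300L) {
  stopifnot(conf_thr >= 0, conf_thr <= 1, iou_thr >= 0, iou_thr <= 1)
  reg_max <- variant$reg_max
  nc <- variant$num_classes
  nb <- dim(tz_value(out[[1]]))[1]
  res <- vector("list", nb)
  for (n in seq_len(nb)) {
    rows <- list()
    for (s in seq_along(out)) {
      o <- tz_value(out[[s]])
      d <- dim(o)
      stride <- img_hw[1] / d[3]
      box <- o[n, seq_len(4 * reg_max), , , drop = FALSE]
      cls <- o[n, 4 * reg_max + seq_len(nc), , , drop = FALSE]
      ncell <- d[3] * d[4]
      dim(box) <- c(4 * reg_max, ncell)  # (1,C,H,W) -> C x (H*W)? see below
      # careful: dims were (1, C, H, W); flattening drops the unit batch dim
      dim(cls) <- c(nc, ncell)
      # after dim<-, layout is (C, H*W) because batch dim was 1 and came first
      probs <- 1 / (1 + exp(-cls))
      conf <- apply(probs, 2, max)
      cid <- max.col(t(probs), ties.method = "first") - 1L
      keep <- which(conf >= conf_thr)
      if (!length(keep)) next
      # distribution expectation per side
      db <- box[, keep, drop = FALSE]
      dim(db) <- c(reg_max, 4L, length(keep))
      e <- exp(sweep(db, c(2, 3), apply(db, c(2, 3), max)))
      p <- sweep(e, c(2, 3), apply(e, c(2, 3), sum), "/")
      dist <- apply(sweep(p, 1, 0:(reg_max - 1), "*"), c(2, 3), sum) # 4 x k
      gh <- (keep - 1L) %% d[3]        # row index (0-based)
      gw <- (keep - 1L) %/% d[3]       # col index
      cy <- (gh + 0.5) * stride
      cx <- (gw + 0.5) * stride
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = cid[keep], conf = conf[keep],
        x1 = pmin(pmax(cx - dist[1, ] * stride, 0), img_hw[2]),
        y1 = pmin(pmax(cy - dist[2, ] * stride, 0), img_hw[1]),
        x2 = pmin(pmax(cx + dist[3, ] * stride, 0), img_hw[2]),
        y2 = pmin(pmax(cy + dist[4, ] * stride, 0), img_hw[1])
      )
    }
    det <- if (length(rows)) do.call(rbind, rows) else
      data.frame(class_id = integer(0), conf = numeric(0), x1 = numeric(0),
                 y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    res[[n]] <- nms_greedy(det, iou_thr, max_det)
  }
  res
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in descending confidence order, dropping any same-class
#' box whose IoU with an already kept box exceeds `iou_thr`. Idempotent.
#'
#' @param det data frame with `class_id`, `conf`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thr IoU threshold.
#' @param max_det maximum detections to keep.
#' @return the filtered data frame.
#' @export
nms_greedy <- function(det, iou_thr = 0.45, max_det = 300L) {
  if (nrow(det) <= 1) return(det)
  det <- det[order(-det$conf), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- det[keep & det$class_id == det$class_id[i], , drop = FALSE]
      if (nrow(prev)) {
        ious <- box_iou_vec(det[i, c("x1", "y1", "x2", "y2")], prev)
        if (any(ious > iou_thr)) ok <- FALSE
      }
    }
    keep[i] <- ok
    if (sum(keep) >= max_det) break
  }
  det[keep, , drop = FALSE]
}

box_iou_vec <- function(a, b) {
  ix <- pmax(0, pmin(a$x2, b$x2) - pmax(a$x1, b$x1))
  iy <- pmax(0, pmin(a$y2, b$y2) - pmax(a$y1, b$y1))
  inter <- ix * iy
  ua <- (a$x2 - a$x1) * (a$y2 - a$y1) + (b$x2 - b$x1) * (b$y2 - b$y1) - inter
  ifelse(ua > 0, inter / ua, 0)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized file holding the variant, the pinned
#' hyperparameters, every trainable parameter and the batch-norm running
#' statistics. `load_checkpoint` rebuilds the model and restores the state.
#'
#' @param model a built model.
#' @param path file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  bs <- collect_buffers(model)
  saveRDS(list(variant = model$hyper$variant, pins = model$hyper$pins,
               params = lapply(ps, function(p) p$v),
               buffers = lapply(bs, function(b) list(rm = b$rm, rv = b$rv))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_model(st$variant, st$pins)
  ps <- collect_params(model)
  if (!setequal(names(ps), names(st$params))) {
    stop("checkpoint parameter names do not match the rebuilt model")
  }
  for (nm in names(st$params)) ps[[nm]]$v <- st$params[[nm]]
  bs <- collect_buffers(model)
  for (nm in names(st$buffers)) {
    bs[[nm]]$rm <- st$buffers[[nm]]$rm
    bs[[nm]]$rv <- st$buffers[[nm]]$rv
  }
  model
}
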