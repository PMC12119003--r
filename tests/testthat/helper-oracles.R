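# Independent oracles used by the tests. These recompute expected values by
# routes that do not share code with the package implementation.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xn <- x; xn[i] <- xn[i] - eps
    g[i] <- (f(xp) - f(xn)) / (2 * eps)
  }
  g
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(1e-8, max(abs(want)))
}

# Brute-force AP oracle: for every confidence cutoff, rematch from scratch
# and record one (recall, precision) point; integrate the precision envelope
# over the 101 COCO recall points.
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

oracle_match_counts <- function(preds, gts, thr) {
  if (is.null(preds$image_id)) preds$image_id <- 1L
  if (is.null(gts$image_id)) gts$image_id <- 1L
  used <- logical(nrow(gts))
  tp <- 0L
  for (i in order(-preds$conf)) {
    cand <- which(!used & gts$image_id == preds$image_id[i] &
                    gts$class_id == preds$class_id[i])
    if (!length(cand)) next
    ious <- sapply(cand, function(j) {
      oracle_iou(unlist(preds[i, c("x1", "y1", "x2", "y2")]),
                 unlist(gts[j, c("x1", "y1", "x2", "y2")]))
    })
    if (max(ious) >= thr) {
      tp <- tp + 1L
      used[cand[which.max(ious)]] <- TRUE
    }
  }
  c(tp = tp, fp = nrow(preds) - tp, fn = nrow(gts) - tp)
}

oracle_ap_all_cutoffs <- function(preds, gts, thr) {
  if (nrow(gts) == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  cuts <- sort(unique(preds$conf), decreasing = TRUE)
  pts <- t(sapply(cuts, function(cc) {
    sub <- preds[preds$conf >= cc, , drop = FALSE]
    m <- oracle_match_counts(sub, gts, thr)
    c(r = m["tp"] / nrow(gts), p = m["tp"] / max(1, m["tp"] + m["fp"]))
  }))
  rs <- pts[, 1]; ps <- pts[, 2]
  # precision envelope and 101-point integration
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    sel <- rs >= r
    ap <- ap + (if (any(sel)) max(ps[sel]) else 0)
  }
  ap / 101
}

# COCO-style mAP oracle: per class, AP by the all-cutoff route, unweighted
# mean over classes with ground truth.
oracle_map <- function(preds, gts, num_classes, thr) {
  aps <- sapply(seq_len(num_classes) - 1L, function(cl) {
    oracle_ap_all_cutoffs(preds[preds$class_id == cl, , drop = FALSE],
                          gts[gts$class_id == cl, , drop = FALSE], thr)
  })
  mean(aps, na.rm = TRUE)
}

# Closed-form Eq-10 FLOP enumeration of the all-flags-off detector at
# 640x640, written out layer by layer from the architecture definition
# (independent of the package's shape-replay profiler).
oracle_baseline_flops_640 <- function(nc = 15) {
  fl <- function(h, cin, k, cout, g = 1) 2 * h * h * (cin / g * k * k + 1) * cout
  total <- 0
  # stem + stage downsamples
  total <- total + fl(320, 3, 3, 16)
  total <- total + fl(160, 16, 3, 32)
  total <- total + fl(80, 32, 3, 64) + fl(40, 64, 3, 128) + fl(20, 128, 3, 256)
  c2f <- function(h, c1, c2, n) {
    ch <- c2 / 2
    fl(h, c1, 1, 2 * ch) + fl(h, (2 + n) * ch, 1, c2) +
      n * 2 * fl(h, ch, 3, ch)
  }
  total <- total + c2f(160, 32, 32, 1) + c2f(80, 64, 64, 2) +
    c2f(40, 128, 128, 2) + c2f(20, 256, 256, 1)
  # SPPF
  total <- total + fl(20, 256, 1, 128) + fl(20, 512, 1, 256)
  # neck
  total <- total + c2f(40, 384, 128, 1) + c2f(80, 192, 64, 1)
  total <- total + fl(40, 64, 3, 64) + c2f(40, 192, 128, 1)
  total <- total + fl(20, 128, 3, 128) + c2f(20, 384, 256, 1)
  # head (c2h = 64, c3h = 64 for nc <= 64)
  for (h in c(80, 40, 20)) {
    cin <- c(64, 128, 256)[match(h, c(80, 40, 20))]
    total <- total + fl(h, cin, 3, 64) + fl(h, 64, 3, 64) + fl(h, 64, 1, 64)
    total <- total + fl(h, cin, 3, 64) + fl(h, 64, 3, 64) + fl(h, 64, 1, nc)
  }
  total
}

# Tiny random detection fixtures for metric equivalence tests.
random_fixture <- function(seed, n_img = 3, nc = 3) {
  set.seed(seed)
  gts <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    n <- sample(0:4, 1)
    if (n == 0) return(NULL)
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    data.frame(image_id = im, class_id = sample(0:(nc - 1), n, TRUE),
               x1 = x1, y1 = y1, x2 = x1 + runif(n, 5, 20),
               y2 = y1 + runif(n, 5, 20))
  }))
  preds <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    gt <- gts[gts$image_id == im, , drop = FALSE]
    rows <- list()
    if (!is.null(gt) && nrow(gt)) {
      for (j in seq_len(nrow(gt))) {
        if (runif(1) < 0.75) {
          jit <- runif(4, -4, 4)
          rows[[length(rows) + 1L]] <- data.frame(
            image_id = im,
            class_id = if (runif(1) < 0.85) gt$class_id[j]
                       else sample(0:(nc - 1), 1),
            conf = runif(1, 0.2, 1),
            x1 = gt$x1[j] + jit[1], y1 = gt$y1[j] + jit[2],
            x2 = gt$x2[j] + jit[3], y2 = gt$y2[j] + jit[4])
        }
      }
    }
    nfp <- sample(0:2, 1)
    for (k in seq_len(nfp)) {
      x1 <- runif(1, 0, 80); y1 <- runif(1, 0, 80)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = im, class_id = sample(0:(nc - 1), 1),
        conf = runif(1, 0.05, 0.9),
        x1 = x1, y1 = y1, x2 = x1 + runif(1, 5, 20), y2 = y1 + runif(1, 5, 20))
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  if (is.null(gts)) gts <- data.frame(image_id = integer(0),
                                      class_id = integer(0), x1 = numeric(0),
                                      y1 = numeric(0), x2 = numeric(0),
                                      y2 = numeric(0))
  if (is.null(preds)) preds <- data.frame(image_id = integer(0),
                                          class_id = integer(0),
                                          conf = numeric(0), x1 = numeric(0),
                                          y1 = numeric(0), x2 = numeric(0),
                                          y2 = numeric(0))
  list(preds = preds, gts = gts, nc = nc)
}

# Set every convolution bias in a module tree to zero (attention blocks use
# bias-carrying convs).
zero_biases <- function(m) {
  if (!is.null(m$prm[["b"]])) m$prm[["b"]]$v[] <- 0
  for (ch in m$ch) if (inherits(ch, "bgm_module")) zero_biases(ch)
  invisible(m)
}
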