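# Synthetic plant-lesion scenes and YOLO-format dataset I/O.
#
# The generator emulates the statistics of a field-photographed plant
# disease detection set: cluttered leaf/soil backgrounds, variable global
# brightness, on average two lesions per image (Poisson), 15 disease
# classes with imbalanced sampling weights, and bounding-box areas from
# 200 px^2 up to (optionally beyond) 8000 px^2. Coordinates are normalized
# center-format (cx, cy, w, h) in files, pixel top-left-origin internally.

#' Scene specification for the synthetic lesion generator
#'
#' @param image_hw image height/width in pixels.
#' @param mean_objects expected lesion count per image (Poisson mean).
#' @param max_objects truncation of the lesion count.
#' @param area_range bounding-box area range in px^2.
#' @param tail_prob probability that a lesion is drawn from the over-range
#'   tail (up to `2 * area_range[2]`).
#' @param num_classes number of lesion classes.
#' @param class_weights per-class sampling weights; default a linear ramp
#'   emulating an imbalanced set (most to least represented).
#' @param clutter_level fraction in `[0, 1]` controlling soil/debris patches.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_hw = c(640, 640), mean_objects = 2,
                       max_objects = 8L, area_range = c(200, 8000),
                       tail_prob = 0.05, num_classes = 15L,
                       class_weights = NULL, clutter_level = 0.5) {
  stopifnot(mean_objects > 0, area_range[1] > 0,
            area_range[2] > area_range[1],
            area_range[2] <= prod(image_hw),
            clutter_level >= 0, clutter_level <= 1)
  if (is.null(class_weights)) {
    class_weights <- seq(800, 300, length.out = num_classes)
  }
  stopifnot(length(class_weights) == num_classes, all(class_weights > 0))
  structure(list(image_hw = as.integer(image_hw), mean_objects = mean_objects,
                 max_objects = as.integer(max_objects),
                 area_range = area_range, tail_prob = tail_prob,
                 num_classes = as.integer(num_classes),
                 class_weights = class_weights / sum(class_weights),
                 clutter_level = clutter_level),
            class = "scene_spec")
}

# clamp to [0, 1] preserving dim attributes (pmin/pmax with a scalar first
# argument would drop them)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(expr)
}

# Per-class visual signature: hue, saturation band, ring-vs-solid texture.
class_signature <- function(class_id, num_classes) {
  h <- (class_id * 0.83) %% 1  # golden-angle hue spacing
  list(hue = h,
       sat = 0.45 + 0.4 * ((class_id * 7) %% num_classes) / num_classes,
       ring = class_id %% 3 == 0,
       spot_freq = 2 + (class_id %% 5))
}

draw_lesion <- function(img, cx, cy, bw, bh, sig) {
  hw <- dim(img)[1:2]
  x0 <- max(1L, floor(cx - bw / 2)); x1 <- min(hw[2], ceiling(cx + bw / 2))
  y0 <- max(1L, floor(cy - bh / 2)); y1 <- min(hw[1], ceiling(cy + bh / 2))
  xs <- x0:x1; ys <- y0:y1
  gx <- outer(rep(1, length(ys)), (xs - cx) / (bw / 2))
  gy <- outer((ys - cy) / (bh / 2), rep(1, length(xs)))
  r2 <- gx^2 + gy^2
  th <- atan2(gy, gx)
  # irregular boundary via a low-order Fourier perturbation
  amp <- runif(3, 0.02, 0.08)
  ph <- runif(3, 0, 2 * pi)
  wobble <- 1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]) +
    amp[3] * sin(5 * th + ph[3])
  mask <- r2 <= wobble^2
  if (!any(mask)) return(NULL)
  rgb <- grDevices::hsv(sig$hue, sig$sat, 0.55)
  col <- grDevices::col2rgb(rgb)[, 1] / 255
  tex <- 0.75 + 0.25 * sin(sig$spot_freq * pi * gx) * sin(sig$spot_freq * pi * gy)
  alpha <- ifelse(mask, ifelse(rep(sig$ring, length(r2)) & r2 < 0.35,
                               0.35, 0.92), 0)
  dim(alpha) <- dim(r2)
  for (k in 1:3) {
    patch <- img[ys, xs, k]
    img[ys, xs, k] <- patch * (1 - alpha) + (col[k] * tex) * alpha
  }
  # tight box from the drawn mask
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  list(img = img,
       box_px = c(x1 = xs[cols[1]], y1 = ys[rows[1]],
                  x2 = xs[cols[2]] + 1, y2 = ys[rows[2]] + 1))
}

leaf_background <- function(hw, clutter, brightness) {
  H <- hw[1]; W <- hw[2]
  yy <- matrix(seq_len(H), H, W) / H
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  base_h <- 0.26 + 0.06 * sin(2 * pi * (xx * runif(1, 0.5, 2) +
                                        yy * runif(1, 0.5, 2)))
  veins <- 0.08 * abs(sin(10 * pi * (xx + 0.6 * yy) + runif(1, 0, pi)))
  v <- pmin(1, pmax(0, 0.45 + 0.18 * sin(2 * pi * yy * runif(1, 1, 3)) +
                      veins + matrix(rnorm(H * W, 0, 0.03), H, W)))
  img <- array(0, dim = c(H, W, 3))
  hsv_mat <- grDevices::col2rgb(grDevices::hsv(pmin(pmax(base_h, 0), 1),
                                               0.6, pmin(pmax(v, 0), 1))) / 255
  img[, , 1] <- matrix(hsv_mat[1, ], H, W)
  img[, , 2] <- matrix(hsv_mat[2, ], H, W)
  img[, , 3] <- matrix(hsv_mat[3, ], H, W)
  # soil / debris clutter patches
  n_patch <- stats::rpois(1, clutter * 6)
  if (n_patch > 0) {
    for (i in seq_len(n_patch)) {
      pcx <- runif(1, 1, W); pcy <- runif(1, 1, H)
      pa <- runif(1, 0.02, 0.12) * min(H, W)
      pb <- pa * runif(1, 0.5, 1.6)
      x0 <- max(1, floor(pcx - pa)); x1 <- min(W, ceiling(pcx + pa))
      y0 <- max(1, floor(pcy - pb)); y1 <- min(H, ceiling(pcy + pb))
      if (x1 <= x0 || y1 <= y0) next
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer(((ys - pcy) / pb)^2, rep(1, length(xs))) +
        outer(rep(1, length(ys)), ((xs - pcx) / pa)^2)
      a <- pmax(0, 1 - d2) * 0.7
      soil <- grDevices::col2rgb(grDevices::hsv(runif(1, 0.06, 0.11),
                                                runif(1, 0.4, 0.7),
                                                runif(1, 0.25, 0.5)))[, 1] / 255
      for (k in 1:3) {
        img[ys, xs, k] <- img[ys, xs, k] * (1 - a) + soil[k] * a
      }
    }
  }
  clamp01(img * brightness)
}

#' Generate one synthetic lesion scene
#'
#' Deterministic given `seed`: a leaf-textured background with soil clutter
#' and a global brightness factor, a Poisson-distributed number of lesions
#' (elliptical blobs with irregular boundaries and class-specific
#' color/texture signatures), and tight bounding boxes.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; the scene is byte-identical across calls with
#'   the same spec and seed.
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `annotations`
#'   (data frame `class_id`, `cx`, `cy`, `w`, `h`, normalized).
#' @export
generate_scene <- function(spec, seed) {
  with_seed(seed, {
    hw <- spec$image_hw
    brightness <- runif(1, 0.65, 1.35)
    img <- leaf_background(hw, spec$clutter_level, brightness)
    n_obj <- min(stats::rpois(1, spec$mean_objects), spec$max_objects)
    ann <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
    for (i in seq_len(n_obj)) {
      area <- if (runif(1) < spec$tail_prob) {
        runif(1, spec$area_range[2], 2 * spec$area_range[2])
      } else {
        runif(1, spec$area_range[1], spec$area_range[2])
      }
      q <- runif(1, 0.6, 1.7)  # aspect ratio
      bw <- sqrt(area * q); bh <- sqrt(area / q)
      cx <- runif(1, bw / 2 + 2, hw[2] - bw / 2 - 2)
      cy <- runif(1, bh / 2 + 2, hw[1] - bh / 2 - 2)
      cid <- sample.int(spec$num_classes, 1, prob = spec$class_weights) - 1L
      sig <- class_signature(cid, spec$num_classes)
      res <- draw_lesion(img, cx, cy, bw, bh, sig)
      if (is.null(res)) next
      img <- res$img
      b <- res$box_px
      ann <- rbind(ann, data.frame(
        class_id = cid,
        cx = (b["x1"] + b["x2"]) / 2 / hw[2],
        cy = (b["y1"] + b["y2"]) / 2 / hw[1],
        w = (b["x2"] - b["x1"]) / hw[2],
        h = (b["y2"] - b["y1"]) / hw[1], row.names = NULL))
    }
    list(image = img, annotations = ann)
  })
}

#' Split a dataset 7:2:1 (floor/floor/remainder)
#'
#' `n_train = floor(r1*n)`, `n_val = floor(r2*n)`, the remainder is test;
#' the assignment is a seeded permutation and a bijection onto `1..n`.
#'
#' @param n number of records.
#' @param ratios train/val/test ratios summing to 1.
#' @param seed permutation seed.
#' @return list with `sizes` (named train/val/test) and `split` (character
#'   vector of length `n`).
#' @export
split_dataset <- function(n, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, n >= 0)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  n_test <- n - n_train - n_val
  perm <- with_seed(seed, sample.int(max(n, 1L)))[seq_len(n)]
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  list(sizes = c(train = n_train, val = n_val, test = n_test), split = split)
}

#' Read / write YOLO-format label files
#'
#' One `class cx cy w h` line per object, whitespace-separated decimals with
#' normalized center-format coordinates. Reading validates every line and
#' reports all malformed or out-of-range lines with their line numbers.
#'
#' @param path label file path.
#' @param num_classes optional; when given, class ids must be
#'   `< num_classes`.
#' @return data frame `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path, num_classes = NULL) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else character(0)
  lines_keep <- which(nzchar(trimws(lines)))
  bad <- character(0)
  rows <- vector("list", length(lines_keep))
  for (j in seq_along(lines_keep)) {
    i <- lines_keep[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(v)) {
      bad <- c(bad, sprintf("line %d: expected 5 numeric fields", i))
      next
    }
    if (v[1] < 0 || v[1] != round(v[1]) ||
        (!is.null(num_classes) && v[1] >= num_classes)) {
      bad <- c(bad, sprintf("line %d: invalid class id %s", i, f[1]))
    }
    if (v[2] < 0 || v[2] > 1 || v[3] < 0 || v[3] > 1) {
      bad <- c(bad, sprintf("line %d: center out of [0,1]", i))
    }
    if (v[4] <= 0 || v[4] > 1 || v[5] <= 0 || v[5] > 1) {
      bad <- c(bad, sprintf("line %d: size out of (0,1]", i))
    }
    rows[[j]] <- data.frame(class_id = as.integer(v[1]), cx = v[2], cy = v[3],
                            w = v[4], h = v[5])
  }
  if (length(bad)) {
    stop("invalid YOLO labels in ", path, ":\n  ", paste(bad, collapse = "\n  "))
  }
  if (!length(rows)) {
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  do.call(rbind, rows)
}

#' @rdname read_yolo_labels
#' @param annotations data frame `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
write_yolo_labels <- function(path, annotations) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", annotations$class_id,
                   annotations$cx, annotations$cy, annotations$w,
                   annotations$h)
  writeLines(lines, path)
  invisible(path)
}

#' Augment an image and its annotations
#'
#' Geometric operations transform boxes consistently with the pixels;
#' photometric operations leave boxes untouched. Crops drop boxes whose
#' remaining-area fraction falls below `drop_thr`.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param annotations data frame `class_id`, `cx`, `cy`, `w`, `h`.
#' @param op one of `"hflip"`, `"rotate"`, `"crop"`, `"brightness"`,
#'   `"contrast"`.
#' @param angle rotation angle in degrees (counter-clockwise), for
#'   `"rotate"`.
#' @param crop_box pixel crop `c(x, y, w, h)` (top-left origin), for
#'   `"crop"`.
#' @param factor multiplier for `"brightness"` / `"contrast"`.
#' @param drop_thr remaining-area fraction below which a cropped box is
#'   dropped.
#' @return list with `image` and `annotations`.
#' @export
augment <- function(image, annotations,
                    op = c("hflip", "rotate", "crop", "brightness", "contrast"),
                    angle = 0, crop_box = NULL, factor = 1, drop_thr = 0.3) {
  op <- match.arg(op)
  H <- dim(image)[1]; W <- dim(image)[2]
  ann <- annotations
  switch(op,
    hflip = {
      image <- image[, W:1, , drop = FALSE]
      ann$cx <- 1 - ann$cx
    },
    rotate = {
      a <- angle %% 360
      if (a != 0) {
        th <- a * pi / 180
        cy0 <- (H + 1) / 2; cx0 <- (W + 1) / 2
        xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx0
        ys <- matrix(seq_len(H), H, W) - cy0
        # inverse map (rotate output coords by -theta)
        sx <- round(cos(th) * xs + sin(th) * ys + cx0)
        sy <- round(-sin(th) * xs + cos(th) * ys + cy0)
        ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
        out <- array(0, dim = dim(image))
        idx_ok <- which(ok)
        src <- cbind(sy[idx_ok], sx[idx_ok])
        for (k in 1:3) {
          ch <- image[, , k]
          o <- matrix(0, H, W)
          o[idx_ok] <- ch[src]
          out[, , k] <- o
        }
        image <- out
        if (nrow(ann)) {
          px <- ann$cx * W; py <- ann$cy * H
          bw <- ann$w * W; bh <- ann$h * H
          newbox <- t(vapply(seq_len(nrow(ann)), function(i) {
            cs <- rbind(c(px[i] - bw[i] / 2, py[i] - bh[i] / 2),
                        c(px[i] + bw[i] / 2, py[i] - bh[i] / 2),
                        c(px[i] - bw[i] / 2, py[i] + bh[i] / 2),
                        c(px[i] + bw[i] / 2, py[i] + bh[i] / 2))
            xr <- cos(th) * (cs[, 1] - cx0) - sin(th) * (cs[, 2] - cy0) + cx0
            yr <- sin(th) * (cs[, 1] - cx0) + cos(th) * (cs[, 2] - cy0) + cy0
            c(max(min(xr), 0), max(min(yr), 0), min(max(xr), W), min(max(yr), H))
          }, numeric(4)))
          keep <- newbox[, 3] > newbox[, 1] & newbox[, 4] > newbox[, 2]
          ann <- ann[keep, , drop = FALSE]
          nb <- newbox[keep, , drop = FALSE]
          ann$cx <- (nb[, 1] + nb[, 3]) / 2 / W
          ann$cy <- (nb[, 2] + nb[, 4]) / 2 / H
          ann$w <- (nb[, 3] - nb[, 1]) / W
          ann$h <- (nb[, 4] - nb[, 2]) / H
        }
      }
    },
    crop = {
      stopifnot(!is.null(crop_box))
      cb <- round(crop_box)
      if (cb[3] > W || cb[4] > H) stop("crop larger than image")
      if (cb[1] < 0 || cb[2] < 0 || cb[1] + cb[3] > W || cb[2] + cb[4] > H) {
        stop("crop window out of bounds")
      }
      image <- image[cb[2] + seq_len(cb[4]), cb[1] + seq_len(cb[3]), ,
                     drop = FALSE]
      if (nrow(ann)) {
        x1 <- ann$cx * W - ann$w * W / 2 - cb[1]
        y1 <- ann$cy * H - ann$h * H / 2 - cb[2]
        x2 <- x1 + ann$w * W; y2 <- y1 + ann$h * H
        cx1 <- pmax(x1, 0); cy1 <- pmax(y1, 0)
        cx2 <- pmin(x2, cb[3]); cy2 <- pmin(y2, cb[4])
        remain <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0)
        orig <- (x2 - x1) * (y2 - y1)
        keep <- remain / orig >= drop_thr
        ann <- ann[keep, , drop = FALSE]
        if (nrow(ann)) {
          ann$cx <- (cx1[keep] + cx2[keep]) / 2 / cb[3]
          ann$cy <- (cy1[keep] + cy2[keep]) / 2 / cb[4]
          ann$w <- (cx2[keep] - cx1[keep]) / cb[3]
          ann$h <- (cy2[keep] - cy1[keep]) / cb[4]
        }
      }
    },
    brightness = {
      image <- clamp01(image * factor)
    },
    contrast = {
      image <- clamp01((image - 0.5) * factor + 0.5)
    }
  )
  list(image = image, annotations = ann)
}

#' Generate a YOLO-convention dataset directory
#'
#' Writes `images/{split}/*.png`, `labels/{split}/*.txt` and a `data.yaml`
#' (class names, split paths, `nc`), split 7:2:1 by [split_dataset()].
#'
#' @param dir output directory.
#' @param n number of scenes.
#' @param spec a [scene_spec()].
#' @param seed master seed; scene `i` uses `seed + i`.
#' @param class_names optional class-name vector (defaults to
#'   `lesion_00 ...`).
#' @param ratios split ratios.
#' @return the dataset manifest (invisibly): data frame with `image`,
#'   `label`, `split`.
#' @export
generate_dataset <- function(dir, n, spec = scene_spec(), seed = 0L,
                             class_names = NULL, ratios = c(0.7, 0.2, 0.1)) {
  if (is.null(class_names)) {
    class_names <- sprintf("lesion_%02d", seq_len(spec$num_classes) - 1L)
  }
  sp <- split_dataset(n, ratios, seed = seed)
  for (s in c("train", "val", "test")) {
    dir.create(file.path(dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seed + i)
    s <- sp$split[i]
    img_path <- file.path(dir, "images", s, sprintf("img_%05d.png", i))
    lab_path <- file.path(dir, "labels", s, sprintf("img_%05d.txt", i))
    png::writePNG(sc$image, img_path)
    write_yolo_labels(lab_path, sc$annotations)
    rows[[i]] <- data.frame(image = img_path, label = lab_path, split = s)
  }
  yaml::write_yaml(list(path = normalizePath(dir),
                        train = "images/train", val = "images/val",
                        test = "images/test",
                        nc = spec$num_classes,
                        names = as.list(class_names)),
                   file.path(dir, "data.yaml"))
  invisible(do.call(rbind, rows))
}

#' Read a YOLO-convention dataset directory
#'
#' @param dir dataset directory containing `data.yaml`.
#' @return list with `config` (parsed yaml) and `manifest` (data frame
#'   `image`, `label`, `split`).
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "data.yaml"))
  rows <- list()
  for (s in c("train", "val", "test")) {
    imgs <- sort(list.files(file.path(dir, "images", s), pattern = "\\.png$",
                            full.names = TRUE))
    if (!length(imgs)) next
    labs <- file.path(dir, "labels", s,
                      sub("\\.png$", ".txt", basename(imgs)))
    rows[[s]] <- data.frame(image = imgs, label = labs, split = s)
  }
  list(config = cfg, manifest = do.call(rbind, rows))
}
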