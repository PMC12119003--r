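# Softmax-gated multi-scale fusion block.

test_that("multiscale extraction is shape-preserving and sums three kernels", {
  set.seed(1)
  m <- bfm_block(8)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  y <- multiscale_features(m, tz(x))
  expect_equal(bgmyolo:::tshape(y), dim(x))
  # zero input with zero biases maps to zero
  zero_biases(m)
  y0 <- multiscale_features(m, tz(array(0, dim = dim(x))))
  expect_true(all(tz_value(y0) == 0))
  # identity kernels on all three branches: output = 3 * x
  for (k in c(3, 5, 7)) {
    blk <- m$ch[[paste0("ms", k)]]
    blk$prm$w$v[] <- 0
    ctr <- (k + 1) / 2
    for (c in 1:8) blk$prm$w$v[c, 1, ctr, ctr] <- 1
    blk$prm[["b"]]$v[] <- 0
  }
  y3 <- tz_value(multiscale_features(m, tz(x)))
  core <- 5:12
  expect_equal(y3[, , core, core], 3 * x[, , core, core], tolerance = 1e-12)
})

test_that("channel descriptor pooling matches brute-force statistics", {
  set.seed(2)
  m <- bfm_block(4)
  # make the descriptor projection the identity on the first C entries so
  # the raw pooled statistics are observable: instead, test the stats by
  # recomputing them directly from the flattened values
  x <- array(rnorm(2 * 4 * 5 * 5), c(2, 4, 5, 5))
  M <- matrix(x, nrow = 2 * 4)
  want <- cbind(rowMeans(M), apply(M, 1, max),
                sqrt(rowMeans(M^2) - rowMeans(M)^2), apply(M, 1, min))
  avg <- bgmyolo:::t_gpool(tz(x), "avg")
  mx <- bgmyolo:::t_gpool(tz(x), "max")
  # reconstruct the stack the descriptor conv consumes
  stack <- local({
    ex2 <- bgmyolo:::t_gpool(bgmyolo:::t_mul(tz(x), tz(x)), "avg")
    sd_ <- bgmyolo:::t_sqrt(bgmyolo:::t_relu(bgmyolo:::t_sub(
      ex2, bgmyolo:::t_mul(avg, avg))), eps = 1e-12)
    mn <- bgmyolo:::t_scale(bgmyolo:::t_gpool(bgmyolo:::t_scale(tz(x), -1),
                                              "max"), -1)
    tz_value(bgmyolo:::t_concat_c(list(avg, mx, sd_, mn)))
  })
  got <- matrix(stack, nrow = 2)  # (batch, 16): 4 stats x 4 channels
  expect_equal(got[, 1:4], matrix(want[, 1], 2, 4, byrow = FALSE)[, 1:4] * 0 +
                 matrix(want[, 1], 2, 4), tolerance = 1e-10)
  expect_equal(got[, 5:8], matrix(want[, 2], 2, 4), tolerance = 1e-10)
  expect_equal(got[, 9:12], matrix(want[, 3], 2, 4), tolerance = 1e-8)
  expect_equal(got[, 13:16], matrix(want[, 4], 2, 4), tolerance = 1e-10)
  # constant plane: avg = max = min = v, std = 0
  xc <- array(1.25, dim = c(1, 4, 3, 3))
  d <- tz_value(channel_descriptor(m, xc))
  expect_equal(dim(d), c(1L, 4L, 1L, 1L))
  # population-convention std on a {1, 3} plane is exactly 1
  x13 <- array(c(1, 3), dim = c(1, 1, 1, 2))
  ex2 <- tz_value(bgmyolo:::t_gpool(bgmyolo:::t_mul(tz(x13), tz(x13)), "avg"))
  mu <- tz_value(bgmyolo:::t_gpool(tz(x13), "avg"))
  expect_equal(sqrt(ex2 - mu^2)[1], 1)
})

test_that("fusion weights are softmax-normalized, symmetric and bounded", {
  set.seed(3)
  m <- bfm_block(6, ms_groupw = 2)
  x1 <- array(rnorm(2 * 6 * 10 * 10), c(2, 6, 10, 10))
  x2 <- array(rnorm(2 * 6 * 10 * 10), c(2, 6, 10, 10))
  fw <- bfm_fuse(m, tz(x1), tz(x2), return_weights = TRUE)
  # normalization: the two weights sum to one per channel and per pixel
  expect_true(all(abs(tz_value(fw$wc1) + tz_value(fw$wc2) - 1) < 1e-12))
  expect_true(all(abs(tz_value(fw$ws1) + tz_value(fw$ws2) - 1) < 1e-12))
  expect_true(all(tz_value(fw$wc1) > 0 & tz_value(fw$wc1) < 1))
  # swapping the inputs swaps the weights exactly (shared paths)
  fw2 <- bfm_fuse(m, tz(x2), tz(x1), return_weights = TRUE)
  expect_equal(tz_value(fw2$wc1), tz_value(fw$wc2), tolerance = 1e-12)
  expect_equal(tz_value(fw2$ws1), tz_value(fw$ws2), tolerance = 1e-12)
  # identical inputs: all weights exactly 0.5
  fw3 <- bfm_fuse(m, tz(x1), tz(x1), return_weights = TRUE)
  expect_true(all(tz_value(fw3$wc1) == 0.5))
  expect_true(all(tz_value(fw3$ws1) == 0.5))
  # zero inputs fuse to zero
  z <- array(0, dim = dim(x1))
  expect_true(all(tz_value(bfm_fuse(m, tz(z), tz(z))) == 0))
  # output bounded by the envelope of the inputs (weights in [0,1],
  # multiply-then-add rule)
  y <- tz_value(fw$y)
  expect_true(all(y <= pmax(abs(x1), abs(x2)) + 1e-12))
  expect_true(all(y >= -pmax(abs(x1), abs(x2)) - 1e-12))
  expect_error(bfm_fuse(m, tz(x1), tz(x1[, , 1:5, , drop = FALSE])),
               "identical shape")
})
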