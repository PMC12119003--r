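# Median-enhanced channel and spatial attention.

test_that("global pooling statistics match brute-force oracles", {
  # constant plane: all three stats equal the constant
  xc <- array(3.7, dim = c(1, 2, 4, 4))
  st <- global_pool_stats(xc)
  expect_equal(as.vector(st$avg), c(3.7, 3.7))
  expect_equal(as.vector(st$max), c(3.7, 3.7))
  expect_equal(as.vector(st$median), c(3.7, 3.7))
  # 2x2 plane [1,2,3,4]: even-count median is the mean of the middle pair
  x2 <- array(c(1, 2, 3, 4), dim = c(1, 1, 2, 2))
  st2 <- global_pool_stats(x2)
  expect_equal(as.vector(st2$avg), 2.5)
  expect_equal(as.vector(st2$max), 4)
  expect_equal(as.vector(st2$median), 2.5)
  # seeded random 5x7 plane against a full-sort oracle
  set.seed(11)
  xr <- array(rnorm(1 * 1 * 5 * 7), c(1, 1, 5, 7))
  v <- sort(as.vector(xr))
  expect_equal(as.vector(global_pool_stats(xr)$median),
               (v[17] + v[18]) / 2 * 0 + median(as.vector(xr)))
  expect_equal(as.vector(global_pool_stats(xr)$median), v[18])
})

test_that("channel gate sums three sigmoided shared-MLP branches", {
  set.seed(5)
  m <- mecs_block(8, r = 2)
  # constant input: the three pooled vectors coincide, so the branches are
  # identical and Fc = 3 * sigmoid(MLP(v))
  xc <- array(0.4, dim = c(2, 8, 6, 6))
  fc <- tz_value(channel_attention(m, xc))
  one <- tz_value(bgmyolo:::t_sigmoid(forward(
    m$ch$mlp2, bgmyolo:::t_relu(forward(m$ch$mlp1,
                                        tz(array(0.4, c(2, 8, 1, 1))))))))
  expect_equal(fc, 3 * one, tolerance = 1e-12)
  # zero final-layer weights and bias: Fc = 3 * sigmoid(0) = 1.5 everywhere
  m$ch$mlp2$prm$w$v[] <- 0
  m$ch$mlp2$prm[["b"]]$v[] <- 0
  fc0 <- tz_value(channel_attention(m, array(rnorm(2 * 8 * 6 * 6),
                                             c(2, 8, 6, 6))))
  expect_true(all(abs(fc0 - 1.5) < 1e-12))
})

test_that("channel gate is bounded in (0,3) and degrades to a (0,2) gate", {
  set.seed(6)
  m <- mecs_block(16, r = 4)
  for (s in c(1, 9)) {
    x <- array(rnorm(1 * 16 * 10 * 10, sd = s), c(1, 16, 10, 10))
    fc <- tz_value(channel_attention(m, x))
    expect_true(all(fc > 0 & fc < 3))
    # dropping the median branch leaves a CBAM-style gate in (0,2)
    fc2 <- tz_value(channel_attention(m, x, stats = c("avg", "max")))
    expect_true(all(fc2 > 0 & fc2 < 2))
  }
})

test_that("channel gating is the elementwise product", {
  x <- array(2, dim = c(1, 2, 2, 2))
  fc <- array(0.5, dim = c(1, 2, 1, 1))
  expect_equal(tz_value(apply_channel(x, fc)),
               array(1, dim = c(1, 2, 2, 2)))
  ones <- array(1, dim = c(1, 2, 1, 1))
  expect_equal(tz_value(apply_channel(x, ones)), x)
  expect_true(all(tz_value(apply_channel(array(0, dim(x)), fc)) == 0))
})

test_that("spatial stage with identity kernels gives (n+1) * F' (x) F'", {
  set.seed(7)
  ks <- c(7, 11)
  m <- mecs_block(4, r = 2, kernels = ks)
  # base 5x5 depthwise identity
  m$ch$base$prm$w$v[] <- 0
  m$ch$base$prm$w$v[, 1, 3, 3] <- 1
  m$ch$base$prm[["b"]]$v[] <- 0
  for (i in seq_along(ks)) {
    k <- ks[i]
    dh <- m$ch[[paste0("dh", i)]]; dv <- m$ch[[paste0("dv", i)]]
    dh$prm$w$v[] <- 0; dh$prm$w$v[, 1, 1, (k + 1) / 2] <- 1
    dh$prm[["b"]]$v[] <- 0
    dv$prm$w$v[] <- 0; dv$prm$w$v[, 1, (k + 1) / 2, 1] <- 1
    dv$prm[["b"]]$v[] <- 0
    m$ch[[paste0("dh", i)]] <- dh; m$ch[[paste0("dv", i)]] <- dv
  }
  m$ch$proj$prm$w$v[] <- 0
  for (c in 1:4) m$ch$proj$prm$w$v[c, c, 1, 1] <- 1
  m$ch$proj$prm[["b"]]$v[] <- 0
  xp <- array(runif(1 * 4 * 32 * 32), c(1, 4, 32, 32))
  got <- tz_value(spatial_attention(m, tz(xp)))
  # interior pixels (away from the zero-padded border)
  core_h <- 12:21; core_w <- 12:21
  want <- (length(ks) + 1) * xp * xp
  expect_equal(got[, , core_h, core_w], want[, , core_h, core_w],
               tolerance = 1e-12)
})

test_that("the full MECS pass preserves shape and maps zero to zero", {
  set.seed(8)
  m <- mecs_block(16, r = 4)
  x <- array(rnorm(1 * 16 * 20 * 20), c(1, 16, 20, 20))
  y <- forward(m, tz(x))
  expect_equal(bgmyolo:::tshape(y), dim(x))
  expect_true(all(is.finite(tz_value(y))))
  y0 <- forward(m, tz(array(0, dim = c(2, 16, 8, 8))))
  expect_true(all(tz_value(y0) == 0))
})
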