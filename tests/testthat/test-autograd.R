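# Reverse-mode gradients of the tensor engine against central finite
# differences, and basic tape mechanics.

bg <- function(name) getFromNamespace(name, "bgmyolo")

grad_of_input <- function(build_loss, x0) {
  env <- new.env()
  bg("with_tape")({
    xt <- bg("t_node")(x0, integer(0), sink = function(g) env$gx <- g)
    tz_backward(build_loss(xt))
  })
  env$gx
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x0 <- array(rnorm(2 * 3 * 5 * 5), c(2, 3, 5, 5))
  w <- bg("new_param")(array(rnorm(4 * 3 * 3 * 3, sd = 0.3), c(4, 3, 3, 3)))
  b <- bg("new_param")(array(rnorm(4), 4))
  wgt <- NULL
  loss_fn <- function(xa) {
    y <- bgmyolo:::cpp_conv2d(xa, w$v, b$v, 2, 2, 1, 1, 1)
    sum(y * seq_along(y))
  }
  gx <- grad_of_input(function(xt) {
    y <- bg("t_conv2d")(xt, w, b, stride = c(2, 2), pad = c(1, 1))
    wgt <<- array(seq_along(tz_value(y)), dim = dim(tz_value(y)))
    bg("t_sum_all")(bg("t_mul")(y, tz(wgt)))
  }, x0)
  expect_lt(rel_err(gx, num_grad(loss_fn, x0)), 1e-6)
  expect_lt(rel_err(w$grad, num_grad(function(wa) {
    sum(bgmyolo:::cpp_conv2d(x0, wa, b$v, 2, 2, 1, 1, 1) * seq_along(wgt))
  }, w$v)), 1e-6)
  expect_lt(rel_err(b$grad, num_grad(function(ba) {
    sum(bgmyolo:::cpp_conv2d(x0, w$v, ba, 2, 2, 1, 1, 1) * seq_along(wgt))
  }, b$v)), 1e-6)
})

test_that("depthwise conv, softmax, median pool gradients are correct", {
  set.seed(2)
  x0 <- array(rnorm(1 * 3 * 4 * 6), c(1, 3, 4, 6))
  wd <- bg("new_param")(array(rnorm(3 * 1 * 3 * 3, sd = 0.3), c(3, 1, 3, 3)))
  gx <- grad_of_input(function(xt) {
    y <- bg("t_conv2d")(xt, wd, NULL, pad = c(1, 1), groups = 3)
    bg("t_sum_all")(bg("t_mul")(y, y))
  }, x0)
  expect_lt(rel_err(gx, num_grad(function(xa) {
    sum(bgmyolo:::cpp_conv2d(xa, wd$v, NULL, 1, 1, 1, 1, 3)^2)
  }, x0)), 1e-6)

  gx <- grad_of_input(function(xt) {
    y <- bg("t_softmax")(xt, 1L)
    bg("t_sum_all")(bg("t_mul")(y, tz(array(seq_along(x0), dim = dim(x0)))))
  }, x0)
  expect_lt(rel_err(gx, num_grad(function(xa) {
    e <- exp(xa)
    s <- sweep(e, c(2, 3, 4), apply(e, c(2, 3, 4), sum), "/")
    sum(s * seq_along(s))
  }, x0)), 1e-5)

  gx <- grad_of_input(function(xt) {
    y <- bg("t_gpool")(xt, "median")
    bg("t_sum_all")(bg("t_mul")(y, tz(array(1:3, dim = c(1, 3, 1, 1)))))
  }, x0)
  expect_lt(rel_err(gx, num_grad(function(xa) {
    M <- matrix(xa, nrow = 3)
    sum(apply(M, 1, median) * 1:3)
  }, x0, eps = 1e-6)), 1e-3)
})

test_that("batch-norm training-mode gradient matches finite differences", {
  set.seed(3)
  x0 <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  gam <- bg("new_param")(array(runif(3, 0.5, 1.5), c(1, 3, 1, 1)))
  bet <- bg("new_param")(array(rnorm(3), c(1, 3, 1, 1)))
  st <- new.env()
  reset <- function() {
    st$rm <- array(0, c(1, 3, 1, 1)); st$rv <- array(1, c(1, 3, 1, 1))
  }
  bn_ref <- function(xa) {
    M <- 2 * 4 * 4
    mu <- bgmyolo:::cpp_sum_to(xa, dim(xa), c(1L, 3L, 1L, 1L)) / M
    xc <- bgmyolo:::cpp_bcast_bin(xa, mu, dim(xa), dim(mu), 1L)
    va <- bgmyolo:::cpp_sum_to(xc * xc, dim(xa), c(1L, 3L, 1L, 1L)) / M
    xh <- bgmyolo:::cpp_bcast_bin(xc, sqrt(va + 1e-5), dim(xc), dim(va), 3L)
    y <- bgmyolo:::cpp_bcast_bin(xh, gam$v, dim(xh), dim(gam$v), 2L)
    y <- bgmyolo:::cpp_bcast_bin(y, bet$v, dim(y), dim(bet$v), 0L)
    sum(y * seq_along(y))
  }
  st_env <- bgmyolo:::.bgm
  st_env$training <- TRUE
  on.exit(st_env$training <- FALSE)
  reset()
  gx <- grad_of_input(function(xt) {
    y <- bg("t_bn")(xt, gam, bet, st)
    bg("t_sum_all")(bg("t_mul")(y, tz(array(seq_along(x0), dim = dim(x0)))))
  }, x0)
  expect_lt(rel_err(gx, num_grad(function(xa) bn_ref(xa), x0)), 1e-5)
  expect_lt(rel_err(gam$grad, num_grad(function(ga) {
    old <- gam$v; gam$v <- ga; on.exit(gam$v <- old); bn_ref(x0)
  }, gam$v)), 1e-5)
})

test_that("gradient flows through a conv-bn-silu block to its parameters", {
  set.seed(4)
  blk <- bgmyolo:::conv_block(3, 4, k = 3, name = "t")
  x0 <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  st_env <- bgmyolo:::.bgm
  st_env$training <- TRUE
  on.exit(st_env$training <- FALSE)
  bg("with_tape")({
    y <- forward(blk, tz(x0))
    tz_backward(bg("t_mean")(bg("t_mul")(y, y)))
  })
  for (p in collect_params(blk)) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
  }
})
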