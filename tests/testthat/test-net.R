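test_that("the encoder pyramid halves spatial dims with constant channel width", {
  net <- path_net(c(224L, 192L), filters = 32L, seed = 1)
  slice <- matrix(rnorm(224 * 192), 224, 192)
  pyr <- encode(net, slice)
  dims <- lapply(pyr, dim)
  expect_equal(dims[[1]], c(224L, 192L, 32L))
  expect_equal(dims[[2]], c(112L, 96L, 32L))
  expect_equal(dims[[3]], c(56L, 48L, 32L))
  expect_equal(dims[[4]], c(28L, 24L, 32L))
  expect_equal(dims[[5]], c(14L, 12L, 32L))
  # both encoders share the architecture; identical weights => identical pyramids
  net$params$enc[[2]] <- net$params$enc[[1]]
  pyr2 <- encode(net, slice, encoder = 2L)
  expect_equal(pyr, pyr2)
  # shapes not divisible by 16 are rejected
  expect_error(path_net(c(50L, 48L)), "divisible by 16")
})

test_that("conv_block preserves spatial dims and is non-negative", {
  net <- path_net(c(32L, 32L), filters = 8L, seed = 2)
  x <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  y <- conv_block(x, net$params$enc[[1]][[2]])
  expect_equal(dim(y), c(32L, 32L, 8L))
  expect_true(all(y >= 0))
})

test_that("padded 3x3 convolution matches the valid-size arithmetic", {
  # with kernel k and no padding the output of a p x p input is (p-k+1)^2;
  # padding 1 with k = 3 restores p x p
  p <- 20L; k <- 3L
  expect_equal(p - k + 1L, 18L)
  w <- matrix(rnorm(9), 1)
  y <- lesionfuse:::conv2d_fwd(array(rnorm(p * p), c(p, p, 1L)), w,
                               0, FALSE)
  expect_equal(dim(y)[1:2], c(p, p))
})

test_that("feature fusion is the stated linear 2x1x1 merge", {
  a <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  b <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  # shape chain: (c,x,y) + (c,x,y) -> (c,x,y)
  w <- matrix(rnorm(8), 4, 2)
  expect_equal(dim(fuse_features(a, b, w)), dim(a))
  # weights (0.5, 0.5), zero bias -> elementwise mean
  wm <- matrix(0.5, 4, 2)
  expect_equal(fuse_features(a, b, wm), (a + b) / 2)
  # identity routing with weights (1, 0)
  wi <- cbind(rep(1, 4), rep(0, 4))
  expect_equal(fuse_features(a, b, wi), a)
  # linearity: fuse(alpha a, alpha b) = alpha fuse(a, b) at zero bias
  expect_equal(fuse_features(2.5 * a, 2.5 * b, w), 2.5 * fuse_features(a, b, w))
  expect_error(fuse_features(a, array(0, c(6, 8, 4)), w), "differ")
})

test_that("the decoder restores full resolution with softmax-paired channels", {
  net <- path_net(c(64L, 48L), filters = 8L, seed = 3)
  x1 <- matrix(rnorm(64 * 48), 64, 48)
  x2 <- matrix(rnorm(64 * 48), 64, 48)
  out <- decode_slice(net, x1, x2)
  expect_equal(dim(out$prob), c(64L, 48L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_equal(out$prob + out$comp, matrix(1, 64, 48))
  # a zero-weight network is perfectly uncertain
  zp <- lesionfuse:::.zero_like(net$params)
  net0 <- net; net0$params <- zp
  expect_true(all(abs(decode_slice(net0, x1, x2)$prob - 0.5) < 1e-12))
})

test_that("path_forward reassembles per-slice maps into the source geometry", {
  vol <- tiny_volume(c(16L, 32L, 16L), seed = 5)
  views <- build_nine_views(vol, flip_lr(vol))
  net_ax <- path_net(c(32L, 16L), filters = 4L, seed = 1)
  soft <- path_forward(views[["axial.in_plane"]], net_ax)
  expect_equal(dim(soft), c(16L, 32L, 16L))
  expect_true(all(soft >= 0 & soft <= 1))
  # determinism in eval mode
  expect_identical(soft, path_forward(views[["axial.in_plane"]], net_ax))
  # a different plane still reassembles to the same 3D shape
  net_sa <- path_net(c(16L, 32L), filters = 4L, seed = 1)
  soft_sa <- path_forward(views[["sagittal.in_plane"]], net_sa)
  expect_equal(dim(soft_sa), dim(soft))
  expect_error(path_forward(views[["sagittal.in_plane"]], net_ax), "in_shape")
})

test_that("analytic path gradients agree with central differences (tie-free net)", {
  set.seed(13)
  net <- path_net(c(16L, 16L), filters = 2L, seed = 9)
  pp <- net$params
  # break exact ReLU ties (zero-initialized biases put many pre-activations
  # exactly at the kink, where central differences straddle the subgradient)
  jitter <- function(p) {
    if (is.list(p)) lapply(p, jitter)
    else if (is.null(dim(p))) p + rnorm(length(p)) * 0.05 else p
  }
  pp <- jitter(pp)
  x1 <- matrix(rnorm(256), 16); x2 <- matrix(rnorm(256), 16)
  r <- matrix(rbinom(256, 1, 0.3), 16)
  fw <- lesionfuse:::.path_fwd_slice(pp, x1, x2, keep = TRUE)
  gr <- lesionfuse:::.path_bwd_slice(pp, fw,
                                     lesionfuse:::.two_channel_loss_grad(fw$p, r))
  lossfun <- function(p)
    two_channel_loss(lesionfuse:::.path_fwd_slice(p, x1, x2, FALSE)$p, r)
  flat <- function(x, pre = "") {
    if (is.list(x))
      unlist(lapply(seq_along(x), function(i)
        flat(x[[i]], paste0(pre, "[[", i, "]]"))), use.names = FALSE)
    else pre
  }
  eps <- 1e-6
  for (path in sample(flat(pp), 12)) {
    th <- eval(parse(text = paste0("pp", path)))
    gth <- eval(parse(text = paste0("gr", path)))
    k <- sample(length(th), 1)
    bump <- function(delta) {
      p2 <- pp
      eval(parse(text = paste0("p2", path, "[k] <- th[k] + delta")))
      p2
    }
    ng <- (lossfun(bump(eps)) - lossfun(bump(-eps))) / (2 * eps)
    expect_equal(gth[k], ng, tolerance = 1e-3)
  }
})

test_that("a fresh path learns discs-in-noise to high training soft Dice", {
  data <- disc_slice_data(n_cases = 2L, n_slices = 6L, seed = 3)
  ctl <- train_control(batch_size = 6L, epochs = 5L, steps_per_epoch = 25L,
                       lr0 = 0.2, seed = 4)
  net <- train_path(data, ctl, path_net(c(32L, 32L), filters = 8L, seed = 5))
  expect_lt(net$trace[length(net$trace)], net$trace[1])
  sd_train <- mean(vapply(seq_len(6), function(i) {
    p <- lesionfuse:::.path_fwd_slice(net$params, data[[1]]$input$primary[i, , ],
                                      data[[1]]$input$auxiliary[i, , ], FALSE)$p
    soft_dice(p, data[[1]]$mask[i, , ])
  }, numeric(1)))
  expect_gt(sd_train, 0.8)
})
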