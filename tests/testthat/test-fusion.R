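test_that("assemble_stack interleaves binarized predictions with the image", {
  vol <- tiny_volume(c(16L, 16L, 16L), seed = 2)
  preds <- lapply(1:9, function(j) array(runif(16^3), c(16, 16, 16)))
  st <- assemble_stack(preds, vol)
  expect_equal(dim(st), c(16L, 16L, 16L, 18L))
  expect_equal(attr(st, "n_paths"), 9L)
  for (j in 1:9) {
    expect_equal(st[, , , 2 * j - 1], (preds[[j]] >= 0.5) * 1)
    expect_equal(st[, , , 2 * j], vol$data)
  }
  # all-zero predictions leave only the image channels
  st0 <- assemble_stack(lapply(1:9, function(j) array(0, c(16, 16, 16))), vol)
  expect_true(all(st0[, , , seq(1, 17, 2)] == 0))
  expect_error(assemble_stack(preds[1:8], vol), "9 path predictions")
  bad <- preds; bad[[4]] <- array(0, c(8, 8, 8))
  expect_error(assemble_stack(bad, vol), "shape")
})

test_that("union and majority agree with brute-force per-voxel counting", {
  set.seed(33)
  for (rep in 1:10) {
    sh <- sample(3:6, 3, replace = TRUE)
    masks <- lapply(1:9, function(j) random_mask(sh, p = runif(1, 0.1, 0.7)))
    votes <- Reduce(`+`, masks)
    un <- fuse_union(masks)
    mj <- fuse_majority(masks)
    expect_equal(un$data, (votes >= 1) * 1)
    expect_equal(mj$data, (votes >= 5) * 1)
    # majority is contained in union; union covers every single path
    expect_true(all(mj$data <= un$data))
    expect_true(sum(un$data) >= max(vapply(masks, sum, numeric(1))))
  }
  # vote-count oracle at the decision boundary
  base <- lapply(1:9, function(j) array(0, c(2, 2, 2)))
  for (j in 1:5) base[[j]][1, 1, 1] <- 1
  for (j in 1:4) base[[j]][2, 1, 1] <- 1
  mj <- fuse_majority(base)
  expect_equal(mj$data[1, 1, 1], 1) # 5 votes
  expect_equal(mj$data[2, 1, 1], 0) # 4 votes
  # unanimity reduces to any single path
  same <- lapply(1:9, function(j) base[[1]])
  expect_equal(fuse_majority(same)$data, base[[1]])
  expect_equal(fuse_union(same)$data, base[[1]])
  # one all-ones path drives the union to all-ones
  ones <- c(list(array(1, c(2, 2, 2))), lapply(1:8, function(j) array(0, c(2, 2, 2))))
  expect_true(all(fuse_union(ones)$data == 1))
  expect_error(fuse_majority(base[1:8]), "even")
})

test_that("flipping a single vote 0 -> 1 never removes fused foreground", {
  set.seed(17)
  masks <- lapply(1:9, function(j) random_mask(c(4, 4, 4), p = 0.3))
  un0 <- fuse_union(masks)$data
  mj0 <- fuse_majority(masks)$data
  for (rep in 1:10) {
    m2 <- masks
    j <- sample(9, 1)
    zero_idx <- which(m2[[j]] == 0)
    m2[[j]][sample(zero_idx, 1)] <- 1
    expect_true(all(fuse_union(m2)$data >= un0))
    expect_true(all(fuse_majority(m2)$data >= mj0))
  }
})

test_that("the 3D fuser preserves shape with softmax-paired output channels", {
  net <- fuser_net(seed = 8)
  plan <- vapply(net$layers, function(l) nrow(l$w), integer(1))
  expect_equal(plan, c(36L, 9L, 9L, 2L))
  expect_equal(ncol(net$layers[[1]]$w), 18L * 27L)
  vol <- tiny_volume(c(16L, 16L, 16L), seed = 3)
  preds <- lapply(1:9, function(j) array(runif(16^3), c(16, 16, 16)))
  st <- assemble_stack(preds, vol)
  out <- fuse_cnn3d(st, net)
  expect_equal(dim(out$p), c(16L, 16L, 16L))
  expect_equal(out$p + out$q, array(1, c(16, 16, 16)))
  # zero-weight fuser is perfectly uncertain; ties at 0.5 map to lesion
  net0 <- net; net0$layers <- lesionfuse:::.zero_like(net$layers)
  out0 <- fuse_cnn3d(st, net0)
  expect_true(all(abs(out0$p - 0.5) < 1e-12))
  expect_true(all(out0$mask$data == 1))
  # channel mismatch is a validation error
  st16 <- st[, , , 1:16, drop = FALSE]
  class(st16) <- class(st)
  expect_error(fuse_cnn3d(st16, net), "channels")
})

test_that("analytic fuser gradients agree with central differences", {
  set.seed(21)
  net <- fuser_net(seed = 5)
  # tie-free biases
  net$layers <- lapply(net$layers, function(l) {
    l$b <- rnorm(length(l$b)) * 0.05; l
  })
  x <- array(rnorm(4 * 4 * 4 * 18), c(4, 4, 4, 18))
  r <- random_mask(c(4, 4, 4), p = 0.4)
  fw <- lesionfuse:::.fuser_fwd(net, x, keep = TRUE)
  gr <- lesionfuse:::.fuser_bwd(net, fw,
                                lesionfuse:::.two_channel_loss_grad(fw$p, r))
  lossfun <- function(layers) {
    n2 <- net; n2$layers <- layers
    two_channel_loss(lesionfuse:::.fuser_fwd(n2, x, FALSE)$p, r)
  }
  eps <- 1e-6
  for (l in 1:4) for (fld in c("w", "b")) {
    th <- net$layers[[l]][[fld]]
    k <- sample(length(th), 1)
    l1 <- net$layers; l1[[l]][[fld]][k] <- th[k] + eps
    l2 <- net$layers; l2[[l]][[fld]][k] <- th[k] - eps
    ng <- (lossfun(l1) - lossfun(l2)) / (2 * eps)
    expect_equal(gr[[l]][[fld]][k], ng, tolerance = 1e-3)
  }
})
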