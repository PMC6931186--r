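test_that("the learning-rate schedule decays geometrically from 0.01", {
  cfg <- train_control()
  expect_equal(lr_schedule(0, cfg), 0.01)
  expect_equal(lr_schedule(1, cfg), 0.0097)
  expect_equal(lr_schedule(49, cfg), 0.01 * 0.97^49)
  expect_equal(lr_schedule(49, cfg), 2.24e-3, tolerance = 0.01)
  # closed form vs the recursion, strictly decreasing and positive
  lrs <- vapply(0:49, lr_schedule, numeric(1), cfg = cfg)
  expect_equal(lrs, 0.01 * cumprod(c(1, rep(0.97, 49))))
  expect_true(all(diff(lrs) < 0) && all(lrs > 0))
  expect_error(lr_schedule(50, cfg), "epoch")
  expect_error(lr_schedule(-1, cfg), "epoch")
})

test_that("train_control validates its hyperparameters", {
  expect_error(train_control(lr0 = -0.1), "lr0")
  expect_error(train_control(lr_decay = 1), "lr_decay")
  expect_error(train_control(epochs = -1), "epochs")
  cfg <- train_control()
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 50L)
})

test_that("path training is reproducible and inert at zero learning rate", {
  data <- disc_slice_data(n_cases = 2L, n_slices = 4L, seed = 6)
  ctl <- train_control(batch_size = 4L, epochs = 2L, steps_per_epoch = 3L,
                       lr0 = 0.1, seed = 11)
  n1 <- train_path(data, ctl, path_net(c(32L, 32L), filters = 4L, seed = 7))
  n2 <- train_path(data, ctl, path_net(c(32L, 32L), filters = 4L, seed = 7))
  expect_identical(n1$trace, n2$trace)
  expect_identical(n1$params, n2$params)
  expect_true(all(is.finite(n1$trace)) && all(n1$trace > 0))
  # zero learning rate leaves the weights untouched
  net0 <- path_net(c(32L, 32L), filters = 4L, seed = 7)
  ctl0 <- train_control(batch_size = 4L, epochs = 1L, steps_per_epoch = 2L,
                        lr0 = 0, seed = 11)
  tr <- train_path(data, ctl0, net0)
  expect_identical(tr$params, net0$params)
  expect_error(train_path(list(), ctl), "empty")
})

test_that("fuser training leaves weights unchanged after zero epochs", {
  vol <- tiny_volume(c(16L, 16L, 16L), seed = 4)
  mask <- lesion_mask((vol$data > 1.05) * 1)
  case <- list(id = "c1", t1 = vol, mask = mask)
  paths <- lapply(as.vector(outer(path_planes(), norm_schemes(), paste, sep = ".")),
                  function(nm) {
                    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
                    d <- dim(extract_slices(vol, parts[1]))
                    path_net(d[2:3], filters = 2L, seed = 1)
                  })
  names(paths) <- as.vector(outer(path_planes(), norm_schemes(), paste, sep = "."))
  f0 <- fuser_net(seed = 2)
  ctl <- train_control(epochs = 0L, seed = 1)
  f1 <- train_fuser(paths, list(case), ctl, f0)
  expect_identical(f1$layers, f0$layers)
})

test_that("k-fold splits are balanced, exhaustive, disjoint and seeded", {
  ids <- paste0("case", 1:99)
  plan <- kfold_split(ids, k = 5, seed = 3)
  sizes <- tabulate(plan$assignments, 5)
  expect_equal(sort(sizes), c(19, 20, 20, 20, 20))
  expect_equal(sum(sizes), 99)
  expect_setequal(names(plan$assignments), ids)
  # same seed -> identical assignments; different seed -> different
  expect_identical(plan$assignments, kfold_split(ids, 5, seed = 3)$assignments)
  expect_false(identical(plan$assignments, kfold_split(ids, 5, seed = 4)$assignments))
  # leave-one-out
  loo <- kfold_split(ids[1:7], k = 7, seed = 1)
  expect_equal(sort(tabulate(loo$assignments, 7)), rep(1, 7))
  expect_error(kfold_split(ids[1:3], k = 5), "exceeds")
})

test_that("cross-study evaluation refuses overlapping case ids", {
  a <- list(list(id = "s1"), list(id = "s2"))
  b <- list(list(id = "s2"), list(id = "s3"))
  expect_error(cross_study_eval(a, b), "leakage")
})

test_that("k-fold cross-validation pools disjoint held-out predictions", {
  cases <- generate_dataset(4, seed = 3)
  ctl <- train_control(batch_size = 4L, epochs = 1L, steps_per_epoch = 2L,
                       lr0 = 0.1, seed = 1)
  fctl <- train_control(batch_size = 1L, epochs = 1L, seed = 1)
  cv <- kfold_crossval(cases, k = 2L, seed = 1, filters = 4L,
                       control = ctl, fuser_control = fctl)
  expect_equal(nrow(cv$table), 4L)
  expect_setequal(cv$table$id, vapply(cases, `[[`, character(1), "id"))
  # each case is predicted exactly once, in the fold it was held out of
  expect_equal(unname(cv$plan$assignments[cv$table$id]), cv$table$fold)
  expect_true(all(cv$table$dice >= 0 & cv$table$dice <= 1))
})
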