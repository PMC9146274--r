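test_that("the learning-rate schedule is piecewise constant with drops", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 1:25), rep(0.01, 25))
  expect_equal(lr_at_epoch(cfg, 26), 0.002)
  expect_equal(lr_at_epoch(cfg, 50), 0.002)
  expect_equal(lr_at_epoch(cfg, 51), 4e-4)
})

test_that("the loss follows the half-mean-square convention", {
  # single pixel, unit batch: (1/2) * 2^2 = 2
  expect_equal(training_loss(matrix(2, 1, 1), matrix(0, 1, 1)), 2)
  p <- array(runif(16), c(2, 2, 1, 4))
  expect_equal(training_loss(p, p), 0)
  expect_error(training_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shapes differ")
})

test_that("the l2 term adds exactly lambda times the penalised weight norm", {
  net <- build_upunet(upunet_spec(L = 2, f0 = 2), seed = 9)
  p <- array(runif(32), c(4, 4, 1, 2))
  tg <- array(runif(32), c(4, 4, 1, 2))
  l0 <- training_loss(p, tg, net$params, 0)
  l1 <- training_loss(p, tg, net$params, 0.1)
  nm <- names(net$params)
  wsum <- sum(vapply(nm[grepl("_w$", nm)],
                     function(n) sum(net$params[[n]]^2), numeric(1)))
  expect_equal(l1 - l0, 0.1 * wsum, tolerance = 1e-12)
  # biases and batch-norm parameters are not penalised
  net$params$enc1_b[] <- 100
  net$params$enc1_gamma[] <- 100
  expect_equal(training_loss(p, tg, net$params, 0.1), l1)
})

test_that("a few epochs of training reduce the loss on a small fixture", {
  ds <- generate_dataset(make_fixture("smoke", seed = 33))
  net <- build_upunet(upunet_spec(L = 4, f0 = 4), seed = 33)
  cfg <- train_config(batch_size = 6, max_epochs = 5, seed = 33)
  fit <- train_model(net, ds, cfg)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_equal(nrow(fit$history), 5)
  expect_equal(fit$history$lr, lr_at_epoch(cfg, 1:5))
  expect_false(any(is.na(fit$history$val_loss)))
})

test_that("training is bit-reproducible for identical seeds", {
  ds <- generate_dataset(make_fixture("unit", seed = 44))
  cfg <- train_config(batch_size = 2, max_epochs = 2, seed = 44)
  f1 <- train_model(build_upunet(upunet_spec(L = 3, f0 = 2), seed = 44),
                    ds, cfg)
  f2 <- train_model(build_upunet(upunet_spec(L = 3, f0 = 2), seed = 44),
                    ds, cfg)
  expect_identical(f1$net$params, f2$net$params)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
})

test_that("reported training loss decomposes into data term plus penalty", {
  ds <- generate_dataset(make_fixture("unit", seed = 55))
  cfg <- train_config(batch_size = 2, max_epochs = 1, seed = 55)
  net0 <- build_upunet(upunet_spec(L = 3, f0 = 2), seed = 55)
  fit <- train_model(net0, ds, cfg)
  # recompute the first epoch loss independently: replay the shuffled
  # batches against the evolving parameters is involved, so check the
  # simpler identity on a fixed forward pass instead
  xb <- upunet:::.stack_batch(ds$pairs, ds$split$train, "input")
  yb <- upunet:::.stack_batch(ds$pairs, ds$split$train, "target")
  fw <- upunet:::net_forward(fit$net, xb, training = FALSE)
  full <- training_loss(fw$y, yb, fit$net$params, cfg$l2_lambda)
  data_term <- training_loss(fw$y, yb)
  pen <- full - data_term
  wsum <- sum(vapply(names(fit$net$params)[grepl("_w$",
                                                 names(fit$net$params))],
                     function(n) sum(fit$net$params[[n]]^2), numeric(1)))
  expect_equal(pen, cfg$l2_lambda * wsum, tolerance = 1e-9 * max(1, pen))
})

test_that("oversized batches and empty splits are rejected", {
  ds <- generate_dataset(make_fixture("unit", seed = 66))
  expect_error(train_model(build_upunet(upunet_spec(L = 3, f0 = 2),
                                        seed = 1),
                           ds, train_config(batch_size = 50,
                                            max_epochs = 1)),
               "batch_size")
})
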