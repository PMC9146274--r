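test_that("network channel plans match the doubling/halving scheme", {
  sp <- upunet_spec(L = 5, f0 = 8)
  expect_equal(sp$channels, c(8L, 16L, 32L, 64L, 128L))
  expect_equal(sp$decoder_channels, c(128L, 64L, 32L, 16L, 8L))
  bs <- baseline_unet_spec()
  expect_equal(bs$channels, c(8L, 16L, 32L))
  expect_equal(bs$bridge, 64L)
})

test_that("parameter totals match an independent closed-form account", {
  # independent layer-by-layer arithmetic, written out from the
  # architecture definition rather than the builder
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  ch <- c(1, 8, 16, 32, 64, 128)
  enc <- sum(sapply(1:5, function(l) conv_p(3, ch[l], ch[l + 1])))
  bn <- 2 * sum(ch[-1])
  dch <- c(128, 128, 64, 32, 16, 8)
  dec <- sum(sapply(1:5, function(j) conv_p(2, dch[j], dch[j + 1])))
  skp <- sum(sapply(ch[-1], function(c) conv_p(2, c, c)))
  head <- conv_p(1, 8, 1)
  expect_equal(enc, 98240)
  expect_equal(bn, 496)
  expect_equal(dec, 109304)
  expect_equal(skp, 87544)
  total <- enc + bn + dec + skp + head
  expect_equal(count_parameters(build_upunet(upunet_spec(), seed = 1)),
               total)
  expect_equal(total, 295593)

  ublock <- function(cin, cout) conv_p(3, cin, cout) + 2 * cout +
    conv_p(3, cout, cout) + 2 * cout
  base <- ublock(1, 8) + ublock(8, 16) + ublock(16, 32) +  # encoder
    ublock(32, 64) +                                       # bridge
    conv_p(2, 64, 32) + ublock(64, 32) +                   # decoder 1
    conv_p(2, 32, 16) + ublock(32, 16) +                   # decoder 2
    conv_p(2, 16, 8) + ublock(16, 8) +                     # decoder 3
    conv_p(1, 8, 1)
  expect_equal(count_parameters(build_baseline_unet(baseline_unet_spec(),
                                                    seed = 1)), base)
  expect_equal(base, 121385)
})

test_that("parameter counting equals a brute-force sum over tensors", {
  net <- build_upunet(upunet_spec(L = 3, f0 = 4), seed = 2)
  expect_equal(count_parameters(net),
               sum(unlist(lapply(net$params, length))))
})

test_that("forward pass keeps shape, is non-negative and deterministic", {
  net <- build_upunet(upunet_spec(), seed = 3)
  x <- matrix(runif(128 * 128) * 255, 128, 128)
  y1 <- restore_frame(net, x)
  expect_equal(dim(y1), c(128, 128))
  expect_true(all(y1 >= 0))
  expect_identical(y1, restore_frame(net, x))
  bl <- build_baseline_unet(seed = 3)
  yb <- restore_frame(bl, x)
  expect_equal(dim(yb), c(128, 128))
})

test_that("indivisible input sizes raise an explicit shape error", {
  net <- build_upunet(upunet_spec(L = 5), seed = 1)
  expect_error(restore_frame(net, matrix(0, 100, 100)), "divisible")
})

test_that("zeroed head weights force an all-zero output", {
  net <- build_upunet(upunet_spec(L = 4, f0 = 4), seed = 5)
  net$params$head_w[] <- 0
  net$params$head_b[] <- 0
  y <- restore_frame(net, matrix(runif(64 * 64) * 255, 64, 64))
  expect_true(all(y == 0))
})

test_that("spatial sizes contract and expand by powers of two", {
  net <- build_upunet(upunet_spec(L = 4, f0 = 4), seed = 7)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  fw <- upunet:::upunet_forward(net, x, training = FALSE, cache = TRUE)
  for (l in 1:4)
    expect_equal(dim(fw$cache$E[[l]])[1:2], c(64, 64) / 2^l)
  for (j in 1:4)
    expect_equal(dim(fw$cache$dec_post[[j]])[1:2], c(64, 64) / 2^(4 - j))
})

test_that("skip level l merges one spatial level finer than its encoder output", {
  net <- build_upunet(upunet_spec(L = 5, f0 = 8), seed = 7)
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  fw <- upunet:::upunet_forward(net, x, training = FALSE, cache = TRUE)
  for (l in 1:5) {
    enc_size <- dim(fw$cache$E[[l]])[1]
    skip_size <- dim(fw$cache$skip_post[[l]])[1]
    expect_equal(skip_size, 2 * enc_size)
    # and it is added at decoder stage j = L - l + 1, whose output has
    # the same spatial size and channel count
    j <- 5 - l + 1
    expect_equal(dim(fw$cache$dec_post[[j]]),
                 dim(fw$cache$skip_post[[l]]))
  }
})

test_that("analytic gradients agree with finite differences off the kinks", {
  set.seed(11)
  net <- build_upunet(upunet_spec(L = 2, f0 = 2), seed = 11)
  # move biases off zero so no pre-activation sits exactly on a kink
  for (nm in names(net$params))
    net$params[[nm]] <- net$params[[nm]] +
      rnorm(length(net$params[[nm]]), 0, 0.05)
  x <- array(runif(8 * 8 * 1 * 2) * 3, c(8, 8, 1, 2))
  tg <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  loss <- function(n) {
    fw <- upunet:::net_forward(n, x, training = TRUE, cache = TRUE)
    sum((fw$y - tg)^2) / 2
  }
  fw <- upunet:::net_forward(net, x, training = TRUE, cache = TRUE)
  g <- upunet:::net_backward(net, fw$cache, fw$y - tg)
  eps <- 1e-6
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      n1 <- net; n1$params[[nm]][i] <- p[i] + eps
      n2 <- net; n2$params[[nm]][i] <- p[i] - eps
      fd <- (loss(n1) - loss(n2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-3,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("baseline gradients also agree with finite differences", {
  set.seed(12)
  bl <- build_baseline_unet(baseline_unet_spec(depth = 2, f0 = 2,
                                               dropout = 0), seed = 12)
  for (nm in names(bl$params))
    bl$params[[nm]] <- bl$params[[nm]] +
      rnorm(length(bl$params[[nm]]), 0, 0.05)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  tg <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  loss <- function(n) {
    fw <- upunet:::net_forward(n, x, training = TRUE, cache = TRUE)
    sum((fw$y - tg)^2) / 2
  }
  fw <- upunet:::net_forward(bl, x, training = TRUE, cache = TRUE)
  g <- upunet:::net_backward(bl, fw$cache, fw$y - tg)
  eps <- 1e-6
  for (nm in names(bl$params)) {
    p <- bl$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      n1 <- bl; n1$params[[nm]][i] <- p[i] + eps
      n2 <- bl; n2$params[[nm]][i] <- p[i] - eps
      fd <- (loss(n1) - loss(n2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-3,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("summary reports a per-tensor table consistent with the total", {
  net <- build_upunet(upunet_spec(L = 2, f0 = 2), seed = 1)
  tab <- suppressMessages(withr::with_output_sink(nullfile(),
                                                  summary(net)))
  expect_equal(sum(tab$params), count_parameters(net))
})
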