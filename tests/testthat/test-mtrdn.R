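test_that("subnetworks honor the fully convolutional scale contract", {
  net2 <- build_subnetwork(tiny_config(scale = 2L), seed = 1)
  y <- rdn_forward(net2, matrix(runif(50 * 50), 50, 50))$y
  expect_identical(dim(y), c(100L, 100L, 1L))

  net4 <- build_subnetwork(tiny_config(scale = 4L), seed = 1)
  y4 <- rdn_forward(net4, matrix(runif(50 * 50), 50, 50))$y
  expect_identical(dim(y4), c(200L, 200L, 1L))

  # another input size, same network (fully convolutional)
  y2 <- rdn_forward(net2, matrix(runif(17 * 23), 17, 23))$y
  expect_identical(dim(y2), c(34L, 46L, 1L))
  expect_true(all(is.finite(y2)))

  expect_error(rdn_forward(net2, matrix(0, 4, 4)), "8 x 8")
  expect_error(rdn_config(D = 0), "positive")
  expect_error(rdn_config(scale = 3), "scale")
})

test_that("parameter count matches the closed-form architecture arithmetic", {
  count_oracle <- function(D, C, G, G0, scale, cin = 1, cout = 1) {
    conv <- function(o, i, k) o * (k * k * i) + o
    n <- conv(G0, cin, 3) + conv(G0, G0, 3)
    for (d in seq_len(D)) {
      for (cc in seq_len(C)) n <- n + conv(G, G0 + (cc - 1) * G, 3)
      n <- n + conv(G0, G0 + C * G, 1)
    }
    n <- n + conv(G0, D * G0, 1) + conv(G0, G0, 3)
    if (scale > 1) n <- n + conv(G0 * scale^2, G0, 3)
    n + conv(cout, G0, 3)
  }
  net <- build_subnetwork(rdn_config(D = 4, C = 4, G = 16, G0 = 32,
                                     scale = 2), seed = 1)
  expect_identical(rdn_n_params(net), count_oracle(4, 4, 16, 32, 2))
  net3 <- build_subnetwork(rdn_config(D = 2, C = 3, G = 8, G0 = 12,
                                      scale = 1, in_channels = 2), seed = 1)
  expect_identical(rdn_n_params(net3), count_oracle(2, 3, 8, 12, 1, cin = 2))
})

test_that("the three-subnetwork forward pass respects shapes and dataflow", {
  p <- mtrdn_params(scale = 2L, D = 2L, C = 2L, G = 3L, G0 = 4L, seed = 2)
  in1 <- matrix(runif(16 * 16), 16, 16)
  in2 <- matrix(runif(16 * 16), 16, 16)
  out <- mtrdn_forward(p, in1, in2)
  expect_identical(dim(out$output1), c(32L, 32L))
  expect_identical(dim(out$output2), c(32L, 32L))
  expect_identical(dim(out$output3), c(32L, 32L))

  # determinism
  out_b <- mtrdn_forward(p, in1, in2)
  expect_identical(out, out_b)

  # perturbing input2 must change outputs 2 and 3 but never output 1
  in2b <- in2; in2b[5, 5] <- in2b[5, 5] + 0.3
  out2 <- mtrdn_forward(p, in1, in2b)
  expect_identical(out2$output1, out$output1)
  expect_false(identical(out2$output2, out$output2))
  expect_false(identical(out2$output3, out$output3))

  expect_error(mtrdn_forward(p, in1, matrix(0, 8, 8)), "same shape")
})

test_that("the multitask loss is the normalized weighted mean absolute error", {
  g <- replicate(3, matrix(runif(36), 6, 6), simplify = FALSE)
  expect_equal(multitask_loss(g, g), 0)
  o <- lapply(g, function(m) m + 0.1)
  # equal residual on all branches: any normalized weights give 0.1
  expect_equal(multitask_loss(o, g, c(0.25, 0.25, 0.5)), 0.1)
  # weights (1,0,0) reduce to the plain MAE of branch 1
  o1 <- list(g[[1]] + 0.07, g[[2]], g[[3]])
  expect_equal(multitask_loss(o1, g, c(1, 0, 0)), 0.07)
  # un-normalized weights are normalized before use
  expect_equal(multitask_loss(o, g, c(1, 1, 2)),
               multitask_loss(o, g, c(0.25, 0.25, 0.5)))
  expect_error(multitask_loss(o, g, c(0, 0, 0)), "not all zero")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  cfg <- tiny_config(scale = 2L)
  net <- build_subnetwork(cfg, seed = 5)
  x <- matrix(runif(10 * 10), 10, 10)
  gt <- matrix(runif(20 * 20), 20, 20)
  fw <- rdn_forward(net, x, keep_cache = TRUE)
  y <- fw$y[, , 1]
  dy <- array(sign(y - gt) / length(y), c(dim(y), 1))
  bk <- rdn_backward(net, fw$cache, dy)
  lossfun <- function(n) mean(abs(rdn_forward(n, x)$y[, , 1] - gt))
  eps <- 1e-6
  for (ly in c("sfe1", "b1c2", "b2lff", "gff1", "up", "recon")) {
    w <- net$layers[[ly]]$w
    i <- sample(length(w), 1)
    n2 <- net
    n2$layers[[ly]]$w[i] <- w[i] + eps; lp <- lossfun(n2)
    n2$layers[[ly]]$w[i] <- w[i] - eps; lm <- lossfun(n2)
    num <- (lp - lm) / (2 * eps)
    expect_equal(bk$grads[[ly]]$dw[i], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s", ly))
  }
})

test_that("multisupervision sends gradient to every subnetwork", {
  p <- mtrdn_params(scale = 2L, D = 2L, C = 2L, G = 3L, G0 = 4L, seed = 3)
  in1 <- matrix(runif(12 * 12), 12, 12)
  in2 <- matrix(runif(12 * 12), 12, 12)
  g1 <- matrix(runif(24 * 24), 24, 24)
  g2 <- matrix(runif(24 * 24), 24, 24)
  g3 <- matrix(runif(24 * 24), 24, 24)
  lg <- mtrdn:::.mtrdn_loss_grads(p, in1, in2, g1, g2, g3)
  expect_true(is.finite(lg$loss))
  for (sn in c("subnet1", "subnet2", "subnet3")) {
    total <- sum(vapply(lg$grads[[sn]],
                        function(l) sum(abs(l$dw)) + sum(abs(l$db)),
                        numeric(1)))
    expect_gt(total, 0)
  }
})

test_that("checkpoints round-trip parameters and configuration", {
  p <- mtrdn_params(scale = 2L, D = 1L, C = 1L, G = 2L, G0 = 3L, seed = 9)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(p, path)
  back <- load_checkpoint(path)
  expect_equal(back, p)
  meta <- jsonlite::fromJSON(readRDS(path)$meta_json)
  expect_identical(meta$subnet1$scale, 2L)
  expect_identical(meta$subnet3$in_channels, 2L)
  unlink(path)
})
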