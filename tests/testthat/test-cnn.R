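# Base CNN: architecture fidelity (parameter counts, shape chain), engine
# correctness against a double-precision oracle, and training behaviour.

test_that("parameter counts match the closed-form layer oracle", {
  # hand-evaluated closed form (k^2*c_in + 1)*c_out and (d_in + 1)*d_out
  per_layer <- c(
    conv1  = (9 * 1 + 1) * 32,     # 320
    conv2  = (9 * 32 + 1) * 32,    # 9248
    conv3  = (9 * 32 + 1) * 32,    # 9248
    conv4  = (9 * 32 + 1) * 64,    # 18496
    conv5  = (9 * 64 + 1) * 128,   # 73856
    dense1 = (25088 + 1) * 200,    # 5017800
    dense2 = (200 + 1) * 5)        # 1005
  expect_equal(sum(per_layer), 5129973)
  expect_equal(count_parameters(architecture_base_cnn(5)), 5129973L)
  # swapping the softmax width changes only the last dense layer
  expect_equal(count_parameters(architecture_base_cnn(2)),
               5129973L - 1005L + (200 + 1) * 2)
  # a lone 200 -> 5 dense layer
  lone <- architecture_spec(list(layer_dense(5)), input_shape = c(200L, 1L, 1L))
  expect_equal(count_parameters(lone), 1005L)
  expect_error(architecture_base_cnn(1), class = "kneedhl_config_error")
  # a built model reports the same count; weightless models error
  m <- build_base_cnn(5, seed = 1)
  expect_equal(count_parameters(m), 5129973L)
  expect_equal(sum(vapply(m$weights, function(w) length(w$W) + length(w$b),
                          numeric(1))), 5129973)
  m$weights <- NULL
  expect_error(count_parameters(m), class = "kneedhl_state_error")
})

test_that("layer output shapes follow the printed chain", {
  shapes <- infer_shapes(architecture_base_cnn(5))
  chw <- function(i) shapes[[i]]
  expect_identical(chw(1), c(32L, 112L, 112L))   # conv block 1
  expect_identical(chw(4), c(32L, 56L, 56L))     # maxpool
  expect_identical(chw(6), c(64L, 56L, 56L))     # conv 64
  expect_identical(chw(7), c(64L, 28L, 28L))     # avgpool
  expect_identical(chw(9), c(128L, 28L, 28L))    # conv 128
  expect_identical(chw(10), c(128L, 14L, 14L))   # avgpool
  expect_identical(chw(12), c(25088L, 1L, 1L))   # flatten = 14*14*128
  expect_identical(chw(13), c(200L, 1L, 1L))     # deep-feature layer
  expect_identical(chw(15), c(5L, 1L, 1L))       # softmax
  # spatial-shape law 112 -> 56 -> 28 -> 14 requires even dims throughout
  odd <- architecture_spec(list(layer_maxpool()), input_shape = c(1L, 7L, 8L))
  expect_error(infer_shapes(odd), class = "kneedhl_invalid_geometry")
})

test_that("forward pass matches the double-precision oracle on a tiny net", {
  set.seed(10)
  m <- build_model(tiny_arch(3), seed = 20)
  img <- matrix(runif(64), 8, 8)
  p <- predict_proba(m, list(img))
  o <- oracle_forward(m, img)
  expect_equal(as.numeric(p), o, tolerance = 1e-5)
  # intermediate feature layer agrees too (dense-4, post ReLU)
  f <- extract_features(m, list(img))
  expect_equal(dim(f), c(1L, 4L))
  expect_equal(as.numeric(f), oracle_forward(m, img, upto = 6), tolerance = 1e-5)
})

test_that("softmax rows normalize and inference is deterministic", {
  m <- build_base_cnn(5, seed = 3)
  imgs <- lapply(1:4, function(i) matrix(runif(112 * 112), 112, 112))
  p1 <- predict_proba(m, imgs)
  expect_equal(dim(p1), c(4L, 5L))
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict_proba(m, imgs))  # dropout off: bit-identical
  # duplicate images give identical feature rows
  f <- extract_features(m, list(imgs[[1]], imgs[[1]], imgs[[2]]))
  expect_identical(f[1, ], f[2, ])
  expect_false(identical(f[1, ], f[3, ]))
  expect_equal(ncol(f), 200L)
})

test_that("engine gradients equal an exact hand-derived oracle", {
  # conv(2, relu) -> avgpool -> flatten -> dense(3, softmax) on 6x6 input;
  # the oracle backpropagates the same chain in double precision
  set.seed(3)
  arch <- architecture_spec(list(layer_conv2d(2), layer_avgpool(),
    layer_flatten(), layer_dense(3, "softmax")), input_shape = c(1L, 6L, 6L))
  m <- build_model(arch, seed = 4)
  imgs <- lapply(1:2, function(i) matrix(runif(36), 6, 6))
  y <- c(0L, 2L)
  Y <- matrix(0, 2, 3); Y[cbind(1:2, y + 1)] <- 1
  res <- kneedhl:::engine_run(m, kneedhl:::pack_tensor(imgs),
                              training = TRUE, y = Y, loss = 1L)
  pad <- function(mm) rbind(0, cbind(0, mm, 0), 0)
  oracle_grads <- function(img, yv) {
    W1 <- m$weights[[1]]$W; b1 <- m$weights[[1]]$b
    W2 <- m$weights[[2]]$W; b2 <- m$weights[[2]]$b
    xp <- pad(img)
    z1 <- lapply(1:2, function(co) {
      acc <- matrix(b1[co], 6, 6)
      for (di in -1:1) for (dj in -1:1)
        acc <- acc + W1[co, (di + 1) * 3 + (dj + 1) + 1] * xp[(2:7) + di, (2:7) + dj]
      acc })
    a1 <- lapply(z1, function(z) pmax(z, 0))
    pool <- lapply(a1, function(a)
      (a[seq(1, 5, 2), seq(1, 5, 2)] + a[seq(2, 6, 2), seq(1, 5, 2)] +
       a[seq(1, 5, 2), seq(2, 6, 2)] + a[seq(2, 6, 2), seq(2, 6, 2)]) / 4)
    flat <- unlist(lapply(pool, function(mm) as.numeric(t(mm))))
    z2 <- as.numeric(t(W2) %*% flat + b2)
    p <- exp(z2 - max(z2)); p <- p / sum(p)
    d2 <- p; d2[yv + 1] <- d2[yv + 1] - 1
    dflat <- as.numeric(W2 %*% d2)
    dpool <- list(matrix(dflat[1:9], 3, 3, byrow = TRUE),
                  matrix(dflat[10:18], 3, 3, byrow = TRUE))
    da1 <- lapply(dpool, function(dp) {
      g <- matrix(0, 6, 6)
      for (i in 1:3) for (j in 1:3)
        g[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- dp[i, j] / 4
      g })
    dz1 <- mapply(function(da, z) da * (z > 0), da1, z1, SIMPLIFY = FALSE)
    dW1 <- matrix(0, 2, 9); db1 <- numeric(2)
    for (co in 1:2) {
      db1[co] <- sum(dz1[[co]])
      for (di in -1:1) for (dj in -1:1)
        dW1[co, (di + 1) * 3 + (dj + 1) + 1] <-
          sum(dz1[[co]] * xp[(2:7) + di, (2:7) + dj])
    }
    list(dW1 = dW1, db1 = db1, dW2 = outer(flat, d2), db2 = d2)
  }
  o1 <- oracle_grads(imgs[[1]], y[1])
  o2 <- oracle_grads(imgs[[2]], y[2])
  expect_equal(res$grads[[1]]$W, (o1$dW1 + o2$dW1) / 2, tolerance = 1e-5)
  expect_equal(res$grads[[1]]$b, (o1$db1 + o2$db1) / 2, tolerance = 1e-5)
  expect_equal(res$grads[[2]]$W, (o1$dW2 + o2$dW2) / 2, tolerance = 1e-5)
  expect_equal(res$grads[[2]]$b, (o1$db2 + o2$db2) / 2, tolerance = 1e-5)
})

test_that("training bookkeeping, degenerate targets and loss descent", {
  set.seed(2)
  # bookkeeping: 2 epochs -> 2 history rows with all four metrics
  m <- build_model(tiny_arch(2, c(1L, 16L, 16L)), seed = 5)
  imgs <- lapply(1:20, function(i) matrix(runif(256), 16, 16))
  labs <- rep(0:1, 10)
  m <- train_model(m, imgs, labs,
                   validation = list(images = imgs[1:4], labels = labs[1:4]),
                   config = train_config(epochs = 2, batch_size = 8, seed = 1))
  expect_equal(nrow(m$history), 2)
  expect_true(all(c("loss", "acc", "val_loss", "val_acc") %in% names(m$history)))
  expect_true(all(is.finite(m$history$loss)))

  # all-one-class labels: the model collapses onto that class
  m1 <- build_model(tiny_arch(3, c(1L, 16L, 16L)), seed = 6)
  m1 <- train_model(m1, imgs, rep(1L, 20),
                    config = train_config(epochs = 15, batch_size = 8,
                                          learning_rate = 0.01, seed = 2))
  expect_true(all(predict_classes(m1, imgs) == 1L))

  # separable phantoms: loss after training < first-epoch loss
  inp <- make_phantom_inputs(rep(c(0, 4), each = 20), seed = 3)
  m2 <- build_base_cnn(2, seed = 7)
  m2 <- train_model(m2, inp$images, as.integer(inp$labels == 4),
                    config = train_config(epochs = 6, batch_size = 8, seed = 3))
  expect_lt(m2$history$loss[6], m2$history$loss[1])

  # invalid inputs
  expect_error(train_model(m1, imgs, labs[1:3]), class = "kneedhl_invalid_input")
  expect_error(train_model(m1, imgs, rep(9L, 20)), class = "kneedhl_invalid_input")
  expect_error(train_config(epochs = 0), class = "kneedhl_config_error")
})
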