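test_that("memory unit attention matches a brute-force hand computation", {
  # single instance: softmax of a 1x1 matrix
  m <- tiny_model()
  one <- memory_unit_forward(matrix(c(0.3, -1, 2), 1, 3), m$par[["block1.A1"]])
  expect_equal(one$S, matrix(1, 1, 1))
  expect_equal(one$p, 1)

  # n = 3, d = 2, identity nonlinearity: recompute with explicit loops
  A <- matrix(c(0.5, -0.2, 1.0, 0.3, 0.8, -0.5), 3, 2)
  X <- matrix(c(1, 0, -1, 2, 0.5, 0.2, -0.3, 1.1, 0.7), 3, 3)
  res <- memory_unit_forward(X, A, rho = "identity")
  U <- X %*% A
  G <- U %*% t(U)
  S <- matrix(0, 3, 3)
  for (k in 1:3) S[, k] <- exp(G[, k]) / sum(exp(G[, k]))
  p <- sapply(1:3, function(j) mean(S[j, ]))
  expect_equal(res$S, S, tolerance = 1e-12)
  expect_equal(res$p, p, tolerance = 1e-12)
  expect_equal(sum(res$p), 1, tolerance = 1e-12)
})

test_that("attention is permutation-equivariant and normalized", {
  m <- tiny_model(f = 4, d = 3)
  set.seed(8)
  for (i in 1:25) {
    X <- matrix(rnorm(6 * 4), 6, 4)
    perm <- sample(6)
    r1 <- memory_unit_forward(X, m$par[["block1.A1"]])
    r2 <- memory_unit_forward(X[perm, ], m$par[["block1.A1"]])
    expect_equal(r2$p, r1$p[perm], tolerance = 1e-12)
    expect_equal(sum(r1$p), 1, tolerance = 1e-6)
  }
})

test_that("bijective unit is per-instance and exact at identity init", {
  m <- tiny_model(f = 3, h = 3)
  mi <- mem_init(3, 2, 2, 3, init = "identity")
  X <- matrix(rnorm(12), 4, 3)
  enc <- bijective_forward(X, block_par <- list(
    W_enc = mi$par[["block1.W_enc"]], b_enc = mi$par[["block1.b_enc"]],
    W_dec = mi$par[["block1.W_dec"]], b_dec = mi$par[["block1.b_dec"]]))
  expect_equal(enc$C, X)
  expect_equal(enc$rec_mse, 0)

  # permutation equivariance for a generic encoder
  bp <- list(W_enc = m$par[["block1.W_enc"]], b_enc = m$par[["block1.b_enc"]],
             W_dec = m$par[["block1.W_dec"]], b_dec = m$par[["block1.b_dec"]])
  perm <- c(3, 1, 4, 2)
  expect_equal(bijective_forward(X[perm, ], bp)$C,
               bijective_forward(X, bp)$C[perm, ])
})

test_that("reconstruction loss decreases over early training steps", {
  ok <- vapply(1:10, function(s) {
    model <- mem_init(4, 2, 2, 6, lambda_rec = 1.0, seed = s)
    bags <- tiny_bags(6, n = 6, f = 4, seed = 200 + s)
    cfg <- train_config(lr = 0.05, batch_size = 6, epochs = 1,
                        optimizer = "sgd", seed = s, log_metrics = FALSE)
    rec <- numeric(10)
    for (i in 1:10) {
      rec[i] <- loss_and_grad(model, bags)$rec
      model <- train_local(model, bags, cfg, epoch_offset = i)$model
    }
    rec[10] < rec[1]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("memory block pooling has the stated degenerate behaviour", {
  m <- tiny_model(f = 3, h = 3)
  # n = 1: every pooled row equals the single encoded instance
  X1 <- matrix(c(0.4, -1, 0.3), 1, 3)
  blk <- memory_block_forward(X1, m, 1)
  for (i in seq_len(nrow(blk$xhat)))
    expect_equal(blk$xhat[i, ], blk$C[1, ], tolerance = 1e-12)

  # zero embedding matrices force uniform attention => mean pooling
  mu <- m
  mu$par[["block1.A1"]][] <- 0
  mu$par[["block1.A2"]][] <- 0
  X <- matrix(rnorm(15), 5, 3)
  blk <- memory_block_forward(X, mu, 1)
  expect_equal(blk$P, matrix(1 / 5, 2, 5))
  expect_equal(blk$xhat[1, ], colMeans(blk$C), tolerance = 1e-12)
})

test_that("classification is permutation-invariant and sane at zero head", {
  m <- tiny_model(f = 4, d = 3, h = 5)
  m0 <- m; m0$par[["head.W"]][] <- 0; m0$par[["head.b"]][] <- 0
  bag <- tiny_bags(1, n = 7, f = 4)[[1]]
  expect_equal(unname(classify(bag, m0)), c(0.5, 0.5))

  set.seed(99)
  for (i in 1:50) {
    X <- matrix(rnorm(8 * 4), 8, 4)
    p1 <- classify(X, m)
    p2 <- classify(X[sample(8), ], m)
    expect_lt(max(abs(p1 - p2)), 1e-6)
    expect_equal(sum(p1), 1, tolerance = 1e-9)
  }
  expect_error(classify(matrix(numeric(0), 0, 4), m), "empty")
})

test_that("two memory blocks stack and stay permutation-invariant", {
  m2 <- tiny_model(f = 4, m = 2, d = 2, h = 3, blocks = 2, seed = 9)
  X <- matrix(rnorm(24), 6, 4)
  p1 <- classify(X, m2)
  p2 <- classify(X[c(4, 1, 6, 2, 5, 3), ], m2)
  expect_lt(max(abs(p1 - p2)), 1e-6)
  # block 1 output is a valid input sequence for block 2
  b1 <- memory_block_forward(X, m2, 1)
  b2 <- memory_block_forward(b1$xhat, m2, 2)
  expect_equal(dim(b2$xhat), c(2L, 3L))
})

test_that("gradients match central finite differences", {
  for (case in list(list(blocks = 1, rho = "tanh"),
                    list(blocks = 2, rho = "tanh"),
                    list(blocks = 1, rho = "identity"))) {
    m <- tiny_model(f = 3, m = 2, d = 2, h = 3, blocks = case$blocks,
                    seed = 5, rho = case$rho)
    bags <- tiny_bags(2, n = 4, f = 3, seed = 300)
    lg <- loss_and_grad(m, bags)
    flat <- params_flatten(m); g <- params_flatten(lg$grad)
    h <- 1e-5
    fd <- vapply(seq_along(flat), function(j) {
      fp <- flat; fp[j] <- fp[j] + h
      fm <- flat; fm[j] <- fm[j] - h
      (loss_and_grad(params_unflatten(m, fp), bags)$loss -
         loss_and_grad(params_unflatten(m, fm), bags)$loss) / (2 * h)
    }, numeric(1))
    rel <- abs(fd - g) / pmax(1e-6, abs(fd) + abs(g))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("loss composition behaves as stated", {
  m <- tiny_model()
  bags <- tiny_bags(3, n = 4, f = 3)
  # duplicated batch leaves the mean loss unchanged
  l1 <- loss_and_grad(m, bags)$loss
  l2 <- loss_and_grad(m, c(bags, bags))$loss
  expect_equal(l1, l2, tolerance = 1e-12)
  # lambda_rec = 0 reduces to pure cross-entropy
  m0 <- m; m0$hyper$lambda_rec <- 0
  lg <- loss_and_grad(m0, bags)
  expect_equal(lg$loss, lg$ce)
  expect_error(loss_and_grad(m, list()), "empty")
})

test_that("flatten/unflatten round-trips and checkpoints are bit-exact", {
  m <- tiny_model(f = 5, m = 3, d = 2, h = 4, seed = 77)
  flat <- params_flatten(m)
  back <- params_unflatten(m, flat)
  expect_identical(back$par, m$par)
  expect_error(params_unflatten(m, flat[-1]), "length")

  path <- withr::local_tempfile(fileext = ".json")
  mem_save(m, path)
  loaded <- mem_load(path)
  expect_identical(params_flatten(loaded), flat)
  expect_equal(loaded$hyper$n_units, m$hyper$n_units)
})

test_that("the model fits a separable fixture end to end", {
  bags <- separable_bags(60, f = 8, seed = 42)
  model <- mem_init(8, 2, 4, 8, seed = 3)
  cfg <- train_config(lr = 0.02, batch_size = 8, epochs = 50,
                      optimizer = "sgd", seed = 4, log_metrics = FALSE)
  fit <- train_local(model, bags, cfg)
  expect_gt(evaluate_bags(fit$model, bags)$accuracy, 0.9)
})
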