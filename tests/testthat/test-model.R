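test_that("softmax outputs are normalized and deterministic at inference", {
  spec <- tiny_spec()
  m <- build_network(spec, seed = 5)
  withr::with_seed(6, {
    X <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  })
  X[, , 3] <- X[, , 1]  # duplicate crop
  probs <- predict_probs(m, particle_stack(X))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_identical(probs[1, ], probs[3, ])
  # permutation equivariance
  perm <- c(4, 1, 3, 2)
  probs_p <- predict_probs(m, particle_stack(X[, , perm]))
  expect_equal(probs_p, probs[perm, ], tolerance = 1e-12)
  # empty stack
  expect_length(predict_scores(m, particle_stack(array(0, c(16, 16, 0)))), 0)
})

test_that("analytic gradients agree with finite differences", {
  spec <- tiny_spec(l2 = 1e-3)
  m <- build_network(spec, seed = 7)
  withr::with_seed(8, {
    X <- array(rnorm(16 * 16 * 6), dim = c(16, 16, 6))
  })
  y <- c(1L, 0L, 1L, 1L, 0L, 0L)
  res <- picksieve:::.cnn_loss_grads(m$resolved, m$params, X, y)
  eps <- 1e-5
  for (nm in names(res$grads)) {
    p <- m$params[[nm]]
    idx <- withr::with_seed(9, sample(length(p), min(4, length(p))))
    for (i in idx) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- picksieve:::.cnn_loss_only(m$resolved, pp, X, y)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- picksieve:::.cnn_loss_only(m$resolved, pp, X, y)
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("spec validation rejects malformed architectures", {
  expect_error(network_spec(input_side = 100L), "stage")
  expect_error(
    network_spec(conv_blocks = list(
      list(kernel = c(4L, 3L), filters = c(2L, 2L), pool = "max",
           pool_size = 2L, pool_stride = 2L))),
    "odd"
  )
  expect_error(network_spec(fc_width = 1L), "fc_width")
})

test_that("augmentation transforms preserve pixel statistics", {
  withr::with_seed(10, {
    X <- array(rnorm(12 * 12 * 20), dim = c(12, 12, 20))
  })
  st <- particle_stack(X)
  aug <- augment_stack(st, seed = 11)
  for (i in 1:20) {
    expect_equal(mean(aug$images[, , i]), mean(X[, , i]), tolerance = 1e-12)
    expect_equal(sort(as.numeric(aug$images[, , i])),
                 sort(as.numeric(X[, , i])), tolerance = 0)
    # no transform is the identity
    expect_false(identical(aug$images[, , i], X[, , i]))
  }
  # rotation by 180 degrees twice is the identity
  r180 <- picksieve:::.dihedral_stack(X, rep(2L, 20))
  r360 <- picksieve:::.dihedral_stack(r180, rep(2L, 20))
  expect_equal(r360, X, tolerance = 0)
  # constant image is unchanged under any transform
  const <- array(3, dim = c(8, 8, 7))
  expect_equal(picksieve:::.dihedral_stack(const, 1:7), const, tolerance = 0)
  # non-square input errors
  expect_error(picksieve:::.dihedral_stack(array(0, c(4, 6, 1)), 1L),
               "square")
})

test_that("training separates synthetic blobs from noise", {
  side <- 64L
  pos <- blob_stack(400, side, seed = 21)
  neg <- noise_stack(400, side, seed = 22)
  spec <- network_spec(input_side = side, width_scale = 0.25)
  m <- build_network(spec, seed = 23)
  cfg <- train_config(max_epochs = 4L, eval_every = 5L, seed = 24)
  m <- train_model(m, pos, neg, cfg)
  expect_gt(m$best_val_acc, 0.95)
  # loss decreases over the first epoch
  h <- m$history
  expect_lt(mean(tail(h$loss, 2)), mean(head(h$loss, 2)))
  # mean score of true particles exceeds mean score of negatives on fresh data
  s_pos <- predict_scores(m, blob_stack(50, side, seed = 25))
  s_neg <- predict_scores(m, noise_stack(50, side, seed = 26))
  expect_gt(mean(s_pos), mean(s_neg))
  expect_true(all(s_pos >= 0 & s_pos <= 1))
})

test_that("training is bit-reproducible under a fixed seed", {
  side <- 16L
  pos <- blob_stack(30, side, seed = 31)
  neg <- noise_stack(30, side, seed = 32)
  spec <- tiny_spec(input_side = side)
  cfg <- train_config(max_epochs = 2L, batch_size = 8L, eval_every = 2L,
                      seed = 33)
  m1 <- train_model(build_network(spec, seed = 34), pos, neg, cfg)
  m2 <- train_model(build_network(spec, seed = 34), pos, neg, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  s1 <- predict_scores(m1, pos)
  s2 <- predict_scores(m2, pos)
  expect_identical(s1, s2)
})

test_that("training rejects unusable inputs", {
  side <- 16L
  pos <- blob_stack(30, side, seed = 41)
  spec <- tiny_spec(input_side = side)
  m <- build_network(spec, seed = 1)
  expect_error(train_model(m, pos, noise_stack(5, side, seed = 42)),
               "at least 10")
  expect_error(train_model(m, pos, noise_stack(30, 32L, seed = 43)),
               "side length")
})

test_that("model checkpoints restore scores exactly", {
  side <- 16L
  pos <- blob_stack(20, side, seed = 51)
  neg <- noise_stack(20, side, seed = 52)
  m <- train_model(build_network(tiny_spec(input_side = side), seed = 53),
                   pos, neg,
                   train_config(max_epochs = 1L, batch_size = 8L,
                                eval_every = 2L, seed = 54))
  d <- withr::local_tempdir()
  save_model(m, d)
  m2 <- load_model(d)
  expect_identical(predict_scores(m2, pos), predict_scores(m, pos))
})
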