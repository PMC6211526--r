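# stacks whose crops encode their origin in a constant value, so that
# contamination after swapping is exactly measurable
tagged_stack <- function(n, side, value) {
  particle_stack(array(value, dim = c(side, side, n)))
}

test_that("label swapping preserves sizes and hits the exact fraction", {
  pos <- tagged_stack(100, 4, 1)
  neg <- tagged_stack(100, 4, 0)
  # level 0: identity
  r0 <- corrupt_labels(pos, neg, 0, seed = 1)
  expect_identical(r0$pos$images, pos$images)
  expect_equal(r0$n_swapped, 0L)
  # divisible level: contamination equals the requested fraction exactly
  for (level in c(0.1, 0.25, 0.4, 0.5)) {
    r <- corrupt_labels(pos, neg, level, seed = 2)
    expect_equal(n_particles(r$pos), 100L)
    expect_equal(n_particles(r$neg), 100L)
    frac_pos <- mean(r$pos$images[1, 1, ] == 0)
    frac_neg <- mean(r$neg$images[1, 1, ] == 1)
    expect_equal(frac_pos, level)
    expect_equal(frac_neg, level)
  }
  # swapping is symmetric: nothing is lost
  r5 <- corrupt_labels(pos, neg, 0.5, seed = 3)
  expect_equal(sum(r5$pos$images[1, 1, ]) + sum(r5$neg$images[1, 1, ]), 100)
  expect_error(corrupt_labels(pos, neg, 0.6), "0.5")
})

test_that("corruption is reproducible under a seed", {
  pos <- noise_stack(40, 8, seed = 81)
  neg <- noise_stack(40, 8, seed = 82)
  a <- corrupt_labels(pos, neg, 0.3, seed = 9)
  b <- corrupt_labels(pos, neg, 0.3, seed = 9)
  expect_identical(a$pos$images, b$pos$images)
  expect_identical(a$neg$images, b$neg$images)
})

test_that("experiment config validates its grid", {
  expect_error(corruption_experiment_config(corruption_levels = c(0, 0.7)),
               "0.5")
  expect_error(corruption_experiment_config(train_sizes = 50L), "100")
  cfg <- corruption_experiment_config()
  expect_equal(cfg$corruption_levels, c(0, 0.25, 0.30, 0.40, 0.45, 0.50))
  expect_equal(cfg$train_sizes, c(3000L, 2000L, 1000L, 500L))
})

test_that("the experiment grid trains per cell and reports one row each", {
  side <- 16L
  pool_pos <- blob_stack(260, side, seed = 91)
  pool_neg <- noise_stack(260, side, seed = 92)
  test_pos <- blob_stack(40, side, seed = 93)
  test_neg <- noise_stack(40, side, seed = 94)
  cfg <- corruption_experiment_config(corruption_levels = c(0, 0.5),
                                      train_sizes = c(100L, 150L),
                                      replicates = 1L, seed = 17L)
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- run_corruption_experiment(
    pool_pos, pool_neg, test_pos, test_neg, cfg,
    spec = tiny_spec(input_side = side),
    train_cfg = train_config(initial_lr = 1e-3, max_epochs = 6L,
                             batch_size = 16L, eval_every = 4L),
    csv = f
  )
  expect_equal(nrow(tab), 4L)  # |levels| x |sizes|
  expect_setequal(names(tab), c("level", "size", "mcc", "precision",
                                "recall", "accuracy", "roc_auc", "pr_auc"))
  expect_true(all(is.finite(tab$roc_auc)))
  # the clean cells should dominate the fully corrupted ones
  expect_gt(mean(tab$roc_auc[tab$level == 0]),
            mean(tab$roc_auc[tab$level == 0.5]) - 0.05)
  expect_true(file.exists(f))
  expect_error(
    run_corruption_experiment(pool_pos, pool_neg, test_pos, test_neg,
                              corruption_experiment_config(
                                train_sizes = 1000L),
                              tiny_spec(input_side = side)),
    "exceeds"
  )
})
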