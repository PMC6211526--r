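test_that("intersect_two averages matched pairs and honors the strict radius", {
  cfg <- consensus_config()
  a <- coord_set(data.frame(micrograph = "m1", x = 10, y = 10), 100, "a")
  b <- coord_set(data.frame(micrograph = "m1", x = 14, y = 13), 100, "b")
  res <- intersect_two(a, b, cfg)  # distance 5 < 10
  expect_equal(res$coords$x, 12)
  expect_equal(res$coords$y, 11.5)

  # distance exactly 10% of the box: excluded (strictly smaller required)
  b2 <- coord_set(data.frame(micrograph = "m1", x = 16, y = 18), 100, "b")
  expect_equal(length(intersect_two(a, b2, cfg)), 0L)

  # mismatched box sizes are a configuration error; empty sets are not
  expect_error(intersect_two(a, coord_set(b$coords, 64, "b")), "box size")
  expect_equal(length(intersect_two(a, coord_set(NULL, 100, "e"), cfg)), 0L)
})

test_that("intersect_two equals the brute-force nearest-pair-first oracle", {
  cfg <- consensus_config()
  for (trial in 1:50) {
    withr::with_seed(5000 + trial, {
      a <- random_coords(200, n_mics = 5)
      b <- random_coords(200, n_mics = 5)
    })
    sa <- coord_set(a, 100, "a")
    sb <- coord_set(b, 100, "b")
    got <- intersect_two(sa, sb, cfg)$coords
    radius <- cfg$and_dist_fraction * 100
    want <- oracle_and_two(sa$coords, sb$coords, radius)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(canon(got), canon(want))
    }
  }
})

test_that("compute_and folds left over sets and shrinks cardinality", {
  cfg <- consensus_config()
  s <- coord_set(random_coords(80, n_mics = 2), 64, "p")
  # identical sets: identity
  res <- compute_and(list(s, s, s), cfg)
  expect_equal(length(res), length(s))
  expect_equal(canon(res$coords), canon(s$coords))
  # pairwise-disjoint micrographs: empty
  s2 <- s
  s2$coords$micrograph <- paste0("other_", s2$coords$micrograph)
  expect_equal(length(compute_and(list(s, s2), cfg)), 0L)
  expect_error(compute_and(list(s), cfg), "two")
})

test_that("three jittered pickers reproduce the oracle fold", {
  cfg <- consensus_config()
  withr::with_seed(99, {
    base <- random_coords(150, n_mics = 3, lim = 400)
    jitter <- function(df) {
      df$x <- df$x + rnorm(nrow(df), sd = 2)
      df$y <- df$y + rnorm(nrow(df), sd = 2)
      df[df$x > 0 & df$y > 0, ]
    }
    sets <- lapply(1:3, function(i) coord_set(jitter(base), 64, paste0("p", i)))
  })
  got <- compute_and(sets, cfg)$coords
  radius <- cfg$and_dist_fraction * 64
  want <- oracle_and_two(sets[[1]]$coords, sets[[2]]$coords, radius)
  want <- oracle_and_two(want, sets[[3]]$coords, radius)
  expect_equal(canon(got), canon(want))
})

test_that("compute_or merges near-duplicates to centroids", {
  cfg <- consensus_config()
  a <- coord_set(data.frame(micrograph = "m1", x = 10, y = 10), 100, "a")
  b <- coord_set(data.frame(micrograph = "m1", x = 12, y = 10), 100, "b")
  res <- compute_or(list(a, b), cfg)
  expect_equal(length(res), 1L)
  expect_equal(res$coords$x, 11)
  expect_equal(res$coords$y, 10)
  # a single set without near-duplicates passes through unchanged
  s <- coord_set(random_coords(60, lim = 5000), 10, "s")
  expect_equal(canon(compute_or(list(s), cfg)$coords), canon(s$coords))
})

test_that("compute_or cluster count equals single-linkage components", {
  skip_if_not_installed("igraph")
  cfg <- consensus_config()
  for (trial in 1:20) {
    withr::with_seed(7000 + trial, {
      cc <- random_coords(250, n_mics = 4, lim = 300)
    })
    s <- coord_set(cc, 100, "s")
    got <- compute_or(list(s), cfg)
    radius <- cfg$or_merge_fraction * 100
    n_oracle <- sum(vapply(split(s$coords, s$coords$micrograph), function(m) {
      max(oracle_or_clusters(m, radius))
    }, numeric(1)))
    expect_equal(length(got), n_oracle)
  }
})

test_that("every AND coordinate lies near some OR coordinate", {
  cfg <- consensus_config()
  withr::with_seed(31, {
    sets <- lapply(1:3, function(i) coord_set(random_coords(150), 64, "p"))
  })
  and_set <- compute_and(sets, cfg)
  or_set <- compute_or(sets, cfg)
  radius <- cfg$or_merge_fraction * 64
  ok <- label_against_truth(and_set, or_set, radius = radius + 1e-9)
  expect_true(all(ok))
  expect_lte(length(and_set), min(lengths(lapply(sets, function(s) s$coords$x))))
  expect_lte(length(or_set), sum(vapply(sets, length, integer(1))))
})

test_that("negative candidates obey the strict exclusion rule", {
  oc <- data.frame(micrograph = "m", x = 50, y = 50)
  # distance exactly the exclusion radius: kept (not strictly closer)
  expect_true(picksieve:::neg_candidate_ok_(90, 80, oc, 50))  # d = 50
  expect_false(picksieve:::neg_candidate_ok_(60, 60, oc, 50)) # d ~ 14.14
  expect_true(picksieve:::neg_candidate_ok_(10, 10, NULL, 50))
})

test_that("pick_negatives yields valid, exclusion-respecting, seeded picks", {
  dims <- data.frame(micrograph = c("mic01", "mic02"), width = 400L,
                     height = 400L, stringsAsFactors = FALSE)
  or_set <- coord_set(withr::with_seed(11, random_coords(120, n_mics = 2, lim = 350)),
                      64, "OR")
  cfg <- consensus_config(seed = 17)
  neg <- pick_negatives(dims, or_set, 100, cfg)
  expect_equal(length(neg), 100L)
  excl <- cfg$neg_excl_fraction * 64
  by_mic <- split(or_set$coords, or_set$coords$micrograph)
  viol <- vapply(seq_len(length(neg)), function(i) {
    oc <- by_mic[[neg$coords$micrograph[i]]]
    if (is.null(oc)) return(FALSE)
    any(sqrt((oc$x - neg$coords$x[i])^2 + (oc$y - neg$coords$y[i])^2) < excl)
  }, logical(1))
  expect_equal(sum(viol), 0L)
  # box fully inside the image
  expect_true(all(neg$coords$x >= 32 & neg$coords$x <= 400 - 32))
  # seeded reproducibility
  neg2 <- pick_negatives(dims, or_set, 100, cfg)
  expect_identical(neg$coords, neg2$coords)
  # empty OR set: everything valid
  neg3 <- pick_negatives(dims, coord_set(NULL, 64, "OR"), 50,
                         consensus_config(seed = 3))
  expect_equal(length(neg3), 50L)
})

test_that("pick_negatives returns survivors with a warning when crowded", {
  dims <- data.frame(micrograph = "m1", width = 120L, height = 120L)
  # OR pick dead center of the only valid region: everything is excluded
  or_set <- coord_set(data.frame(micrograph = "m1", x = 60, y = 60), 100, "OR")
  expect_warning(
    neg <- pick_negatives(dims, or_set, 10, consensus_config(seed = 1)),
    "only"
  )
  expect_lt(length(neg), 10L)
})

test_that("zscore_rank flags planted outliers and is stable on ties", {
  # identical crops: all scores zero, ranking is input order
  s <- particle_stack(array(1, dim = c(8, 8, 5)))
  zr <- zscore_rank(s, consensus_config())
  expect_equal(zr$scores, rep(0, 5))
  expect_equal(zr$order, 1:5)
  expect_error(zscore_rank(subset_stack(s, 1)), "two")

  # one high-variance crop among uniform crops ranks first
  withr::with_seed(8, {
    imgs <- array(0, dim = c(8, 8, 10))
    imgs[, , 4] <- matrix(rnorm(64, sd = 5), 8, 8)
  })
  zr2 <- zscore_rank(particle_stack(imgs), consensus_config())
  expect_equal(zr2$order[1], 4L)

  # 1000 crops with 1% mean-shifted outliers: top-1% recall >= 0.9
  withr::with_seed(123, {
    imgs <- array(rnorm(16 * 16 * 1000), dim = c(16, 16, 1000))
    outliers <- sample.int(1000, 10)
    imgs[, , outliers] <- imgs[, , outliers] + 4
  })
  zr3 <- zscore_rank(particle_stack(imgs), consensus_config())
  expect_equal(zr3$n_top, 10L)
  expect_gte(mean(outliers %in% zr3$top), 0.9)
})

test_that("set operations are order-invariant when matches are unambiguous", {
  cfg <- consensus_config()
  withr::with_seed(77, {
    cc <- random_coords(100, n_mics = 2, lim = 800)
  })
  s1 <- coord_set(cc, 50, "a")
  s2 <- coord_set(cc[sample(nrow(cc)), ], 50, "a")
  jit <- cc
  jit$x <- pmax(jit$x + runif(nrow(jit), -1, 1), 0)
  s3 <- coord_set(jit, 50, "b")
  r1 <- intersect_two(s1, s3, cfg)$coords
  r2 <- intersect_two(s2, s3, cfg)$coords
  expect_equal(canon(r1), canon(r2))
  o1 <- compute_or(list(s1, s3), cfg)$coords
  o2 <- compute_or(list(s3, s2), cfg)$coords
  expect_equal(canon(o1), canon(o2))
})
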