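# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately use the most naive algorithm available so
# they stay independent of the package implementation.

# nearest-pair-first one-to-one matcher: repeated full scans of the distance
# matrix (O(n^3)), strict < radius
oracle_match <- function(a, b, radius) {
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  d[d >= radius] <- Inf
  pairs <- matrix(integer(), ncol = 2)
  repeat {
    if (all(!is.finite(d))) break
    ij <- which(d == min(d), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, , drop = FALSE]
    pairs <- rbind(pairs, ij)
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  pairs
}

# AND oracle over full sets: fold of the naive matcher, averaging matches
oracle_and_two <- function(set_a, set_b, radius) {
  mics <- intersect(unique(set_a$micrograph), unique(set_b$micrograph))
  out <- lapply(mics, function(m) {
    a <- set_a[set_a$micrograph == m, , drop = FALSE]
    b <- set_b[set_b$micrograph == m, , drop = FALSE]
    p <- oracle_match(a, b, radius)
    if (nrow(p) == 0) return(NULL)
    data.frame(micrograph = m, x = (a$x[p[, 1]] + b$x[p[, 2]]) / 2,
               y = (a$y[p[, 1]] + b$y[p[, 2]]) / 2)
  })
  do.call(rbind, out)
}

# single-linkage clusters at strict < radius via igraph connected components
oracle_or_clusters <- function(coords, radius) {
  n <- nrow(coords)
  d <- sqrt(outer(coords$x, coords$x, "-")^2 +
              outer(coords$y, coords$y, "-")^2)
  adj <- (d < radius) & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# ROC-auc as exhaustive pairwise concordance probability, ties counted 1/2
oracle_concordance <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# random coordinate table over several micrographs
random_coords <- function(n, n_mics = 3, lim = 500) {
  data.frame(
    micrograph = sample(sprintf("mic%02d", seq_len(n_mics)), n, replace = TRUE),
    x = runif(n, 0, lim), y = runif(n, 0, lim),
    stringsAsFactors = FALSE
  )
}

# sorted (micrograph, x, y) table for set-equality comparisons
canon <- function(df, digits = 9) {
  df <- df[order(df$micrograph, round(df$x, digits), round(df$y, digits)), ]
  rownames(df) <- NULL
  df
}

# small synthetic blob/noise stacks for classifier tests
blob_stack <- function(n, side, seed, noise_sd = 1) {
  withr::with_seed(seed, {
    g <- seq_len(side) - side / 2
    r2 <- outer(g^2, g^2, "+")
    tmpl <- -2 * exp(-(r2 / (side / 4)^2))
    imgs <- vapply(seq_len(n), function(i) {
      standardize_crop(tmpl + matrix(rnorm(side * side, sd = noise_sd),
                                     side, side))
    }, matrix(0, side, side))
    particle_stack(array(imgs, dim = c(side, side, n)))
  })
}

noise_stack <- function(n, side, seed) {
  withr::with_seed(seed, {
    imgs <- vapply(seq_len(n), function(i) {
      standardize_crop(matrix(rnorm(side * side), side, side))
    }, matrix(0, side, side))
    particle_stack(array(imgs, dim = c(side, side, n)))
  })
}

# tiny two-block network spec for fast unit tests
tiny_spec <- function(input_side = 16L, l2 = 0) {
  network_spec(
    input_side = input_side,
    conv_blocks = list(
      list(kernel = c(3L, 3L), filters = c(2L, 2L), pool = "max",
           pool_size = 3L, pool_stride = 2L),
      list(kernel = c(3L, 3L), filters = c(2L, 3L), pool = "avg",
           pool_size = 2L, pool_stride = 2L)
    ),
    fc_width = 4L, dropout_p = 0, l2_strength = l2
  )
}
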