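#' Coordinate sets
#'
#' A `coord_set` holds particle-center coordinates for one or more
#' micrographs together with the box size (the side, in pixels, of the square
#' window that will be cropped around each center). Coordinates are 0-based
#' pixel centers; `x` indexes the first (fastest-varying) image axis.
#'
#' @param coords data frame with columns `micrograph` (character), `x`, `y`
#'   (numeric pixel centers, >= 0).
#' @param box_size particle box side in pixels (one value for the whole set).
#' @param source_label free-text provenance tag (picker name, "AND", "OR",
#'   "NEG", ...).
#' @return An object of class `coord_set`.
#' @export
coord_set <- function(coords, box_size, source_label = "unknown") {
  if (is.null(coords) || nrow(coords) == 0) {
    coords <- data.frame(micrograph = character(), x = numeric(), y = numeric())
  }
  stopifnot(all(c("micrograph", "x", "y") %in% names(coords)))
  coords <- data.frame(
    micrograph = as.character(coords$micrograph),
    x = as.numeric(coords$x),
    y = as.numeric(coords$y),
    stringsAsFactors = FALSE
  )
  if (nrow(coords) && any(coords$x < 0 | coords$y < 0)) {
    stop("coordinates must be non-negative pixel centers")
  }
  if (!is.numeric(box_size) || length(box_size) != 1L || box_size <= 0) {
    stop("box_size must be a single positive number")
  }
  coords <- unique(coords)
  rownames(coords) <- NULL
  structure(
    list(coords = coords, box_size = box_size, source_label = source_label),
    class = "coord_set"
  )
}

#' @export
print.coord_set <- function(x, ...) {
  cat(sprintf(
    "<coord_set '%s': %d coordinates on %d micrograph(s), box %g px>\n",
    x$source_label, nrow(x$coords), length(unique(x$coords$micrograph)),
    x$box_size
  ))
  invisible(x)
}

#' @export
length.coord_set <- function(x) nrow(x$coords)

#' Consensus configuration
#'
#' Distance rules for the consensus coordinate algebra. All fractions are
#' relative to the box size `b`: two picks agree (AND) when their Euclidean
#' distance is strictly smaller than `and_dist_fraction * b`; a random
#' negative is rejected when strictly closer than `neg_excl_fraction * b` to
#' any OR coordinate; OR duplicates are merged below
#' `or_merge_fraction * b`; `zscore_top_fraction` flags the worst-sorted
#' fraction of AND particles as extra negatives.
#'
#' @param and_dist_fraction agreement radius as a fraction of box size.
#' @param neg_excl_fraction exclusion radius for negative picking.
#' @param or_merge_fraction de-duplication radius for the OR set.
#' @param zscore_top_fraction fraction of AND particles flagged by the
#'   outlier sorter as negative-augmentation candidates.
#' @param seed integer seed controlling negative picking; `NULL` uses the
#'   current RNG state.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(and_dist_fraction = 0.10,
                             neg_excl_fraction = 0.50,
                             or_merge_fraction = 0.10,
                             zscore_top_fraction = 0.01,
                             seed = NULL) {
  fr <- c(and_dist_fraction, neg_excl_fraction, or_merge_fraction,
          zscore_top_fraction)
  if (any(fr <= 0) || any(fr > 1)) stop("all fractions must lie in (0, 1]")
  if (and_dist_fraction > neg_excl_fraction) {
    stop("and_dist_fraction must not exceed neg_excl_fraction")
  }
  structure(
    list(and_dist_fraction = and_dist_fraction,
         neg_excl_fraction = neg_excl_fraction,
         or_merge_fraction = or_merge_fraction,
         zscore_top_fraction = zscore_top_fraction,
         seed = seed),
    class = "consensus_config"
  )
}

# Greedy nearest-pair-first one-to-one matching between two point lists.
# Returns a 2-column matrix of (index in a, index in b); each index used at
# most once; candidate pairs require distance strictly < radius. Ties on
# distance are broken by (i, j) order, which makes the result deterministic.
match_greedy_ <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  empty <- matrix(integer(), ncol = 2)
  if (na == 0L || nb == 0L) return(empty)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  cand <- which(d < radius, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  ord <- order(d[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[r] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Intersection (AND) of two coordinate sets
#'
#' Matches coordinates of `set_a` and `set_b` on the same micrograph whose
#' Euclidean distance is strictly smaller than
#' `and_dist_fraction * box_size`; every matched pair contributes its mean
#' coordinate to the result. Matching is greedy nearest-pair-first and
#' one-to-one.
#'
#' @param set_a,set_b `coord_set` objects with equal box size.
#' @param cfg a [consensus_config()].
#' @return A `coord_set` labelled "AND".
#' @export
intersect_two <- function(set_a, set_b, cfg = consensus_config()) {
  stopifnot(inherits(set_a, "coord_set"), inherits(set_b, "coord_set"))
  if (set_a$box_size != set_b$box_size) {
    stop("box sizes differ between input sets")
  }
  radius <- cfg$and_dist_fraction * set_a$box_size
  mics <- intersect(unique(set_a$coords$micrograph),
                    unique(set_b$coords$micrograph))
  out <- lapply(mics, function(m) {
    a <- set_a$coords[set_a$coords$micrograph == m, , drop = FALSE]
    b <- set_b$coords[set_b$coords$micrograph == m, , drop = FALSE]
    mm <- match_greedy_(a$x, a$y, b$x, b$y, radius)
    if (nrow(mm) == 0L) return(NULL)
    data.frame(
      micrograph = m,
      x = (a$x[mm[, 1L]] + b$x[mm[, 2L]]) / 2,
      y = (a$y[mm[, 1L]] + b$y[mm[, 2L]]) / 2,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  coord_set(out, set_a$box_size, "AND")
}

#' Consensus (AND) of two or more coordinate sets
#'
#' Left-fold of [intersect_two()]: the running AND set (whose coordinates are
#' the averages of earlier matches) is intersected with the third set, then
#' the fourth, and so on.
#'
#' @param sets list of two or more `coord_set` objects, equal box size.
#' @param cfg a [consensus_config()].
#' @return A `coord_set` labelled "AND".
#' @export
compute_and <- function(sets, cfg = consensus_config()) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("compute_and needs at least two coordinate sets")
  }
  Reduce(function(a, b) intersect_two(a, b, cfg), sets)
}

# exclusion rule for negative candidates: rejected only when STRICTLY closer
# than the exclusion distance to some OR coordinate of the same micrograph
neg_candidate_ok_ <- function(x, y, or_coords, excl) {
  if (is.null(or_coords) || nrow(or_coords) == 0L) return(TRUE)
  !any(sqrt((or_coords$x - x)^2 + (or_coords$y - y)^2) < excl)
}

# union-find with path halving
uf_find_ <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Union (OR) of coordinate sets
#'
#' Pools all coordinates from all pickers and collapses near-duplicates
#' (same micrograph, distance strictly below `or_merge_fraction * box_size`,
#' single linkage) to their centroid so each physical particle appears once.
#'
#' @param sets list of one or more `coord_set` objects, equal box size.
#' @param cfg a [consensus_config()].
#' @return A `coord_set` labelled "OR".
#' @export
compute_or <- function(sets, cfg = consensus_config()) {
  if (!is.list(sets) || length(sets) < 1L) stop("compute_or needs >= 1 set")
  b <- sets[[1L]]$box_size
  for (s in sets) {
    stopifnot(inherits(s, "coord_set"))
    if (s$box_size != b) stop("box sizes differ between input sets")
  }
  all_coords <- unique(do.call(rbind, lapply(sets, function(s) s$coords)))
  radius <- cfg$or_merge_fraction * b
  out <- lapply(unique(all_coords$micrograph), function(m) {
    cc <- all_coords[all_coords$micrograph == m, , drop = FALSE]
    n <- nrow(cc)
    if (n == 1L) return(cc)
    d <- sqrt(outer(cc$x, cc$x, "-")^2 + outer(cc$y, cc$y, "-")^2)
    pairs <- which(d < radius & upper.tri(d), arr.ind = TRUE)
    parent <- seq_len(n)
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        ri <- uf_find_(parent, pairs[r, 1L])
        rj <- uf_find_(parent, pairs[r, 2L])
        if (ri != rj) parent[rj] <- ri
        # path compression performed lazily inside uf_find_
      }
    }
    root <- vapply(seq_len(n), function(i) uf_find_(parent, i), integer(1))
    data.frame(
      micrograph = m,
      x = as.numeric(tapply(cc$x, root, mean)),
      y = as.numeric(tapply(cc$y, root, mean)),
      stringsAsFactors = FALSE
    )
  })
  coord_set(do.call(rbind, out), b, "OR")
}

#' Random negative coordinates away from all picks
#'
#' Draws up to `n_wanted` box centers uniformly over the valid placement
#' region of the given micrographs, rejecting candidates strictly closer
#' than `neg_excl_fraction * box_size` to any OR coordinate on the same
#' micrograph. Rejection sampling is capped at `50 * n_wanted` attempts;
#' if fewer survive, the survivors are returned with a warning.
#'
#' @param micrograph_dims data frame with columns `micrograph`, `width`,
#'   `height` (pixels).
#' @param or_set `coord_set` of all candidate picks (the OR set).
#' @param n_wanted number of negatives requested.
#' @param cfg a [consensus_config()]; `cfg$seed` makes the draw reproducible.
#' @return A `coord_set` labelled "NEG".
#' @export
pick_negatives <- function(micrograph_dims, or_set, n_wanted,
                           cfg = consensus_config()) {
  stopifnot(inherits(or_set, "coord_set"), n_wanted > 0)
  b <- or_set$box_size
  dims <- micrograph_dims
  stopifnot(all(c("micrograph", "width", "height") %in% names(dims)))
  if (any(dims$width < b | dims$height < b)) {
    stop("some micrographs are smaller than the box size")
  }
  excl <- cfg$neg_excl_fraction * b
  by_mic <- split(or_set$coords, or_set$coords$micrograph)
  with_seed_(cfg$seed, {
    budget <- 50L * as.integer(n_wanted)
    got <- list()
    n_got <- 0L
    attempts <- 0L
    chunk <- max(64L, as.integer(n_wanted))
    while (n_got < n_wanted && attempts < budget) {
      k <- min(chunk, budget - attempts)
      attempts <- attempts + k
      mi <- sample.int(nrow(dims), k, replace = TRUE)
      xs <- runif(k, b / 2, dims$width[mi] - b / 2)
      ys <- runif(k, b / 2, dims$height[mi] - b / 2)
      ok <- vapply(seq_len(k), function(i) {
        neg_candidate_ok_(xs[i], ys[i], by_mic[[dims$micrograph[mi[i]]]], excl)
      }, logical(1))
      if (any(ok)) {
        got[[length(got) + 1L]] <- data.frame(
          micrograph = dims$micrograph[mi[ok]],
          x = xs[ok], y = ys[ok], stringsAsFactors = FALSE
        )
        n_got <- n_got + sum(ok)
      }
    }
    res <- do.call(rbind, got)
    if (!is.null(res) && nrow(res) > n_wanted) {
      res <- res[seq_len(n_wanted), , drop = FALSE]
    }
    if (is.null(res) || nrow(res) < n_wanted) {
      warning(sprintf(
        "pick_negatives: only %d of %d negatives found within attempt budget",
        if (is.null(res)) 0L else nrow(res), n_wanted
      ))
    }
    coord_set(res, b, "NEG")
  })
}

#' Outlier ranking of a particle stack
#'
#' Ranks crops by a standardized-feature outlier score so that the worst
#' particles of a positive set can be recycled as extra negatives. The score
#' is the Euclidean norm of the per-feature z-scores of (crop mean, crop
#' variance, center-vs-edge radial intensity contrast) — a deliberately
#' simple three-feature sorter, documented as such.
#'
#' @param stack a [particle_stack()] with at least two crops.
#' @param cfg a [consensus_config()]; `zscore_top_fraction` sets how many of
#'   the top-ranked (most outlying) crops are flagged.
#' @return list with `order` (indices, most outlying first), `scores`
#'   (aligned with the stack), `top` (the flagged indices) and `n_top`.
#' @export
zscore_rank <- function(stack, cfg = consensus_config()) {
  stopifnot(inherits(stack, "particle_stack"))
  n <- n_particles(stack)
  if (n < 2L) stop("outlier ranking needs at least two crops")
  s <- stack$side_len
  flat <- matrix(stack$images, nrow = s * s, ncol = n)
  mu <- colMeans(flat)
  v <- colMeans(flat^2) - mu^2
  # radial masks: central disc vs outer band
  ctr <- (s - 1) / 2
  r <- sqrt(outer((seq_len(s) - 1 - ctr)^2, (seq_len(s) - 1 - ctr)^2, "+"))
  inner <- as.vector(r <= s / 4)
  outer_band <- as.vector(r >= 0.375 * s)
  contrast <- colMeans(flat[inner, , drop = FALSE]) -
    colMeans(flat[outer_band, , drop = FALSE])
  feats <- cbind(mu, v, contrast)
  z <- apply(feats, 2L, function(f) {
    sdev <- sd(f)
    if (!is.finite(sdev) || sdev == 0) rep(0, length(f)) else (f - mean(f)) / sdev
  })
  scores <- sqrt(rowSums(z^2))
  ord <- order(-scores)  # stable: ties keep input order
  n_top <- ceiling(cfg$zscore_top_fraction * n)
  list(order = ord, scores = scores, top = ord[seq_len(n_top)], n_top = n_top)
}
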