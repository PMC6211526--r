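#' Scored coordinate sets
#'
#' Couples a [coord_set()] (normally the OR set) with classifier scores in
#' \[0, 1\], aligned element-wise.
#'
#' @param coords a [coord_set()].
#' @param scores numeric vector in \[0, 1\], same length as the set.
#' @return An object of class `scored_set`.
#' @export
scored_set <- function(coords, scores) {
  stopifnot(inherits(coords, "coord_set"))
  scores <- as.numeric(scores)
  if (length(scores) != nrow(coords$coords)) {
    stop("scores must align one-to-one with coordinates")
  }
  if (length(scores) && (min(scores) < 0 || max(scores) > 1)) {
    stop("scores must lie in [0, 1]")
  }
  structure(list(coords = coords, scores = scores), class = "scored_set")
}

#' @export
print.scored_set <- function(x, ...) {
  cat(sprintf("<scored_set: %d coordinates, median score %.3f>\n",
              length(x$scores),
              if (length(x$scores)) stats::median(x$scores) else NA))
  invisible(x)
}

#' Prune a scored set at a threshold
#'
#' Splits the scored coordinates into a retained set (score greater than or
#' equal to the threshold — the boundary is inclusive on the retained side)
#' and a pruned set (score below it). Input order is preserved within each
#' output.
#'
#' @param scored a [scored_set()].
#' @param threshold score cutoff in \[0, 1\]; 0.5 is the fully automated
#'   default.
#' @return An object of class `prune_result`: list with `retained` and
#'   `pruned` [coord_set()]s, the aligned `retained_scores` /
#'   `pruned_scores`, and `threshold`.
#' @export
prune_scored <- function(scored, threshold = 0.5) {
  stopifnot(inherits(scored, "scored_set"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  keep <- scored$scores >= threshold
  cc <- scored$coords$coords
  b <- scored$coords$box_size
  structure(
    list(
      retained = coord_set(cc[keep, , drop = FALSE], b, "retained"),
      pruned = coord_set(cc[!keep, , drop = FALSE], b, "pruned"),
      retained_scores = scored$scores[keep],
      pruned_scores = scored$scores[!keep],
      threshold = threshold
    ),
    class = "prune_result"
  )
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("<prune_result: %d retained / %d pruned at threshold %g>\n",
              length(x$retained), length(x$pruned), x$threshold))
  invisible(x)
}

#' Histogram of classifier scores
#'
#' Bin counts over \[0, 1\] for visual threshold selection. Bins are
#' left-closed (`[lo, hi)`), the last bin closing at 1.
#'
#' @param scored a [scored_set()].
#' @param n_bins number of equal-width bins.
#' @return Named integer vector of counts (names are the bin left edges);
#'   counts sum to the number of scores.
#' @export
score_histogram <- function(scored, n_bins = 20L) {
  stopifnot(inherits(scored, "scored_set"), n_bins >= 1L)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(findInterval(scored$scores, edges), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- formatC(edges[-length(edges)], format = "g")
  counts
}
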