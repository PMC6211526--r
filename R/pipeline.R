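#' End-to-end consensus pruning pipeline
#'
#' Runs the whole workflow on in-memory objects: computes the AND, OR and
#' NEG coordinate sets from two or more picker outputs, extracts and
#' normalizes the crops, optionally augments the negatives with the
#' worst-sorted fraction of the AND particles, trains the classifier on
#' AND (positive) vs NEG (negative), scores every OR candidate and prunes
#' at the given threshold.
#'
#' @param micrographs list of [micrograph()] objects.
#' @param picker_sets list of two or more [coord_set()]s (equal box size).
#' @param consensus a [consensus_config()].
#' @param spec a [network_spec()]; its `input_side` sets the crop size.
#' @param train_cfg a [train_config()].
#' @param threshold pruning threshold (0.5 = fully automated default).
#' @param neg_ratio negatives requested per AND positive.
#' @param extra_negatives optional user-supplied [particle_stack()] of
#'   additional negative crops (e.g. hand-picked contamination); merged
#'   into the NEG stack.
#' @param add_zscore_negatives when no `extra_negatives` are given, append
#'   the top `zscore_top_fraction` outliers of the AND stack to the
#'   negatives (the automatic fallback).
#' @param invert_contrast passed to [extract_particles()].
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return list of class `consensus_result` with the coordinate sets, the
#'   stacks, the trained `model`, the `scored` OR set and the `pruning`
#'   [prune_scored()] result.
#' @export
consensus_pipeline <- function(micrographs, picker_sets,
                               consensus = consensus_config(),
                               spec = network_spec(),
                               train_cfg = train_config(),
                               threshold = 0.5, neg_ratio = 1.0,
                               extra_negatives = NULL,
                               add_zscore_negatives = TRUE,
                               invert_contrast = FALSE, seed = 1L) {
  stopifnot(length(picker_sets) >= 2L)
  seed <- as.integer(seed)
  consensus$seed <- seed + 1L
  and_set <- compute_and(picker_sets, consensus)
  or_set <- compute_or(picker_sets, consensus)
  if (length(and_set) < 20L) {
    stop("AND set too small to train on; check picker agreement radii")
  }
  mic_dims <- data.frame(
    micrograph = vapply(micrographs, function(m) m$id, character(1)),
    width = vapply(micrographs, function(m) m$width, integer(1)),
    height = vapply(micrographs, function(m) m$height, integer(1)),
    stringsAsFactors = FALSE
  )
  n_neg <- max(20L, round(neg_ratio * length(and_set)))
  neg_set <- pick_negatives(mic_dims, or_set, n_neg, consensus)
  side <- spec$input_side
  pos_stack <- extract_particles(micrographs, and_set, side, invert_contrast)
  neg_stack <- extract_particles(micrographs, neg_set, side, invert_contrast)
  if (!is.null(extra_negatives)) {
    neg_stack <- bind_stacks(neg_stack, extra_negatives)
  } else if (add_zscore_negatives && n_particles(pos_stack) >= 2L) {
    zr <- zscore_rank(pos_stack, consensus)
    neg_stack <- bind_stacks(neg_stack, subset_stack(pos_stack, zr$top))
  }
  train_cfg$seed <- seed + 2L
  model <- build_network(spec, seed = seed + 3L)
  model <- train_model(model, pos_stack, neg_stack, train_cfg)
  or_stack <- extract_particles(micrographs, or_set, side, invert_contrast)
  kept <- attr(or_stack, "kept")
  or_scored_coords <- coord_set(or_set$coords[kept, , drop = FALSE],
                                or_set$box_size, "OR")
  scored <- scored_set(or_scored_coords, predict_scores(model, or_stack))
  pruning <- prune_scored(scored, threshold)
  structure(
    list(and_set = and_set, or_set = or_set, neg_set = neg_set,
         pos_stack = pos_stack, neg_stack = neg_stack, model = model,
         scored = scored, pruning = pruning, mic_dims = mic_dims,
         threshold = threshold, seed = seed),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    paste0("<consensus_result: |AND| = %d, |OR| = %d, |NEG| = %d; ",
           "%d retained / %d pruned at %g>\n"),
    length(x$and_set), length(x$or_set), length(x$neg_set),
    length(x$pruning$retained), length(x$pruning$pruned), x$threshold
  ))
  invisible(x)
}
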