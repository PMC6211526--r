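#' Extract and normalize particle crops
#'
#' Crops a `box_size x box_size` window centered on every coordinate,
#' resamples it to `side_len x side_len` by area-preserving local-mean
#' down-sampling, optionally inverts contrast, and standardizes each crop to
#' zero mean and unit variance (a constant crop becomes all zeros).
#' Coordinates whose box does not fit inside the micrograph are dropped; the
#' dropped count is reported in the `"n_dropped"` attribute and via a
#' message.
#'
#' @param micrographs a single `micrograph` or a list of them (names are
#'   taken from each object's `id`).
#' @param coord_set a [coord_set()]; its `box_size` defines the crop window.
#' @param side_len output crop side in pixels.
#' @param invert_contrast negate intensities before normalization (useful
#'   when particles are dark on a bright background).
#' @return A [particle_stack()] with attributes `n_dropped` (count) and
#'   `kept` (row indices of `coord_set$coords` that produced a crop, in
#'   order).
#' @export
extract_particles <- function(micrographs, coord_set, side_len = 128L,
                              invert_contrast = FALSE) {
  stopifnot(inherits(coord_set, "coord_set"))
  if (inherits(micrographs, "micrograph")) micrographs <- list(micrographs)
  names(micrographs) <- vapply(micrographs, function(m) m$id, character(1))
  b <- as.integer(round(coord_set$box_size))
  cc <- coord_set$coords
  missing_ids <- setdiff(unique(cc$micrograph), names(micrographs))
  if (length(missing_ids)) {
    stop("coordinates reference unknown micrograph(s): ",
         paste(missing_ids, collapse = ", "))
  }
  n <- nrow(cc)
  crops <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    mic <- micrographs[[cc$micrograph[i]]]
    x0 <- as.integer(round(cc$x[i] - b / 2))
    y0 <- as.integer(round(cc$y[i] - b / 2))
    if (x0 < 0L || y0 < 0L || x0 + b > mic$width || y0 + b > mic$height) next
    win <- mic$pixels[(x0 + 1L):(x0 + b), (y0 + 1L):(y0 + b)]
    if (invert_contrast) win <- -win
    crops[[i]] <- standardize_crop(.area_resample(win, as.integer(side_len)))
    kept[i] <- TRUE
  }
  n_dropped <- n - sum(kept)
  if (n_dropped > 0L) {
    message(sprintf("extract_particles: dropped %d edge coordinate(s)",
                    n_dropped))
  }
  imgs <- array(unlist(crops[kept]), dim = c(side_len, side_len, sum(kept)))
  out <- particle_stack(imgs, NULL, as.integer(side_len))
  attr(out, "n_dropped") <- n_dropped
  attr(out, "kept") <- which(kept)
  out
}

#' Standardize one crop to zero mean, unit variance
#'
#' Uses the population standard deviation; a constant crop maps to all
#' zeros rather than dividing by zero. Idempotent to floating-point
#' accuracy.
#'
#' @param win numeric matrix.
#' @export
standardize_crop <- function(win) {
  mu <- mean(win)
  sdev <- sqrt(mean((win - mu)^2))
  if (!is.finite(sdev) || sdev == 0) {
    matrix(0, nrow(win), ncol(win))
  } else {
    (win - mu) / sdev
  }
}

#' Random flip/rotation augmentation of a stack
#'
#' Applies one independently drawn transform from the dihedral group of the
#' square (identity excluded: rotations by 90/180/270 degrees, horizontal
#' and vertical flips, both diagonal reflections) to every crop.
#'
#' @param stack a [particle_stack()] (square crops by construction).
#' @param seed integer seed; `NULL` uses the current RNG.
#' @return A `particle_stack` of the transformed crops, labels carried over.
#' @export
augment_stack <- function(stack, seed = NULL) {
  stopifnot(inherits(stack, "particle_stack"))
  ops <- with_seed_(seed, sample.int(7L, n_particles(stack), replace = TRUE))
  particle_stack(.dihedral_stack(stack$images, ops), stack$labels,
                 stack$side_len)
}
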