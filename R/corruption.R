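#' Inject mislabeling noise by swapping examples between classes
#'
#' A fraction `level` of each training set is exchanged with examples of
#' the opposite class: `m = round(level * n)` crops (with `n` the smaller
#' class size) move from the positive to the negative stack and vice
#' versa, keeping both set sizes fixed. `level = 0.5` makes each set half
#' wrong — the point of complete label ambiguity — and larger levels are
#' rejected.
#'
#' @param pos_stack,neg_stack [particle_stack()]s.
#' @param level corruption fraction in \[0, 0.5\].
#' @param seed integer seed.
#' @return list with `pos` and `neg` stacks of unchanged sizes, plus
#'   `n_swapped`.
#' @export
corrupt_labels <- function(pos_stack, neg_stack, level, seed = NULL) {
  stopifnot(inherits(pos_stack, "particle_stack"),
            inherits(neg_stack, "particle_stack"))
  if (level < 0 || level > 0.5) {
    stop("corruption level must lie in [0, 0.5]")
  }
  np <- n_particles(pos_stack); nn <- n_particles(neg_stack)
  m <- round(level * min(np, nn))
  if (m == 0L) {
    return(list(pos = pos_stack, neg = neg_stack, n_swapped = 0L))
  }
  with_seed_(seed, {
    ip <- sample.int(np, m)
    iin <- sample.int(nn, m)
    pos_imgs <- pos_stack$images
    neg_imgs <- neg_stack$images
    tmp <- pos_imgs[, , ip, drop = FALSE]
    pos_imgs[, , ip] <- neg_imgs[, , iin, drop = FALSE]
    neg_imgs[, , iin] <- tmp
    list(
      pos = particle_stack(pos_imgs, pos_stack$labels, pos_stack$side_len),
      neg = particle_stack(neg_imgs, neg_stack$labels, neg_stack$side_len),
      n_swapped = m
    )
  })
}

#' Corruption-experiment configuration
#'
#' Grid of mislabeling levels and training-set sizes for the label-noise
#' robustness experiment.
#'
#' @param corruption_levels fractions in \[0, 0.5\].
#' @param train_sizes per-class training-set sizes (each >= 100).
#' @param replicates independent repeats per cell.
#' @param seed integer master seed.
#' @export
corruption_experiment_config <- function(
    corruption_levels = c(0, 0.25, 0.30, 0.40, 0.45, 0.50),
    train_sizes = c(3000L, 2000L, 1000L, 500L),
    replicates = 1L, seed = 1L) {
  if (any(corruption_levels < 0 | corruption_levels > 0.5)) {
    stop("corruption levels must lie in [0, 0.5]")
  }
  if (any(train_sizes < 100L)) stop("train sizes must be >= 100")
  structure(
    list(corruption_levels = corruption_levels,
         train_sizes = as.integer(train_sizes),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "corruption_experiment_config"
  )
}

#' Label-noise robustness experiment
#'
#' For every (corruption level, training size) cell: subsample the clean
#' positive/negative pools to the requested size, swap-corrupt them at the
#' requested level, train a fresh network, and evaluate on the fixed clean
#' held-out test stacks with the full metric battery at the
#' MCC-maximizing threshold. Cells are aggregated over replicates by the
#' median.
#'
#' @param pool_pos,pool_neg clean labelled pools to draw training sets
#'   from.
#' @param test_pos,test_neg clean held-out test stacks (never corrupted).
#' @param cfg a [corruption_experiment_config()].
#' @param spec a [network_spec()] (scaled-down specs keep runtimes short).
#' @param train_cfg a [train_config()].
#' @param csv optional path; when given, the grid is also written as CSV.
#' @return data frame with one row per (level, size):
#'   level, size, mcc, precision, recall, accuracy, roc_auc, pr_auc.
#' @export
run_corruption_experiment <- function(pool_pos, pool_neg, test_pos, test_neg,
                                      cfg = corruption_experiment_config(),
                                      spec = network_spec(),
                                      train_cfg = train_config(),
                                      csv = NULL) {
  np <- n_particles(pool_pos); nn <- n_particles(pool_neg)
  if (max(cfg$train_sizes) > min(np, nn)) {
    stop(sprintf("largest train size %d exceeds pool size %d",
                 max(cfg$train_sizes), min(np, nn)))
  }
  test_labels <- c(rep(1L, n_particles(test_pos)),
                   rep(0L, n_particles(test_neg)))
  test_stack <- bind_stacks(test_pos, test_neg)
  grid <- expand.grid(level = cfg$corruption_levels, size = cfg$train_sizes)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    level <- grid$level[g]; size <- grid$size[g]
    reps <- lapply(seq_len(cfg$replicates), function(r) {
      cell_seed <- cfg$seed + 7919L * g + r
      sub <- with_seed_(cell_seed, list(
        p = sample.int(np, size), n = sample.int(nn, size)
      ))
      cor <- corrupt_labels(subset_stack(pool_pos, sub$p),
                            subset_stack(pool_neg, sub$n),
                            level, seed = cell_seed + 1L)
      tc <- train_cfg
      tc$seed <- cell_seed + 2L
      model <- build_network(spec, seed = cell_seed + 3L)
      model <- train_model(model, cor$pos, cor$neg, tc)
      scores <- predict_scores(model, test_stack)
      rep <- metrics_report(test_labels, scores)
      c(mcc = rep$mcc, precision = rep$precision, recall = rep$recall,
        accuracy = rep$accuracy, roc_auc = rep$roc_auc, pr_auc = rep$pr_auc)
    })
    med <- apply(do.call(rbind, reps), 2L, stats::median)
    data.frame(level = level, size = size, t(med))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) {
    write.table(out, csv, sep = ",", row.names = FALSE, quote = FALSE)
  }
  out
}
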