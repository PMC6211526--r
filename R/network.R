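#' Network architecture specification
#'
#' Describes the particle-classification CNN: four blocks of
#' (convolution + relu, convolution + batch norm + relu, pooling) — max
#' pooling for the first three blocks, average pooling for the last — then
#' one fully connected relu layer with dropout and a two-way softmax
#' output. The defaults give, for 128 x 128 inputs, filter counts
#' 8/8 - 8/16 - 32/32 - 64/64 with kernels 15/15 - 7/7 - 3/3 - 3/3, pools
#' 7/2, 5/2, 3/2 (max) and 4/2 (average), and a 512-unit dense layer.
#'
#' `width_scale` multiplies every filter count and the dense width so that
#' the same topology trains in minutes on a CPU at reduced size; 1 keeps
#' the reference architecture.
#'
#' @param input_side input crop side in pixels; must be divisible by 16
#'   (four stride-2 pooling stages).
#' @param conv_blocks list of blocks, each a list with `kernel` (two odd
#'   kernel sizes), `filters` (two filter counts), `pool` ("max"/"avg"),
#'   `pool_size`, `pool_stride`.
#' @param fc_width dense layer width.
#' @param dropout_p dropout probability after the dense layer.
#' @param l2_strength L2 weight-penalty coefficient applied to every kernel.
#' @param width_scale channel/dense width multiplier for reduced-size runs.
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_side = 128L,
                         conv_blocks = default_conv_blocks(),
                         fc_width = 512L,
                         dropout_p = 0.5,
                         l2_strength = 1e-5,
                         width_scale = 1,
                         bn_momentum = 0.9) {
  input_side <- as.integer(input_side)
  n_blocks <- length(conv_blocks)
  strides <- vapply(conv_blocks, function(b) as.integer(b$pool_stride),
                    integer(1))
  side <- input_side
  for (i in seq_len(n_blocks)) {
    if (side %% strides[i] != 0L) {
      stop(sprintf("input_side %d is not divisible through pooling stage %d",
                   input_side, i))
    }
    side <- side %/% strides[i]
  }
  for (b in conv_blocks) {
    if (any(unlist(b$kernel) %% 2L == 0L)) stop("kernel sizes must be odd")
    if (b$pool_stride < 1L) stop("pool strides must be >= 1")
    if (!b$pool %in% c("max", "avg")) stop("pool must be 'max' or 'avg'")
  }
  if (fc_width < 2L) stop("fc_width must be >= 2")
  stopifnot(dropout_p >= 0, dropout_p < 1, l2_strength >= 0, width_scale > 0)
  structure(
    list(input_side = input_side, conv_blocks = conv_blocks,
         fc_width = as.integer(fc_width), dropout_p = dropout_p,
         l2_strength = l2_strength, width_scale = width_scale,
         bn_momentum = bn_momentum),
    class = "network_spec"
  )
}

#' @rdname network_spec
#' @export
default_conv_blocks <- function() {
  list(
    list(kernel = c(15L, 15L), filters = c(8L, 8L), pool = "max",
         pool_size = 7L, pool_stride = 2L),
    list(kernel = c(7L, 7L), filters = c(8L, 16L), pool = "max",
         pool_size = 5L, pool_stride = 2L),
    list(kernel = c(3L, 3L), filters = c(32L, 32L), pool = "max",
         pool_size = 3L, pool_stride = 2L),
    list(kernel = c(3L, 3L), filters = c(64L, 64L), pool = "avg",
         pool_size = 4L, pool_stride = 2L)
  )
}

# resolve width_scale into concrete filter counts for the C++ backend
resolved_spec_ <- function(spec) {
  ws <- spec$width_scale
  blocks <- lapply(spec$conv_blocks, function(b) {
    list(kernel = as.integer(b$kernel),
         filters = pmax(1L, as.integer(round(b$filters * ws))),
         pool = b$pool, pool_size = as.integer(b$pool_size),
         pool_stride = as.integer(b$pool_stride))
  })
  list(input_side = spec$input_side, conv_blocks = blocks,
       fc_width = max(2L, as.integer(round(spec$fc_width * ws))),
       dropout_p = spec$dropout_p, l2_strength = spec$l2_strength,
       bn_momentum = spec$bn_momentum)
}

#' Layer output shapes of a network
#'
#' Per-layer output shapes of the forward pass (input, every convolution,
#' every pooling stage, dense, softmax), resolved at the spec's
#' `width_scale`.
#'
#' @param spec a [network_spec()].
#' @return data frame with columns `layer` and `shape` (e.g. "128x128x8").
#' @export
network_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shp <- .cnn_shapes(resolved_spec_(spec))
  labels <- c("input")
  for (i in seq_along(spec$conv_blocks)) {
    b <- spec$conv_blocks[[i]]
    labels <- c(labels,
                sprintf("conv%d.1", i), sprintf("conv%d.2+bn", i),
                sprintf("%spool%d", if (b$pool == "max") "max" else "avg", i))
  }
  labels <- c(labels, "dense", "softmax")
  data.frame(
    layer = labels,
    shape = vapply(shp, function(s) paste(s, collapse = "x"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Build an untrained network
#'
#' Initializes all parameters (Glorot-uniform kernels, zero biases,
#' unit-gamma batch norm) for the given architecture.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `cnn_model`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  rs <- resolved_spec_(spec)
  structure(
    list(spec = spec, resolved = rs,
         params = .cnn_init(rs, as.integer(seed)),
         history = NULL, trained = FALSE),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model: input %d px, width_scale %g, %s, %d parameters>\n",
    x$spec$input_side, x$spec$width_scale,
    if (x$trained) "trained" else "untrained", count_parameters(x)
  ))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every trainable tensor (convolution and dense kernels and biases,
#' batch-norm scale and shift); batch-norm running statistics are state,
#' not parameters, and are excluded.
#'
#' @param model a `cnn_model`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  nm <- names(model$params)
  keep <- !grepl("bn_(mean|var)$", nm)
  sum(vapply(model$params[keep], length, integer(1)))
}

#' Training configuration
#'
#' Adam optimization of the two-class cross entropy with a plateau learning
#' rate schedule: when validation accuracy has not improved for
#' `patience_batches` batches the learning rate is divided by
#' `lr_decay_factor`; after the second decay, a further stall of
#' `3 * patience_batches` batches stops training (or `max_epochs` is
#' reached). A stratified `val_fraction` of the training data is held out
#' before training. Each batch is supplemented with `augment_ratio` random
#' flip/rotation copies per original crop.
#'
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay_factor divisor applied at each plateau.
#' @param patience_batches plateau patience, in batches.
#' @param val_fraction fraction held out for validation, in (0, 0.5).
#' @param batch_size originals per batch (augmented copies are added on
#'   top).
#' @param max_epochs hard cap on passes over the training set.
#' @param augment_ratio augmented:original ratio (1 = one copy each).
#' @param eval_every validation-accuracy evaluation interval, in batches.
#' @param seed integer seed for the split, shuffling, augmentation and
#'   dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, lr_decay_factor = 10,
                         patience_batches = 300L, val_fraction = 0.10,
                         batch_size = 32L, max_epochs = 20L,
                         augment_ratio = 1.0, eval_every = 25L, seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 1, patience_batches >= 1,
            val_fraction > 0, val_fraction < 0.5, batch_size >= 1,
            max_epochs >= 1, augment_ratio >= 0, eval_every >= 1)
  structure(
    list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
         patience_batches = as.integer(patience_batches),
         val_fraction = val_fraction, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), augment_ratio = augment_ratio,
         eval_every = as.integer(eval_every), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the classifier on positive and negative stacks
#'
#' @param model an untrained (or previously trained) `cnn_model`.
#' @param pos,neg [particle_stack()]s of positive and negative crops whose
#'   side length equals the model's `input_side`. Each class needs at least
#'   10 examples so the validation split is defined.
#' @param cfg a [train_config()].
#' @return The trained `cnn_model`, with a `history` data frame
#'   (step, lr, loss, val_acc) and `best_val_acc`.
#' @export
train_model <- function(model, pos, neg, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"),
            inherits(pos, "particle_stack"), inherits(neg, "particle_stack"))
  if (pos$side_len != neg$side_len) stop("stack side lengths differ")
  if (pos$side_len != model$spec$input_side) {
    stop(sprintf("stack side %d does not match network input %d",
                 pos$side_len, model$spec$input_side))
  }
  np <- n_particles(pos); nn <- n_particles(neg)
  if (np < 10L || nn < 10L) {
    stop("each class needs at least 10 examples for a defined split")
  }
  s <- pos$side_len
  # stratified validation split, seeded
  split <- with_seed_(cfg$seed, {
    vp <- sample.int(np, max(1L, round(cfg$val_fraction * np)))
    vn <- sample.int(nn, max(1L, round(cfg$val_fraction * nn)))
    list(vp = vp, vn = vn)
  })
  tr_p <- setdiff(seq_len(np), split$vp)
  tr_n <- setdiff(seq_len(nn), split$vn)
  xtr <- array(c(pos$images[, , tr_p], neg$images[, , tr_n]),
               dim = c(s, s, length(tr_p) + length(tr_n)))
  ytr <- c(rep(1L, length(tr_p)), rep(0L, length(tr_n)))
  xval <- array(c(pos$images[, , split$vp], neg$images[, , split$vn]),
                dim = c(s, s, length(split$vp) + length(split$vn)))
  yval <- c(rep(1L, length(split$vp)), rep(0L, length(split$vn)))
  ccfg <- list(initial_lr = cfg$initial_lr,
               lr_decay_factor = cfg$lr_decay_factor,
               patience_batches = cfg$patience_batches,
               batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
               augment_ratio = cfg$augment_ratio,
               eval_every = cfg$eval_every, rng_seed = cfg$seed)
  fit <- .cnn_train(model$resolved, model$params, xtr, ytr, xval, yval, ccfg)
  model$params <- fit$params
  model$history <- as.data.frame(fit$history)
  model$trained <- TRUE
  model$train_cfg <- cfg
  model$best_val_acc <- if (fit$best_val_acc >= 0) fit$best_val_acc else {
    mean((predict_scores(model, particle_stack(xval)) >= 0.5) == (yval == 1L))
  }
  model
}

#' Score particle crops
#'
#' Deterministic inference pass (dropout off, batch norm using running
#' statistics). The score is the softmax probability of the particle class;
#' the two class outputs sum to one.
#'
#' @param model a trained `cnn_model`.
#' @param stack a [particle_stack()] with `side_len` equal to the model
#'   input.
#' @param batch inference batch size.
#' @return Numeric vector of scores in \[0, 1\], aligned with the stack.
#' @export
predict_scores <- function(model, stack, batch = 64L) {
  stopifnot(inherits(model, "cnn_model"), inherits(stack, "particle_stack"))
  if (stack$side_len != model$spec$input_side) {
    stop("stack side length does not match network input")
  }
  if (n_particles(stack) == 0L) return(numeric())
  p <- .cnn_predict(model$resolved, model$params, stack$images,
                    as.integer(batch))
  p[, 2L]
}

#' Class probabilities for particle crops
#'
#' @inheritParams predict_scores
#' @return N x 2 matrix of softmax probabilities (non-particle, particle).
#' @export
predict_probs <- function(model, stack, batch = 64L) {
  stopifnot(inherits(model, "cnn_model"), inherits(stack, "particle_stack"))
  if (n_particles(stack) == 0L) return(matrix(numeric(), ncol = 2L))
  .cnn_predict(model$resolved, model$params, stack$images, as.integer(batch))
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds `spec.json` (architecture and training
#' configuration), `history.csv`, and the learned parameters in the
#' backend's native serialization (`weights.rds`).
#'
#' @param model a `cnn_model`.
#' @param dir checkpoint directory.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "cnn_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    spec = unclass(model$spec), trained = model$trained,
    train_cfg = if (is.null(model$train_cfg)) NULL else unclass(model$train_cfg),
    best_val_acc = model$best_val_acc
  )
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(model$history)) {
    write.table(model$history, file.path(dir, "history.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "spec.json")
  if (!file.exists(meta_path)) stop("no checkpoint at ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  blocks <- lapply(seq_len(nrow_or_len(meta$spec$conv_blocks)), function(i) {
    b <- pick_block_(meta$spec$conv_blocks, i)
    list(kernel = as.integer(b$kernel), filters = as.integer(b$filters),
         pool = b$pool, pool_size = as.integer(b$pool_size),
         pool_stride = as.integer(b$pool_stride))
  })
  spec <- network_spec(
    input_side = meta$spec$input_side, conv_blocks = blocks,
    fc_width = meta$spec$fc_width, dropout_p = meta$spec$dropout_p,
    l2_strength = meta$spec$l2_strength, width_scale = meta$spec$width_scale,
    bn_momentum = meta$spec$bn_momentum
  )
  model <- build_network(spec, seed = 1L)
  model$params <- readRDS(file.path(dir, "weights.rds"))
  model$trained <- isTRUE(meta$trained)
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) {
    model$history <- read.table(hist_path, sep = ",", header = TRUE)
  }
  model$best_val_acc <- meta$best_val_acc
  model
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

pick_block_ <- function(blocks, i) {
  if (is.data.frame(blocks)) {
    list(kernel = blocks$kernel[[i]], filters = blocks$filters[[i]],
         pool = blocks$pool[[i]], pool_size = blocks$pool_size[[i]],
         pool_stride = blocks$pool_stride[[i]])
  } else {
    blocks[[i]]
  }
}
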