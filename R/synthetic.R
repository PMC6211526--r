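#' Synthetic scene configuration
#'
#' Parameters of the synthetic micrograph generator. A scene is a flat
#' background carrying `n_particles` dark multi-lobe particles (soft disc
#' envelope with 2-4 Gaussian lobes of internal structure), optional
#' contaminants (one large smooth carbon-like intensity gradient plus
#' small very-dark ice dots) and white Gaussian noise. The signal-to-noise
#' ratio is defined as the variance of the noiseless signal over the
#' particle support divided by the noise variance — conventions vary, so
#' the definition is fixed here. Planted particle centers are at least one
#' diameter apart so that pick labels are unambiguous.
#'
#' @param width,height micrograph size in pixels.
#' @param n_particles particles planted per micrograph.
#' @param particle_diameter particle diameter in pixels (must be below a
#'   quarter of the smaller image side).
#' @param snr signal-to-noise ratio as defined above.
#' @param contaminant_density ice/carbon artifacts per micrograph.
#' @param seed integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 1024L, height = 1024L, n_particles = 150L,
                         particle_diameter = 40L, snr = 0.3,
                         contaminant_density = 3L, seed = 1L) {
  if (particle_diameter >= min(width, height) / 4) {
    stop("particle_diameter must be below min(width, height) / 4")
  }
  stopifnot(snr > 0, n_particles >= 1, contaminant_density >= 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_particles = as.integer(n_particles),
         particle_diameter = as.integer(particle_diameter), snr = snr,
         contaminant_density = as.integer(contaminant_density),
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# place n points in [lo, hi]^2 with pairwise distance >= min_dist
place_centers_ <- function(n, lo_x, hi_x, lo_y, hi_y, min_dist,
                           max_attempts = 200L * n) {
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
    if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n) {
    stop(sprintf(
      "could only place %d of %d particles with %g px spacing; lower the density",
      length(xs), n, min_dist
    ))
  }
  cbind(xs, ys)
}

# render one multi-lobe particle template into a (2R+1)^2 window
render_particle_ <- function(radius) {
  s <- 2L * radius + 1L
  g <- seq_len(s) - 1 - radius
  r2 <- outer(g^2, g^2, "+")
  envelope <- exp(-(r2 / radius^2)^2)          # soft disc
  n_lobes <- sample(2:4, 1L)
  lobes <- matrix(0, s, s)
  for (k in seq_len(n_lobes)) {
    cx <- runif(1, -0.45, 0.45) * radius
    cy <- runif(1, -0.45, 0.45) * radius
    sig <- runif(1, 0.18, 0.30) * radius
    amp <- runif(1, 0.6, 1.0)
    lobes <- lobes + amp * exp(-(outer((g - cx)^2, (g - cy)^2, "+")) /
                                 (2 * sig^2))
  }
  -(0.6 * envelope + lobes * envelope)          # dark on bright background
}

#' Generate one synthetic micrograph
#'
#' @param cfg a [scene_config()].
#' @param id micrograph identifier for the returned objects.
#' @return list with `micrograph` (a [micrograph()]), `truth` (a
#'   [coord_set()] of the exact planted centers, box size = 1.5 x
#'   particle diameter) and `sigma_noise` (the applied noise s.d.).
#' @export
generate_micrograph <- function(cfg, id = "synthetic_001") {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed_(cfg$seed, {
    W <- cfg$width; H <- cfg$height
    d <- cfg$particle_diameter
    radius <- d / 2
    box <- round(1.5 * d)
    margin <- box / 2 + 1
    img <- matrix(0, W, H)
    centers <- place_centers_(cfg$n_particles, margin, W - margin,
                              margin, H - margin, d)
    Ri <- as.integer(ceiling(radius))
    for (i in seq_len(nrow(centers))) {
      tmpl <- render_particle_(Ri)
      x0 <- as.integer(round(centers[i, 1])) - Ri
      y0 <- as.integer(round(centers[i, 2])) - Ri
      sz <- 2L * Ri + 1L
      img[x0:(x0 + sz - 1L) + 1L, y0:(y0 + sz - 1L) + 1L] <-
        img[x0:(x0 + sz - 1L) + 1L, y0:(y0 + sz - 1L) + 1L] + tmpl
    }
    # particle support mask (for the SNR definition), before contaminants
    support <- img < -0.05
    sig_var <- if (any(support)) var(img[support]) else var(as.numeric(img))
    # contaminants: one large smooth carbon-like gradient + dark ice dots
    if (cfg$contaminant_density > 0L) {
      cx <- runif(1, 0, W); cy <- runif(1, 0, H)
      scale <- 0.35 * min(W, H)
      gx <- (seq_len(W) - cx) / scale
      gy <- (seq_len(H) - cy) / scale
      img <- img - 0.5 * exp(-outer(gx^2, gy^2, "+"))
      n_ice <- cfg$contaminant_density
      ix <- runif(n_ice, margin, W - margin)
      iy <- runif(n_ice, margin, H - margin)
      for (k in seq_len(n_ice)) {
        sig <- runif(1, 2, 5)
        half <- as.integer(ceiling(3 * sig))
        xs <- max(1L, round(ix[k]) - half):min(W, round(ix[k]) + half)
        ys <- max(1L, round(iy[k]) - half):min(H, round(iy[k]) + half)
        img[xs, ys] <- img[xs, ys] -
          3 * exp(-(outer((xs - ix[k])^2, (ys - iy[k])^2, "+")) / (2 * sig^2))
      }
    }
    sigma <- sqrt(sig_var / cfg$snr)
    img <- img + matrix(rnorm(W * H, sd = sigma), W, H)
    truth <- coord_set(
      data.frame(micrograph = id, x = centers[, 1], y = centers[, 2],
                 stringsAsFactors = FALSE),
      box_size = box, source_label = "truth"
    )
    list(micrograph = micrograph(img, id = id), truth = truth,
         sigma_noise = sigma)
  })
}

#' Parametric simulated picker
#'
#' Emulates an automatic particle picker: each true particle is reported
#' with probability `tpr`, displaced by isotropic Gaussian localization
#' error, and `round(fp_density * n_true)` false picks are added uniformly
#' over valid box centers while staying at least one particle diameter away
#' from every true center (so pick labels stay unambiguous).
#'
#' @param tpr true-positive (retention) rate in \[0, 1\].
#' @param fp_density false picks per true particle.
#' @param jitter_sigma localization error s.d. in pixels.
#' @param seed integer seed.
#' @return A list of class `picker_config`.
#' @export
picker_config <- function(tpr = 0.9, fp_density = 0.3, jitter_sigma = 2,
                          seed = 1L) {
  stopifnot(tpr >= 0, tpr <= 1, fp_density >= 0, jitter_sigma >= 0)
  structure(
    list(tpr = tpr, fp_density = fp_density, jitter_sigma = jitter_sigma,
         seed = as.integer(seed)),
    class = "picker_config"
  )
}

#' @rdname picker_config
#' @param truth ground-truth [coord_set()] (planted centers).
#' @param mic_dims data frame `micrograph`, `width`, `height`.
#' @param cfg a `picker_config`.
#' @param particle_diameter diameter used for the false-pick exclusion
#'   zone; defaults to `2/3` of the truth box size (the generator's box is
#'   1.5 diameters).
#' @param source_label picker name recorded on the output set.
#' @return A [coord_set()] of simulated picks.
#' @export
simulate_picker <- function(truth, mic_dims, cfg,
                            particle_diameter = truth$box_size / 1.5,
                            source_label = "simulated_picker") {
  stopifnot(inherits(truth, "coord_set"), inherits(cfg, "picker_config"))
  b <- truth$box_size
  with_seed_(cfg$seed, {
    tc <- truth$coords
    keep <- runif(nrow(tc)) < cfg$tpr
    picked <- tc[keep, , drop = FALSE]
    if (nrow(picked) && cfg$jitter_sigma > 0) {
      picked$x <- picked$x + rnorm(nrow(picked), sd = cfg$jitter_sigma)
      picked$y <- picked$y + rnorm(nrow(picked), sd = cfg$jitter_sigma)
    }
    # clamp jittered picks into the valid placement band
    dim_of <- mic_dims[match(picked$micrograph, mic_dims$micrograph), ]
    picked$x <- pmin(pmax(picked$x, b / 2), dim_of$width - b / 2)
    picked$y <- pmin(pmax(picked$y, b / 2), dim_of$height - b / 2)
    n_fp <- round(cfg$fp_density * nrow(tc))
    fps <- list()
    n_got <- 0L
    attempts <- 0L
    by_mic <- split(tc, tc$micrograph)
    while (n_got < n_fp && attempts < 200L * max(n_fp, 1L)) {
      k <- max(32L, n_fp - n_got)
      attempts <- attempts + k
      mi <- sample.int(nrow(mic_dims), k, replace = TRUE)
      xs <- runif(k, b / 2, mic_dims$width[mi] - b / 2)
      ys <- runif(k, b / 2, mic_dims$height[mi] - b / 2)
      ok <- vapply(seq_len(k), function(i) {
        tt <- by_mic[[mic_dims$micrograph[mi[i]]]]
        if (is.null(tt) || nrow(tt) == 0L) return(TRUE)
        min(sqrt((tt$x - xs[i])^2 + (tt$y - ys[i])^2)) >= particle_diameter
      }, logical(1))
      if (any(ok)) {
        fps[[length(fps) + 1L]] <- data.frame(
          micrograph = mic_dims$micrograph[mi[ok]], x = xs[ok], y = ys[ok],
          stringsAsFactors = FALSE
        )
        n_got <- n_got + sum(ok)
      }
    }
    fp_df <- do.call(rbind, fps)
    if (!is.null(fp_df) && nrow(fp_df) > n_fp) {
      fp_df <- fp_df[seq_len(n_fp), , drop = FALSE]
    }
    coord_set(rbind(picked, fp_df), b, source_label)
  })
}

#' Build a self-contained synthetic benchmark
#'
#' Generates `n_micrographs` micrographs from one scene configuration
#' (per-micrograph seeds derived from the master seed), the pooled ground
#' truth, and one simulated coordinate set per picker. With `dir` set, the
#' bundle is written to disk: MRC micrographs, per-picker TSV coordinate
#' files, ground-truth TSV and a JSON manifest of every configuration and
#' seed.
#'
#' @param scene a [scene_config()]; its `seed` is the master seed.
#' @param n_micrographs number of micrographs to simulate.
#' @param picker_cfgs list of two or more [picker_config()]s.
#' @param dir optional output directory.
#' @return list with `micrographs` (list of [micrograph()]), `truth`
#'   (pooled [coord_set()]), `picker_sets` (list of [coord_set()]),
#'   `mic_dims` (data frame), `scene`, and `dir` when written.
#' @export
make_benchmark <- function(scene, n_micrographs = 2L, picker_cfgs,
                           dir = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (length(picker_cfgs) < 2L) stop("need at least two pickers")
  mics <- list()
  truths <- list()
  for (i in seq_len(n_micrographs)) {
    cfg_i <- scene
    cfg_i$seed <- scene$seed + 1000L * i
    gen <- generate_micrograph(cfg_i, id = sprintf("synthetic_%03d", i))
    mics[[i]] <- gen$micrograph
    truths[[i]] <- gen$truth
  }
  truth <- coord_set(do.call(rbind, lapply(truths, function(t) t$coords)),
                     truths[[1L]]$box_size, "truth")
  mic_dims <- data.frame(
    micrograph = vapply(mics, function(m) m$id, character(1)),
    width = vapply(mics, function(m) m$width, integer(1)),
    height = vapply(mics, function(m) m$height, integer(1)),
    stringsAsFactors = FALSE
  )
  picker_sets <- lapply(seq_along(picker_cfgs), function(j) {
    pc <- picker_cfgs[[j]]
    pc$seed <- pc$seed + scene$seed * 10L + j
    simulate_picker(truth, mic_dims, pc,
                    source_label = sprintf("picker_%d", j))
  })
  out <- list(micrographs = mics, truth = truth, picker_sets = picker_sets,
              mic_dims = mic_dims, scene = scene)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (m in mics) write_micrograph(m, file.path(dir, paste0(m$id, ".mrc")))
    write_coords_tsv(truth, file.path(dir, "truth.tsv"))
    for (j in seq_along(picker_sets)) {
      write_coords_tsv(picker_sets[[j]],
                       file.path(dir, sprintf("picker_%d.tsv", j)))
    }
    manifest <- list(
      scene = unclass(scene), n_micrographs = n_micrographs,
      pickers = lapply(picker_cfgs, unclass),
      box_size = truth$box_size, n_truth = length(truth)
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}

#' Label picks against the ground truth
#'
#' A pick counts as a true particle when some planted center on the same
#' micrograph lies strictly within `radius`. Because simulated false picks
#' keep one diameter away from every true center, any radius between the
#' jitter scale and the diameter gives unambiguous labels.
#'
#' @param set a [coord_set()] of picks.
#' @param truth ground-truth [coord_set()].
#' @param radius match radius in pixels; default half the particle
#'   diameter implied by the truth box.
#' @return Logical vector aligned with `set`.
#' @export
label_against_truth <- function(set, truth,
                                radius = truth$box_size / 3) {
  stopifnot(inherits(set, "coord_set"), inherits(truth, "coord_set"))
  by_mic <- split(truth$coords, truth$coords$micrograph)
  cc <- set$coords
  vapply(seq_len(nrow(cc)), function(i) {
    tt <- by_mic[[cc$micrograph[i]]]
    if (is.null(tt) || nrow(tt) == 0L) return(FALSE)
    min(sqrt((tt$x - cc$x[i])^2 + (tt$y - cc$y[i])^2)) < radius
  }, logical(1))
}
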