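small_scene <- function(seed = 1L) {
  scene_config(width = 320L, height = 320L, n_particles = 12L,
               particle_diameter = 30L, snr = 2, contaminant_density = 1L,
               seed = seed)
}

test_that("generation is bit-reproducible and respects spacing", {
  g1 <- generate_micrograph(small_scene(5), id = "m")
  g2 <- generate_micrograph(small_scene(5), id = "m")
  expect_identical(g1$micrograph$pixels, g2$micrograph$pixels)
  expect_identical(g1$truth$coords, g2$truth$coords)
  cc <- g1$truth$coords
  d <- sqrt(outer(cc$x, cc$x, "-")^2 + outer(cc$y, cc$y, "-")^2)
  diag(d) <- Inf
  expect_gte(min(d), 30)
  expect_error(
    generate_micrograph(scene_config(width = 320L, height = 320L,
                                     n_particles = 400L,
                                     particle_diameter = 30L, seed = 2)),
    "density"
  )
})

test_that("noise-free particles peak within a pixel of their centers", {
  cfg <- small_scene(7)
  cfg$snr <- 1e9  # effectively noiseless
  cfg$contaminant_density <- 0L
  g <- generate_micrograph(cfg, id = "m")
  px <- g$micrograph$pixels
  for (i in seq_len(nrow(g$truth$coords))) {
    x <- g$truth$coords$x[i]; y <- g$truth$coords$y[i]
    r <- 8L
    win <- px[(round(x) - r):(round(x) + r) + 1L,
              (round(y) - r):(round(y) + r) + 1L]
    # particles are dark: the darkest pixel marks the particle body
    peak <- which(win == min(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - (r + 1L))), 8)
  }
})

test_that("empirical variance decomposes into signal plus noise at snr 1", {
  # independence of signal and noise: var(noisy) = var(clean) + sigma^2.
  # The same seed replays identical placements/templates; snr = 1e12 makes
  # the injected noise negligible, exposing the clean image.
  rel_err <- vapply(1:20, function(s) {
    cfg <- scene_config(width = 256L, height = 256L, n_particles = 8L,
                        particle_diameter = 28L, snr = 1,
                        contaminant_density = 0L, seed = 100L + s)
    clean_cfg <- cfg
    clean_cfg$snr <- 1e12
    g_clean <- generate_micrograph(clean_cfg, id = "m")
    g_noisy <- generate_micrograph(cfg, id = "m")
    v_clean <- var(as.numeric(g_clean$micrograph$pixels))
    v_noisy <- var(as.numeric(g_noisy$micrograph$pixels))
    (v_noisy - (v_clean + g_noisy$sigma_noise^2)) /
      (v_clean + g_noisy$sigma_noise^2)
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.05)
})

test_that("simulated pickers reproduce their configuration", {
  g <- generate_micrograph(small_scene(9), id = "m")
  dims <- data.frame(micrograph = "m", width = 320L, height = 320L)
  # identity picker
  p_id <- simulate_picker(g$truth, dims,
                          picker_config(tpr = 1, fp_density = 0,
                                        jitter_sigma = 0, seed = 3))
  expect_equal(canon(p_id$coords), canon(g$truth$coords))
  # pure false-positive picker
  p_fp <- simulate_picker(g$truth, dims,
                          picker_config(tpr = 0, fp_density = 0.5,
                                        jitter_sigma = 0, seed = 4))
  expect_equal(length(p_fp), round(0.5 * length(g$truth)))
  expect_true(all(!label_against_truth(p_fp, g$truth)))
})

test_that("retention rate concentrates at the configured tpr", {
  grid <- seq(40, 970, by = 30)
  truth <- coord_set(
    data.frame(micrograph = "m",
               x = rep(grid, times = length(grid)),
               y = rep(grid, each = length(grid)))[1:1000, ],
    60, "truth"
  )
  dims <- data.frame(micrograph = "m", width = 1000L, height = 1000L)
  fracs <- vapply(1:50, function(s) {
    p <- simulate_picker(truth, dims,
                         picker_config(tpr = 0.8, fp_density = 0,
                                       jitter_sigma = 0, seed = s))
    length(p) / length(truth)
  }, numeric(1))
  expect_equal(mean(fracs), 0.8, tolerance = 0.03)
})

test_that("benchmarks are reproducible and consensus beats single pickers", {
  scene <- scene_config(width = 512L, height = 512L, n_particles = 40L,
                        particle_diameter = 30L, snr = 1, seed = 42L)
  pickers <- list(picker_config(tpr = 0.9, fp_density = 0.3, jitter_sigma = 2),
                  picker_config(tpr = 0.8, fp_density = 0.3, jitter_sigma = 2))
  b1 <- make_benchmark(scene, n_micrographs = 3L, pickers)
  b2 <- make_benchmark(scene, n_micrographs = 3L, pickers)
  expect_identical(b1$truth$coords, b2$truth$coords)
  expect_identical(b1$picker_sets[[1]]$coords, b2$picker_sets[[1]]$coords)
  expect_identical(b1$micrographs[[2]]$pixels, b2$micrographs[[2]]$pixels)

  and_set <- compute_and(b1$picker_sets)
  prec <- vapply(b1$picker_sets, function(s)
    mean(label_against_truth(s, b1$truth)), numeric(1))
  prec_and <- mean(label_against_truth(and_set, b1$truth))
  expect_gte(prec_and, max(prec))
  # OR recall >= each picker's recall
  or_set <- compute_or(b1$picker_sets)
  rec <- vapply(c(b1$picker_sets, list(or_set)), function(s) {
    hits <- label_against_truth(b1$truth, s, radius = b1$truth$box_size / 3)
    mean(hits)
  }, numeric(1))
  expect_gte(rec[3], max(rec[1:2]))
})

test_that("a written benchmark bundle is complete and readable", {
  d <- withr::local_tempdir()
  scene <- scene_config(width = 320L, height = 320L, n_particles = 10L,
                        particle_diameter = 30L, snr = 1, seed = 8L)
  b <- make_benchmark(scene, n_micrographs = 2L,
                      list(picker_config(seed = 1), picker_config(seed = 2)),
                      dir = d)
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  truth_back <- read_coords_tsv(file.path(d, "truth.tsv"), b$truth$box_size)
  expect_equal(length(truth_back), length(b$truth))
  mic_back <- read_micrograph(file.path(d, "synthetic_001.mrc"))
  expect_equal(mic_back$pixels, b$micrographs[[1]]$pixels, tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$n_truth, length(b$truth))
})
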