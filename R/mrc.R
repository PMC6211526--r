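#' MRC2014 image input/output
#'
#' Minimal reader and writer for the MRC2014 format used for micrographs and
#' particle stacks. Reading supports the real-valued modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16); writing always uses mode 2.
#' Pixel data are stored column-major with the x axis fastest, so a
#' micrograph's pixels are an R matrix indexed `[x + 1, y + 1]` with
#' `nrow = width`.
#'
#' @name mrc_io
NULL

MRC_HEADER_BYTES <- 1024L

read_mrc_header_ <- function(con) {
  ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  floats1 <- readBin(con, "numeric", n = 6L, size = 4L, endian = "little")
  ints2 <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  floats2 <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  ints3 <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  extra <- readBin(con, "integer", n = 25L, size = 4L, endian = "little")
  origin <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  map <- readChar(con, 4L, useBytes = TRUE)
  machst <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  rms <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", n = 800L))
  list(
    nx = ints[1L], ny = ints[2L], nz = ints[3L], mode = ints[4L],
    mx = ints[8L], my = ints[9L], mz = ints[10L],
    cella = floats1[1:3], mapc = ints2[1L], mapr = ints2[2L],
    maps = ints2[3L], dmin = floats2[1L], dmax = floats2[2L],
    dmean = floats2[3L], ispg = ints3[1L], nsymbt = ints3[2L],
    origin = origin, map = map, rms = rms, nlabl = nlabl
  )
}

read_mrc_data_ <- function(con, hdr) {
  n <- hdr$nx * hdr$ny * hdr$nz
  vals <- switch(as.character(hdr$mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"),
    stop(sprintf("unsupported MRC mode %d (only 0/1/2/6 are readable)",
                 hdr$mode))
  )
  if (length(vals) < n) stop("truncated MRC file: fewer voxels than header declares")
  as.numeric(vals)
}

write_mrc_ <- function(path, data, nx, ny, nz, pixel_size = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * pixel_size), con, size = 4L,
           endian = "little")                       # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  stats <- if (length(data)) c(min(data), max(data), mean(data)) else c(0, 0, 0)
  writeBin(as.numeric(stats), con, size = 4L, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4L, endian = "little")  # ispg, nsymbt
  writeBin(integer(25L), con, size = 4L, endian = "little")           # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little") # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.integer(c(0x44L, 0x44L, 0x00L, 0x00L)), con, size = 1L)
  rms <- if (length(data) > 1L) sd(data) else 0
  writeBin(as.numeric(rms), con, size = 4L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little")                     # nlabl
  label <- charToRaw(formatC("picksieve", width = 80L, flag = "-"))
  writeBin(c(label, raw(800L - length(label))), con)
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname mrc_io
#' @param path an MRC file path.
#' @param id micrograph identifier; defaults to the file stem.
#' @return `read_micrograph` returns a `micrograph` object: list with `id`,
#'   `pixels` (width x height matrix), `width`, `height`, `pixel_size`.
#' @export
read_micrograph <- function(path, id = sub("\\.mrcs?$", "", basename(path))) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  if (file.size(path) < MRC_HEADER_BYTES) {
    stop("truncated MRC file (shorter than the 1024-byte header): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_mrc_header_(con)
  if (hdr$nz > 1L) {
    stop(sprintf("'%s' is a %d-section stack, not a single micrograph",
                 path, hdr$nz))
  }
  vals <- read_mrc_data_(con, hdr)
  pixel_size <- if (hdr$mx > 0) hdr$cella[1L] / hdr$mx else NA_real_
  micrograph(matrix(vals, nrow = hdr$nx, ncol = hdr$ny), id = id,
             pixel_size = pixel_size)
}

#' @rdname mrc_io
#' @param pixels width x height numeric matrix (x fastest).
#' @param pixel_size physical pixel size in angstroms (metadata only).
#' @export
micrograph <- function(pixels, id = "micrograph", pixel_size = NA_real_) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  structure(
    list(id = id, pixels = pixels, width = nrow(pixels),
         height = ncol(pixels), pixel_size = pixel_size),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s': %d x %d px>\n", x$id, x$width, x$height))
  invisible(x)
}

#' @rdname mrc_io
#' @param mic a `micrograph` object.
#' @export
write_micrograph <- function(mic, path) {
  stopifnot(inherits(mic, "micrograph"))
  ps <- if (is.na(mic$pixel_size)) 1 else mic$pixel_size
  write_mrc_(path, as.numeric(mic$pixels), mic$width, mic$height, 1L, ps)
  invisible(path)
}

#' Particle stacks
#'
#' A `particle_stack` is a set of N square single-channel crops stored as a
#' `side_len x side_len x N` array, optionally with binary labels
#' (1 = particle, 0 = non-particle).
#'
#' @param images numeric array `side x side x N` (a single matrix is
#'   promoted to N = 1).
#' @param labels optional integer vector of 0/1, length N.
#' @param side_len crop side in pixels; inferred from `images` when omitted.
#' @return An object of class `particle_stack`.
#' @export
particle_stack <- function(images, labels = NULL, side_len = NULL) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  if (length(dim(images)) != 3L || dim(images)[1L] != dim(images)[2L]) {
    stop("images must be a side x side x N array of square crops")
  }
  if (!all(is.finite(images))) stop("crops contain non-finite values")
  if (is.null(side_len)) side_len <- dim(images)[1L]
  if (side_len != dim(images)[1L]) stop("side_len does not match images")
  n <- dim(images)[3L]
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels length must equal crop count")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  }
  structure(list(images = images, labels = labels, side_len = side_len),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack: %d crops of %d x %d px%s>\n",
              n_particles(x), x$side_len, x$side_len,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Number of crops in a particle stack
#' @param stack a [particle_stack()].
#' @export
n_particles <- function(stack) dim(stack$images)[3L]

#' Concatenate particle stacks
#' @param ... [particle_stack()] objects with equal side length.
#' @return A single `particle_stack`; labels are kept only if every input
#'   carries them.
#' @export
bind_stacks <- function(...) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 1L)
  s <- stacks[[1L]]$side_len
  if (any(vapply(stacks, function(x) x$side_len, numeric(1)) != s)) {
    stop("side lengths differ")
  }
  imgs <- array(unlist(lapply(stacks, function(x) x$images)),
                dim = c(s, s, sum(vapply(stacks, n_particles, integer(1)))))
  labs <- lapply(stacks, function(x) x$labels)
  labels <- if (any(vapply(labs, is.null, logical(1)))) NULL else unlist(labs)
  particle_stack(imgs, labels, s)
}

#' Subset a particle stack
#' @param stack a [particle_stack()].
#' @param idx integer indices of the crops to keep.
#' @export
subset_stack <- function(stack, idx) {
  particle_stack(stack$images[, , idx, drop = FALSE],
                 if (is.null(stack$labels)) NULL else stack$labels[idx],
                 stack$side_len)
}

#' @rdname mrc_io
#' @param stack a [particle_stack()].
#' @return `write_particle_stack` writes an MRC stack plus, when labels are
#'   present, a sidecar TSV `<path>.labels.tsv` of `index<TAB>label`.
#' @export
write_particle_stack <- function(stack, path) {
  stopifnot(inherits(stack, "particle_stack"))
  s <- stack$side_len
  write_mrc_(path, as.numeric(stack$images), s, s, n_particles(stack))
  sidecar <- paste0(path, ".labels.tsv")
  if (!is.null(stack$labels)) {
    write.table(
      data.frame(seq_along(stack$labels), stack$labels), sidecar,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  invisible(path)
}

#' @rdname mrc_io
#' @export
read_particle_stack <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_mrc_header_(con)
  if (hdr$nx != hdr$ny) stop("particle stack crops must be square")
  vals <- read_mrc_data_(con, hdr)
  imgs <- array(vals, dim = c(hdr$nx, hdr$ny, hdr$nz))
  sidecar <- paste0(path, ".labels.tsv")
  labels <- NULL
  if (file.exists(sidecar)) {
    tab <- read.table(sidecar, sep = "\t", header = FALSE)
    labels <- as.integer(tab[[2L]][order(tab[[1L]])])
  }
  particle_stack(imgs, labels, hdr$nx)
}
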