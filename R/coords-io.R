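#' Read and write coordinate files
#'
#' Three dialects are supported:
#' * **TSV**: one header-less file, lines `micrograph<TAB>x<TAB>y`
#'   (floats allowed); an optional fourth `score` column is written by
#'   [write_scored_tsv()].
#' * **EMAN BOX**: one file per micrograph named `<micrograph>.box`, lines
#'   `x_corner<TAB>y_corner<TAB>b<TAB>b`. Corner coordinates are converted
#'   to centers on read (`corner + b/2`) and back on write.
#' * **minimal STAR**: one file per micrograph named `<micrograph>.star`
#'   with a `data_` block and a `loop_` over at least `_rlnCoordinateX` and
#'   `_rlnCoordinateY`; unknown tags are preserved on round-trip.
#'
#' @param path file path (TSV) or directory (BOX/STAR).
#' @param box_size particle box size in pixels.
#' @param source_label provenance tag for the returned set.
#' @return `read_*` return a [coord_set()]; `write_*` return the written
#'   path(s), invisibly.
#' @name coord_io
NULL

#' @rdname coord_io
#' @export
read_coords_tsv <- function(path, box_size, source_label = basename(path)) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw)) {
    return(coord_set(NULL, box_size, source_label))
  }
  if (ncol(raw) < 3L) stop("TSV dialect needs >= 3 columns in ", path)
  coord_set(
    data.frame(micrograph = as.character(raw[[1L]]), x = raw[[2L]],
               y = raw[[3L]], stringsAsFactors = FALSE),
    box_size, source_label
  )
}

#' @rdname coord_io
#' @param set a [coord_set()] to write.
#' @export
write_coords_tsv <- function(set, path) {
  stopifnot(inherits(set, "coord_set"))
  write.table(set$coords, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname coord_io
#' @param scored a [scored_set()] to write (adds a 4th score column).
#' @export
write_scored_tsv <- function(scored, path) {
  stopifnot(inherits(scored, "scored_set"))
  df <- scored$coords$coords
  df$score <- scored$scores
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname coord_io
#' @export
read_coords_box <- function(path, box_size, source_label = basename(path)) {
  files <- list.files(path, pattern = "\\.box$", full.names = TRUE)
  if (length(files) == 0L) stop("no .box files under ", path)
  rows <- lapply(files, function(f) {
    mic <- sub("\\.box$", "", basename(f))
    raw <- read.table(f, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 4L) stop("BOX dialect needs 4 columns in ", f)
    b <- raw[[3L]]
    data.frame(micrograph = mic, x = raw[[1L]] + b / 2, y = raw[[2L]] + b / 2,
               stringsAsFactors = FALSE)
  })
  coord_set(do.call(rbind, rows), box_size, source_label)
}

#' @rdname coord_io
#' @param dir output directory (one file per micrograph is written).
#' @export
write_coords_box <- function(set, dir) {
  stopifnot(inherits(set, "coord_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- set$box_size
  paths <- vapply(split(set$coords, set$coords$micrograph), function(cc) {
    f <- file.path(dir, paste0(cc$micrograph[1L], ".box"))
    write.table(
      data.frame(cc$x - b / 2, cc$y - b / 2, b, b),
      f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    f
  }, character(1))
  invisible(unname(paths))
}

# parse one minimal STAR file: returns data.frame of the loop_ columns
parse_star_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  i_loop <- which(lines == "loop_")
  if (length(i_loop) == 0L) stop("no loop_ block in ", path)
  i <- i_loop[1L] + 1L
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("^(_\\S+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  if (length(tags) == 0L) stop("loop_ without tags in ", path)
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "data_") &
                 !startsWith(body, "#")]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(numeric(), ncol = length(tags)))
    names(df) <- tags
    return(df)
  }
  fields <- strsplit(body, "\\s+")
  if (any(lengths(fields) != length(tags))) {
    stop("STAR row width does not match tag count in ", path)
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- tags
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

#' @rdname coord_io
#' @export
read_coords_star <- function(path, box_size, source_label = basename(path)) {
  files <- list.files(path, pattern = "\\.star$", full.names = TRUE)
  if (length(files) == 0L) stop("no .star files under ", path)
  extras <- list()
  rows <- lapply(files, function(f) {
    mic <- sub("\\.star$", "", basename(f))
    df <- parse_star_(f)
    need <- c("_rlnCoordinateX", "_rlnCoordinateY")
    if (!all(need %in% names(df))) {
      stop("missing _rlnCoordinateX/_rlnCoordinateY in ", f)
    }
    extras[[mic]] <<- df[setdiff(names(df), need)]
    data.frame(micrograph = mic, x = df$`_rlnCoordinateX`,
               y = df$`_rlnCoordinateY`, stringsAsFactors = FALSE)
  })
  out <- coord_set(do.call(rbind, rows), box_size, source_label)
  attr(out, "star_extras") <- extras
  out
}

#' @rdname coord_io
#' @export
write_coords_star <- function(set, dir) {
  stopifnot(inherits(set, "coord_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  extras <- attr(set, "star_extras")
  paths <- vapply(split(set$coords, set$coords$micrograph), function(cc) {
    mic <- cc$micrograph[1L]
    f <- file.path(dir, paste0(mic, ".star"))
    df <- data.frame(`_rlnCoordinateX` = cc$x, `_rlnCoordinateY` = cc$y,
                     check.names = FALSE)
    ex <- extras[[mic]]
    if (!is.null(ex) && ncol(ex) > 0L && nrow(ex) == nrow(df)) {
      df <- cbind(df, ex)
    }
    con <- file(f, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("", "data_", "", "loop_",
                 sprintf("%s #%d", names(df), seq_along(df))), con)
    writeLines(apply(df, 1L, function(r) paste(r, collapse = "\t")), con)
    f
  }, character(1))
  invisible(unname(paths))
}
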