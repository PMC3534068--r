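# Readers and writers: grayscale PNG/PGM frame stacks, YAML configs,
# CSV field exports and JSON run manifests.

#' Load a frame stack from image files
#'
#' Reads two or more grayscale PNG or PGM frames (8- or 16-bit; RGB inputs
#' are converted by the channel average) into a [frame_stack()]. Frames are
#' sorted by their zero-padded numeric file names.
#'
#' @param path a directory containing frames, a glob pattern, or a
#'   character vector of files.
#' @return a [frame_stack()].
#' @export
load_frames <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.(png|pgm)$", full.names = TRUE,
               ignore.case = TRUE)
  } else if (length(path) == 1 && grepl("[*?]", path)) {
    Sys.glob(path)
  } else {
    path
  }
  files <- sort(files)
  if (length(files) < 2) {
    stop("need at least 2 readable frames, found ", length(files))
  }
  mats <- lapply(files, read_gray_image)
  d1 <- dim(mats[[1]])
  for (i in seq_along(mats)) {
    if (!all(dim(mats[[i]]) == d1)) {
      stop(sprintf("mixed frame sizes: '%s' is %dx%d, expected %dx%d",
                   files[i], dim(mats[[i]])[1], dim(mats[[i]])[2],
                   d1[1], d1[2]))
    }
  }
  out <- array(0, c(d1[1], d1[2], length(mats)))
  for (i in seq_along(mats)) out[, , i] <- mats[[i]]
  frame_stack(out)
}

# Read one grayscale image ([0,1] matrix) from PNG or PGM.
read_gray_image <- function(file) {
  if (!file.exists(file)) stop("unreadable file: ", file)
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    img <- png::readPNG(file)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE],
                                            c(1, 2), mean)
    img
  } else if (ext == "pgm") {
    read_pgm(file)
  } else {
    stop("unsupported image format: ", file)
  }
}

# Minimal PGM reader (P2 ASCII and P5 binary, 8/16-bit), scaled to [0,1].
read_pgm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PGM: ", file)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", file)
  W <- as.integer(token()); H <- as.integer(token())
  maxval <- as.integer(token())
  n <- W * H
  vals <- if (magic == "P2") {
    as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else if (maxval < 256) {
    as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                       endian = "big"))
  }
  if (length(vals) < n) stop("truncated PGM: ", file)
  matrix(vals / maxval, H, W, byrow = TRUE)
}

#' Write a frame stack as numbered images
#'
#' @param frames a [frame_stack()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param format `"png"` (8-bit grayscale) or `"pgm"` (P2 ASCII).
#' @return the written file paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame", format = "png") {
  frames <- as_frame_stack(frames)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  T <- n_frames(frames)
  fmt <- paste0("%s_%0", max(4, nchar(T)), "d.%s")
  paths <- character(T)
  for (t in seq_len(T)) {
    paths[t] <- file.path(dir, sprintf(fmt, prefix, t, format))
    m <- frames[, , t]
    if (format == "png") {
      png::writePNG(m, paths[t])
    } else if (format == "pgm") {
      write_pgm(m, paths[t])
    } else {
      stop("unsupported format: ", format)
    }
  }
  invisible(paths)
}

# P2 ASCII PGM writer, 8-bit.
write_pgm <- function(m, path) {
  vals <- round(pmin(pmax(m, 0), 1) * 255)
  lines <- c("P2", paste(ncol(m), nrow(m)), "255",
             apply(vals, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write an encoded map as an 8-bit grayscale PNG
#'
#' @param enc integer matrix of gray values in 0..255 (e.g. from
#'   [encode_class_map()]) or a logical matrix (mapped to 0/255).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_map_png <- function(enc, path) {
  if (is.logical(enc)) enc <- enc * 255L
  png::writePNG(enc / 255, path)
  invisible(path)
}

#' Render a gradient field as an HSV color-wheel image
#'
#' The pattern angle chi is mapped onto the hue circle with the
#' conventional anchors red = EXP (chi = 0), violet = CCW (90), light blue
#' = CON (180), yellow = CW (-90); saturation encodes the gradient
#' magnitude relative to its 95th percentile; masked cells are black.
#'
#' @param grad a [velocity_gradients()] result.
#' @param path optional PNG path.
#' @return an `h x w x 3` RGB array, invisibly written to `path` if given.
#' @export
render_gradient_field <- function(grad, path = NULL) {
  h <- nrow(grad$chi); w <- ncol(grad$chi)
  hue <- matrix(0, h, w)
  # chi 0 -> red (0), 90 (CCW) -> violet (0.75), 180 -> light blue (0.5),
  # 270/-90 (CW) -> yellow (1/6): hue decreases with chi
  hue <- ((-grad$chi / 360) %% 1)
  mag <- grad$magnitude
  ref <- stats::quantile(mag[grad$mask], 0.95, na.rm = TRUE)
  sat <- pmin(mag / max(ref, 1e-12), 1)
  val <- matrix(1, h, w)
  val[!grad$mask] <- 0
  sat[!grad$mask] <- 0
  hue[!grad$mask] <- 0
  cols <- grDevices::hsv(as.vector(hue), as.vector(sat), as.vector(val))
  rgb <- grDevices::col2rgb(cols) / 255
  img <- array(0, c(h, w, 3))
  img[, , 1] <- matrix(rgb[1, ], h, w)
  img[, , 2] <- matrix(rgb[2, ], h, w)
  img[, , 3] <- matrix(rgb[3, ], h, w)
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Export a velocity-likelihood field as long-format CSV
#'
#' One row per (frame, y, x, speed, direction) with the activation value -
#' the text analogue of a multi-axis dataset.
#'
#' @param fields list over frames of `h x w x ns x nd` arrays.
#' @param grid the [velocity_grid()] labelling the last two axes.
#' @param path output CSV path.
#' @param thin write only every `thin`-th spatial cell (keeps files small).
#' @return the path, invisibly.
#' @export
write_velocity_csv <- function(fields, grid, path, thin = 1) {
  rows <- list()
  for (t in seq_along(fields)) {
    a <- fields[[t]]
    d <- dim(a)
    iy <- seq(1, d[1], by = thin)
    ix <- seq(1, d[2], by = thin)
    sub <- a[iy, ix, , , drop = FALSE]
    rows[[t]] <- data.frame(
      frame = t,
      y = rep(iy, times = length(ix) * d[3] * d[4]),
      x = rep(rep(ix, each = length(iy)), times = d[3] * d[4]),
      speed = rep(rep(grid$speeds, each = length(iy) * length(ix)),
                  times = d[4]),
      direction = rep(grid$directions,
                      each = length(iy) * length(ix) * d[3]),
      value = as.vector(sub)
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
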