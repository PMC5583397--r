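# --- minimal grayscale TIFF codec -------------------------------------------
# No TIFF package ships with this stack, so a minimal baseline codec is
# provided: little-endian, uncompressed, single-channel, 8- or 16-bit,
# multi-page. Sufficient for the movies this package produces and consumes.

.tif_tag_u <- function(con) {
  tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  typ <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  cnt <- readBin(con, "integer", 1, 4, endian = "little")
  val_raw <- readBin(con, "raw", 4)
  list(tag = tag, type = typ, count = cnt, raw = val_raw)
}

.tif_val <- function(entry, con) {
  sz <- c(`1` = 1, `3` = 2, `4` = 4)[as.character(entry$type)]
  if (is.na(sz)) return(NULL)
  n <- entry$count
  inline <- n * sz <= 4
  read_vals <- function(r) {
    if (sz == 1) as.integer(r[seq_len(n)])
    else if (sz == 2) readBin(r, "integer", n, 2, signed = FALSE, endian = "little")
    else readBin(r, "integer", n, 4, endian = "little")
  }
  if (inline) return(read_vals(entry$raw))
  off <- readBin(entry$raw, "integer", 1, 4, endian = "little")
  pos <- seek(con)
  seek(con, off)
  v <- read_vals(readBin(con, "raw", n * sz))
  seek(con, pos)
  v
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the baseline subset written by [write_tiff()]: little- or
#' big-endian, uncompressed, single-channel, 8- or 16-bit, strip-organized.
#'
#' @param path Path to a .tif/.tiff file.
#' @return List with \code{frames} (list of matrices, raw integer values)
#'   and \code{bits} (bits per sample).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("read_tiff: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (identical(as.integer(magic[1:2]), c(0x49L, 0x49L))) endian <- "little"
  else if (identical(as.integer(magic[1:2]), c(0x4dL, 0x4dL)))
    stop("read_tiff: big-endian TIFF not supported by this minimal reader")
  else stop("read_tiff: not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1, 4, endian = "little")
  frames <- list(); bits <- 8L
  while (ifd_off != 0) {
    seek(con, ifd_off)
    nent <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
    entries <- lapply(seq_len(nent), function(i) .tif_tag_u(con))
    ifd_off <- readBin(con, "integer", 1, 4, endian = "little")
    tags <- stats::setNames(entries, vapply(entries, `[[`, 0, "tag"))
    gv <- function(id, default = NULL) {
      e <- tags[[as.character(id)]]
      if (is.null(e)) default else .tif_val(e, con)
    }
    W <- gv(256); H <- gv(257)
    bits <- gv(258, 8L)[1]
    comp <- gv(259, 1L)[1]
    spp <- gv(277, 1L)[1]
    offs <- gv(273); counts <- gv(279)
    if (comp != 1) stop("read_tiff: only uncompressed TIFF supported")
    if (spp != 1) stop("read_tiff: only single-channel TIFF supported")
    if (!(bits %in% c(8L, 16L))) stop("read_tiff: only 8/16-bit TIFF supported")
    buf <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", counts[s]))
    }
    vals <- if (bits == 8) as.integer(buf)
            else readBin(buf, "integer", W * H, 2, signed = FALSE, endian = "little")
    frames[[length(frames) + 1]] <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
  }
  if (length(frames) == 0) stop("read_tiff: zero frames in ", path)
  list(frames = frames, bits = as.integer(bits))
}

#' Write a multi-page grayscale TIFF
#'
#' Uncompressed little-endian baseline TIFF, one page per frame.
#'
#' @param frames List of integer-valued matrices (or a 3-D array).
#' @param path Output path.
#' @param bits 8 or 16 bits per sample; values are clamped to the range.
#' @export
write_tiff <- function(frames, path, bits = 8L) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  stopifnot(bits %in% c(8L, 16L), length(frames) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)
  w4(8)                                   # offset of the first IFD
  ntag <- 9L
  ifd_size <- 2 + 12 * ntag + 4
  pos <- 8
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    H <- nrow(fr); W <- ncol(fr)
    nbytes <- W * H * (bits %/% 8L)
    data_off <- pos + ifd_size
    # IFD
    w2(ntag)
    tag <- function(id, typ, cnt, val) { w2(id); w2(typ); w4(cnt); w4(val) }
    tag(256, 4, 1, W); tag(257, 4, 1, H)
    tag(258, 3, 1, bits)
    tag(259, 3, 1, 1)          # no compression
    tag(262, 3, 1, 1)          # BlackIsZero
    tag(273, 4, 1, data_off)   # single strip
    tag(277, 3, 1, 1)
    tag(278, 4, 1, H)
    tag(279, 4, 1, nbytes)
    next_ifd <- if (i < length(frames)) data_off + nbytes else 0
    w4(next_ifd)
    v <- as.integer(round(pmin(pmax(t(fr), 0), 2^bits - 1)))  # row-major
    if (bits == 8) writeBin(as.raw(v), con)
    else writeBin(v, con, 2, endian = "little")
    pos <- data_off + nbytes
  }
  invisible(path)
}

# --- PGM (portable graymap) --------------------------------------------------

#' Read a PGM image (P2 plain or P5 binary)
#' @param path File path.
#' @return List with \code{frame} (integer matrix) and \code{maxval}.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4) {
    line <- readLines(con, 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  W <- as.integer(tok[2]); H <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (magic == "P5") {
    nb <- if (maxval > 255) 2 else 1
    v <- if (nb == 1) as.integer(readBin(con, "raw", W * H))
         else readBin(con, "integer", W * H, 2, signed = FALSE, endian = "big")
  } else if (magic == "P2") {
    v <- scan(con, what = integer(), n = W * H, quiet = TRUE)
  } else stop("read_pgm: not a PGM file: ", path)
  list(frame = matrix(v, nrow = H, ncol = W, byrow = TRUE), maxval = maxval)
}

#' Write a PGM image
#' @param frame Integer-valued matrix.
#' @param path Output path.
#' @param maxval Maximum gray value (default 255).
#' @param plain Write text (P2) instead of binary (P5).
#' @export
write_pgm <- function(frame, path, maxval = 255L, plain = FALSE) {
  v <- as.integer(round(pmin(pmax(t(frame), 0), maxval)))
  if (plain) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(frame), nrow(frame)), as.character(maxval)), con)
    writeLines(paste(v, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(frame), nrow(frame)), as.character(maxval)), con)
    if (maxval > 255) writeBin(v, con, 2, endian = "big")
    else writeBin(as.raw(v), con)
  }
  invisible(path)
}

# --- stack reading -----------------------------------------------------------

#' Read an image stack from a TIFF or a directory of images
#'
#' A multi-page TIFF, or a directory of lexicographically sorted
#' single-channel images (.tif/.tiff/.pgm). Pixel values are normalized to a
#' common 0-255 scale from the container bit depth, with the original range
#' recorded in the result.
#'
#' @param path File or directory path.
#' @param fps Frames per second metadata (default 10).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, fps = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|pgm)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop("read_stack: zero frames in ", path)
    frames <- list(); scale <- numeric(0)
    for (f in files) {
      if (grepl("\\.pgm$", f, ignore.case = TRUE)) {
        p <- read_pgm(f)
        frames[[length(frames) + 1]] <- p$frame
        scale <- c(scale, p$maxval)
      } else {
        tf <- read_tiff(f)
        for (fr in tf$frames) frames[[length(frames) + 1]] <- fr
        scale <- c(scale, rep(2^tf$bits - 1, length(tf$frames)))
      }
    }
    shapes <- vapply(frames, function(m) paste(dim(m), collapse = "x"), "")
    if (length(unique(shapes)) > 1) {
      bad <- files[which(shapes != shapes[1])]
      stop("read_stack: mixed frame shapes; offending file(s): ",
           paste(basename(bad), collapse = ", "))
    }
  } else {
    tf <- read_tiff(path)
    frames <- tf$frames
    scale <- rep(2^tf$bits - 1, length(frames))
  }
  rng <- range(unlist(lapply(frames, range)))
  norm <- lapply(seq_along(frames), function(i) frames[[i]] * (255 / scale[i]))
  image_stack(norm, fps = fps, range = rng)
}

# --- CSV round-trip writers --------------------------------------------------

.fmt <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write flow grids to CSV
#'
#' Plain-text serialization: one row per node with columns \code{frame},
#' \code{node_x}, \code{node_y}, \code{pixel_x}, \code{pixel_y}, \code{ux},
#' \code{uy}, \code{valid}. Full double precision (lossless round trip via
#' [read_flow_csv()]).
#'
#' @param flows A [flow_grid()] or list of them.
#' @param path Output path.
#' @export
write_flow_csv <- function(flows, path) {
  if (inherits(flows, "flow_grid")) flows <- list(flows)
  rows <- lapply(seq_along(flows), function(t) {
    f <- flows[[t]]
    data.frame(frame = t,
               node_x = rep(seq_along(f$x), each = length(f$y)),
               node_y = rep(seq_along(f$y), times = length(f$x)),
               pixel_x = rep(f$x, each = length(f$y)),
               pixel_y = rep(f$y, times = length(f$x)),
               ux = .fmt(as.vector(f$ux)), uy = .fmt(as.vector(f$uy)),
               valid = as.integer(as.vector(f$valid)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read flow grids from CSV written by [write_flow_csv()]
#' @param path CSV path.
#' @return List of [flow_grid()]s.
#' @export
read_flow_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, factor(d$frame, levels = unique(d$frame))), function(df) {
    xs <- sort(unique(df$pixel_x)); ys <- sort(unique(df$pixel_y))
    ux <- matrix(df$ux, length(ys), length(xs))
    uy <- matrix(df$uy, length(ys), length(xs))
    valid <- matrix(df$valid == 1, length(ys), length(xs))
    flow_grid(ux, uy, xs, ys,
              spacing = if (length(xs) > 1) xs[2] - xs[1] else 1, valid = valid)
  })
}

#' Write scalar maps to CSV (frame, node_x, node_y, value)
#' @param maps A [scalar_map()] or list of them.
#' @param path Output path.
#' @export
write_scalar_map_csv <- function(maps, path) {
  if (inherits(maps, "scalar_map")) maps <- list(maps)
  rows <- lapply(seq_along(maps), function(t) {
    m <- maps[[t]]
    data.frame(frame = t,
               node_x = rep(m$x, each = length(m$y)),
               node_y = rep(m$y, times = length(m$x)),
               value = .fmt(as.vector(m$values)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a beat pattern to CSV (time_s, value)
#' @param pattern A [beat_pattern()].
#' @param path Output path.
#' @export
write_beat_csv <- function(pattern, path) {
  d <- data.frame(time_s = .fmt((seq_along(pattern$values) - 1) / pattern$fps),
                  value = .fmt(pattern$values))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an extrema sequence to CSV (kind, frame, value)
#' @param extrema An \code{extrema_sequence} from [find_extrema()].
#' @param signal The signal the extrema refer to.
#' @param path Output path.
#' @export
write_extrema_csv <- function(extrema, signal, path) {
  d <- rbind(data.frame(kind = "min", frame = extrema$minima,
                        value = .fmt(signal[extrema$minima])),
             data.frame(kind = "max", frame = extrema$maxima,
                        value = .fmt(signal[extrema$maxima])))
  d <- d[order(d$frame), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a contractility overlay as a PPM image
#'
#' Grayscale source frame with s* rendered as a red-to-yellow heat layer
#' (alpha proportional to s*). PPM binary (P6); no PNG codec is available in
#' this environment.
#'
#' @param frame Source image matrix.
#' @param map A [scalar_map()] (values >= 0) on the frame's lattice.
#' @param path Output path.
#' @export
write_overlay_ppm <- function(frame, map, path) {
  g <- (frame - min(frame)) / max(1e-12, diff(range(frame))) * 255
  H <- nrow(g); W <- ncol(g)
  v <- map$values
  v[is.na(v)] <- 0
  vmax <- max(v, 1e-12)
  # nearest-node lookup per pixel
  iy <- pmin(pmax(round((seq_len(H) - map$y[1]) / map$spacing) + 1, 1), length(map$y))
  ix <- pmin(pmax(round((seq_len(W) - map$x[1]) / map$spacing) + 1, 1), length(map$x))
  a <- v[iy, ix] / vmax
  R <- g * (1 - a) + 255 * a
  G <- g * (1 - a) + 160 * a
  B <- g * (1 - a)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(W, H), "255"), con)
  rgb <- as.integer(round(rbind(as.vector(t(R)), as.vector(t(G)), as.vector(t(B)))))
  writeBin(as.raw(pmin(pmax(rgb, 0), 255)), con)
  invisible(path)
}
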