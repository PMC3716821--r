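# Standard-format I/O: PNG (8/16-bit, linearized to [0, 1] floats) and TIFF
# (including 32-bit float and multi-page for sequences), plus CSV export of
# kernels and JSON sidecars carrying fixture/parameter provenance.

#' Read a grayscale image
#'
#' PNG (8/16-bit, values in [0, 1]) or TIFF (integer depths mapped to
#' [0, 1]; 32-bit float restored to its original range via the companion
#' range file written by [write_image()]). Multi-channel input is averaged
#' to grayscale.
#'
#' @param path file path; format chosen by extension.
#' @return `image2d`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("read_image: unsupported format '", ext,
                   "' (use png/tif/tiff)"))
  m <- undo_tiff_range(m, path)
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
  image2d(m)
}

# TIFF sample storage is normalized to [0, 1] (the tiff package clamps
# values outside that range); the original affine range is carried in a
# small companion JSON and undone on read.  Foreign TIFFs without the
# companion are returned as stored.
range_meta_path <- function(path) paste0(path, ".range.json")

write_tiff_range <- function(path, lo, sc) {
  jsonlite::write_json(list(offset = lo, scale = sc),
                       range_meta_path(path), auto_unbox = TRUE,
                       digits = NA)
}

normalize_tiff <- function(m) {
  (m - min(m)) / max(max(m) - min(m), .Machine$double.xmin)
}

undo_tiff_range <- function(m, path) {
  mp <- range_meta_path(path)
  if (!file.exists(mp)) return(m)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  m * meta$scale + meta$offset
}

#' Write a grayscale image
#'
#' PNG output is quantized to 8 or 16 bits (exact round trip for
#' already-quantized data in [0, 1]); TIFF output is 32-bit float,
#' normalized into [0, 1] with the affine range stored in a companion
#' `.range.json`, and round-trips to single precision.
#'
#' @param image `image2d` or matrix.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bits PNG bit depth, 8 or 16.
#' @return the path, invisibly.
#' @export
write_image <- function(image, path, bits = 16) {
  m <- unclass(as.matrix(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!bits %in% c(8, 16)) stop("write_image: PNG bits must be 8 or 16")
    if (min(m) < 0 || max(m) > 1)
      stop("write_image: PNG output requires values in [0, 1]")
    if (bits == 16) write_png16(m, path) else png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(normalize_tiff(m), path, bits.per.sample = 32,
                    reduce = FALSE)
    write_tiff_range(path, min(m), max(max(m) - min(m),
                                       .Machine$double.xmin))
  } else stop("write_image: unsupported format '", ext, "'")
  invisible(path)
}

#' Read an image sequence
#'
#' Either a multi-page TIFF, or a directory of numbered PNG/TIFF frames
#' (frame order by the integer embedded in each filename; a gap in the
#' numbering is an error).
#'
#' @param path multi-page TIFF file or frame directory.
#' @return `image_sequence`.
#' @export
read_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) < 3) stop("read_sequence: need >= 3 frame files")
    idx <- as.integer(gsub("\\D", "", basename(files)))
    if (any(is.na(idx))) stop("read_sequence: frames must carry an index")
    o <- order(idx)
    files <- files[o]; idx <- idx[o]
    if (any(diff(idx) != 1))
      stop("read_sequence: gap in frame numbering (",
           paste(idx, collapse = ", "), ")")
    frames <- lapply(files, function(f) unclass(read_image(f)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 3) stop("read_sequence: need >= 3 frames")
    frames <- lapply(pages, function(p) {
      p <- undo_tiff_range(p, path)
      if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)
      p
    })
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  image_sequence(arr)
}

#' Write an image sequence as a multi-page float TIFF
#'
#' @param seq `image_sequence`.
#' @param path output `.tif` path.
#' @return the path, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  raw <- unclass(seq)
  lo <- min(raw); sc <- max(max(raw) - lo, .Machine$double.xmin)
  pages <- lapply(seq_len(dim(raw)[1]), function(t) (raw[t, , ] - lo) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  write_tiff_range(path, lo, sc)
  invisible(path)
}

#' Export a kernel as CSV
#'
#' Plain numeric CSV of the taps, row = y, column = x.
#'
#' @param kernel `kernel2d` or matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  utils::write.table(unclass(as.matrix(kernel)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder ---------------------------------
# The png package reads 16-bit PNGs but can only write 8-bit (or raw RGBA),
# so the 16-bit path is encoded here directly: IHDR/IDAT/IEND chunks with
# the zlib stream from memCompress (whose "gzip" type emits an RFC 1950
# zlib wrapper, Adler-32 included).

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
        else bitwShiftR(bitwAnd(c, -2L), 1)
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

png_crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1])
  crc <- bitwXor(crc, -1L)
  writeBin(crc, raw(), size = 4, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(writeBin(length(data), raw(), size = 4, endian = "big"), body,
    png_crc32(body))
}

write_png16 <- function(m, path) {
  v <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  h <- nrow(m); w <- ncol(m)
  # scanlines: filter byte 0, then big-endian 16-bit samples row by row
  vm <- as.integer(t(v))
  hi <- as.raw(vm %/% 256L); lo <- as.raw(vm %% 256L)
  sample_bytes <- as.raw(rbind(hi, lo))
  dim(sample_bytes) <- NULL
  rows <- split(sample_bytes, rep(seq_len(h), each = 2L * w))
  scan <- unlist(lapply(rows, function(r) c(as.raw(0), r)),
                 use.names = FALSE)
  idat <- memCompress(scan, "gzip")
  ihdr <-c(writeBin(w, raw(), size = 4, endian = "big"),
            writeBin(h, raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# JSON sidecar with parameter provenance next to an artifact
write_sidecar <- function(path, params) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(params, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}
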