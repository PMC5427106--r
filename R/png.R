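# Minimal deterministic PNG codec for truecolor rasters.
#
# Visual maps must be byte-reproducible, so rasters are serialized with a
# fixed pipeline: 8-bit RGB, filter 0 on every scanline, one zlib IDAT
# (memCompress, fixed level), no ancillary chunks. The reader only accepts
# what the writer emits; it exists for round-trip tests and CLI inspection.

.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v)
    c <- bitwXor(.crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  c <- bitwXor(c, -1L)
  if (c < 0) c + 4294967296 else as.double(c)
}

adler32 <- function(bytes) {
  v <- as.double(as.integer(bytes))
  s1 <- 1; s2 <- 0
  # chunked so partial sums stay exactly representable in doubles
  for (i in seq(1L, length(v), by = 65536L)) {
    chunk <- v[i:min(i + 65535L, length(v))]
    c1 <- cumsum(chunk)
    s2 <- (s2 + length(chunk) * s1 + sum(c1)) %% 65521
    s1 <- (s1 + c1[length(c1)]) %% 65521
  }
  s2 * 65536 + s1
}

u32_bytes <- function(x) {
  as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, u32_bytes(crc32(body)))
}

# raster: character matrix of "#RRGGBB" strings (rows = scanlines)
png_encode <- function(raster) {
  h <- nrow(raster); w <- ncol(raster)
  if (h < 1L || w < 1L)
    abort_etho("style", "cannot encode an empty raster")
  # col2rgb over the transposed matrix yields pixels in scanline order
  pix <- grDevices::col2rgb(as.vector(t(raster)))
  scan <- matrix(as.raw(as.vector(pix)), nrow = 3L * w, ncol = h)
  dat <- as.vector(rbind(as.raw(0L), scan))  # filter byte 0 per scanline
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))  # 8-bit, truecolor
  idat <- memCompress(dat, type = "gzip")   # zlib stream (0x78 ...)
  c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0)))
}

png_write_raster <- function(raster, path) {
  writeBin(png_encode(raster), path)
  invisible(path)
}

# Reader for the subset this package writes (8-bit RGB, filter 0).
png_read_raster <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8L ||
      !identical(bytes[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    abort_etho("io", "not a PNG file: %s", path)
  pos <- 9L
  w <- h <- NULL; idat <- raw(0)
  u32 <- function(b) sum(as.integer(b) * c(16777216, 65536, 256, 1))
  while (pos + 7L <= length(bytes)) {
    len <- u32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- u32(data[1:4]); h <- u32(data[5:8])
      if (data[9] != as.raw(8L) || data[10] != as.raw(2L))
        abort_etho("io", "unsupported PNG subformat in %s", path)
    } else if (type == "IDAT") idat <- c(idat, data)
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  dat <- memDecompress(idat, type = "gzip")
  stride <- 1L + 3L * w
  m <- matrix(dat, nrow = stride, ncol = h)
  if (any(m[1L, ] != as.raw(0L)))
    abort_etho("io", "unsupported PNG filter in %s", path)
  rgbv <- as.integer(m[-1L, , drop = FALSE])           # per column: scanline
  px <- matrix(rgbv, nrow = 3L)                        # 3 x (w*h)
  hexes <- grDevices::rgb(px[1, ], px[2, ], px[3, ], maxColorValue = 255)
  matrix(hexes, nrow = h, ncol = w, byrow = TRUE)
}
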