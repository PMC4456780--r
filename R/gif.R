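# Minimal GIF87a encoder.
#
# None of the available raster back-ends write GIF, so panels requested in
# that format are rasterized to PNG first and re-encoded here.  Colors are
# quantized to the 216-color web-safe cube (panels are text on a plain
# background, so the quantization loss is negligible) and the pixel stream is
# emitted as 9-bit LZW codes with a clear code issued before the decoder's
# table can outgrow 9 bits -- valid, if uncompressed, LZW.

.gif_pack_codes <- function(codes, width = 9L) {
  bits <- vapply(seq_len(width) - 1L,
                 function(b) bitwAnd(bitwShiftR(codes, b), 1L),
                 integer(length(codes)))
  bits <- as.vector(t(matrix(bits, ncol = width)))  # LSB-first per code
  pad <- (-length(bits)) %% 8L
  if (pad) bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * 2L^(0:7)))
}

.uint16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

#' Write an RGB raster as a GIF87a file
#'
#' @param img Numeric array `height x width x 3` (or deeper; extra channels
#'   ignored) with values in `[0, 1]`, as returned by [png::readPNG()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_gif <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  lv <- function(k) pmin(5L, pmax(0L, as.integer(round(img[, , k] * 5))))
  idx <- matrix(lv(1) * 36L + lv(2) * 6L + lv(3), nrow = h)  # 0..215
  idx <- as.integer(t(idx))                        # GIF scans rows first

  pal <- as.integer(seq(0, 255, length.out = 6))
  cube <- expand.grid(b = pal, g = pal, r = pal)   # varies b fastest
  table256 <- rbind(as.matrix(cube[, c("r", "g", "b")]),
                    matrix(0L, nrow = 256 - 216, ncol = 3))

  clear <- 256L; eoi <- 257L
  # Insert a clear code every 250 pixel codes: the decoder adds one table
  # entry per code after a clear, so codes never exceed 9 bits.
  chunks <- split(idx, (seq_along(idx) - 1L) %/% 250L)
  codes <- c(clear,
             unlist(lapply(chunks, function(ch) c(ch, clear)), use.names = FALSE))
  codes[length(codes)] <- eoi
  payload <- .gif_pack_codes(codes)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF87a"), con)
  writeBin(c(.uint16le(w), .uint16le(h), as.raw(c(0xF7, 0x00, 0x00))), con)
  writeBin(as.raw(as.vector(t(table256))), con)
  writeBin(c(as.raw(0x2C), .uint16le(0L), .uint16le(0L),
             .uint16le(w), .uint16le(h), as.raw(0x00), as.raw(8L)), con)
  for (off in seq.int(1L, length(payload), by = 255L)) {
    block <- payload[off:min(length(payload), off + 254L)]
    writeBin(c(as.raw(length(block)), block), con)
  }
  writeBin(as.raw(c(0x00, 0x3B)), con)
  invisible(path)
}
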