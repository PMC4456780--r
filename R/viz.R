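# Raster rendering: per-primer alignment panels and per-target
# primer-distribution maps.  Every image gets a JSON sidecar describing its
# geometry; pixel-level golden-image tests are brittle across rasterizers,
# so the sidecar is the testable surface.

.viz_formats <- c("png", "jpeg", "gif")

.open_raster <- function(path, format, width, height) {
  # gif renders via a temporary png that is re-encoded on close
  if (format == "png") {
    grDevices::png(path, width = width, height = height)
    NULL
  } else if (format == "jpeg") {
    grDevices::jpeg(path, width = width, height = height, quality = 90)
    NULL
  } else {
    tmp <- tempfile(fileext = ".png")
    grDevices::png(tmp, width = width, height = height)
    tmp
  }
}

.close_raster <- function(path, format, tmp) {
  grDevices::dev.off()
  if (format == "gif") {
    write_gif(png::readPNG(tmp), path)
    unlink(tmp)
  }
  invisible(path)
}

.write_sidecar <- function(path, payload) {
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  sidecar
}

.infer_format <- function(out_path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(out_path))
    if (format == "jpg") format <- "jpeg"
  }
  if (!format %in% .viz_formats) {
    stop_usage(sprintf("unsupported image format '%s' (supported: %s)",
                       format, paste(.viz_formats, collapse = ", ")))
  }
  format
}

#' Render a per-primer alignment panel
#'
#' Draws one primer's alignment view: sequence name, primer name and strand,
#' coordinate ticks, and the target and primer text rows.  The output format
#' follows the file extension (png, jpeg/jpg, gif) unless given explicitly.
#' A JSON sidecar `<out_path>.json` records the panel geometry.
#'
#' @param view An [build_alignment_view()] result.
#' @param out_path Output raster path.
#' @param format `"png"`, `"jpeg"` or `"gif"`; default inferred from
#'   `out_path`'s extension.
#' @param width,height Image size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_alignment_panel <- function(view, out_path, format = NULL,
                                   width = 940L, height = 260L) {
  format <- .infer_format(out_path, format)
  n <- nchar(view$target_line)
  tmp <- .open_raster(out_path, format, width, height)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit({ graphics::par(op); .close_raster(out_path, format, tmp) })
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, n + 1), ylim = c(0, 6))
  title <- if (nzchar(view$description)) {
    paste(view$target_id, view$description)
  } else view$target_id
  graphics::text((n + 1) / 2, 5.5, title, font = 2, cex = 1.1)
  graphics::text((n + 1) / 2, 4.7,
                 sprintf("primer %s  (%s strand, %d..%d)", view$primer_name,
                         view$strand, view$primer_start, view$primer_end),
                 cex = 0.95)
  cx <- min(1, 55 / n)
  xpos <- seq_len(n)
  graphics::text(xpos, 3, strsplit(view$target_line, "")[[1]],
                 family = "mono", cex = cx)
  chars <- strsplit(view$primer_line, "")[[1]]
  in_span <- chars != "-"
  graphics::text(xpos, 2.2, chars, family = "mono", cex = cx,
                 col = ifelse(in_span, "firebrick", "grey60"))
  for (tick in view$tick_positions) {
    x <- tick - view$window_start + 1L
    graphics::lines(c(x, x), c(3.45, 3.6))
    graphics::text(x, 3.85, tick, cex = 0.75)
  }
  .write_sidecar(out_path, list(
    type = "alignment_panel", title = title, target_id = view$target_id,
    primer = view$primer_name, direction = view$direction,
    strand = view$strand,
    window = list(start = view$window_start, end = view$window_end),
    primer_span = list(start = view$primer_start, end = view$primer_end),
    ticks = view$tick_positions
  ))
  invisible(out_path)
}

# Greedy first-fit row packing by start coordinate; gap in nt keeps labels
# from colliding on dense sets.
.pack_rows <- function(starts, ends, target_length) {
  gap <- max(2, ceiling(0.03 * target_length))
  row_end <- numeric(0)
  rows <- integer(length(starts))
  for (i in seq_along(starts)) {
    fit <- which(row_end + gap < starts[i])
    if (length(fit)) {
      rows[i] <- fit[1L]
    } else {
      rows[i] <- length(row_end) + 1L
    }
    row_end[rows[i]] <- ends[i]
  }
  rows
}

#' Render a primer-distribution map for one target
#'
#' Draws the target as a scaled number line (a coordinate ruler spanning
#' `1..target_length`) with one labeled arrow glyph per accepted primer,
#' pointing in the direction of synthesis: forward primers toward increasing
#' coordinates, reverse primers toward decreasing.  Overlapping glyphs are
#' packed onto separate rows (greedy first-fit by start).  An empty primer
#' set yields a valid ruler-only image.  A JSON sidecar `<out_path>.json`
#' lists the ruler extent and every glyph's geometry.
#'
#' @param set A `primer_set` from [design_primers()].
#' @param out_path Output raster path (default format PNG; jpeg/gif follow
#'   the extension).
#' @param format Optional explicit format.
#' @param width Image width in pixels; height scales with the packed rows.
#' @return `out_path`, invisibly.
#' @export
render_distribution_map <- function(set, out_path, format = NULL,
                                    width = 940L) {
  format <- .infer_format(out_path, format)
  df <- set$primers
  L <- set$target_length
  rows <- if (nrow(df)) .pack_rows(df$start, df$end, L) else integer(0)
  n_rows <- if (length(rows)) max(rows) else 0L
  height <- 140L + 34L * n_rows
  tmp <- .open_raster(out_path, format, width, height)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit({ graphics::par(op); .close_raster(out_path, format, tmp) })
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.04 * L, 1.04 * L),
                        ylim = c(-1.6, n_rows + 1.5))
  graphics::text(L / 2, n_rows + 1.1, set$target_id, font = 2, cex = 1.1)
  graphics::lines(c(1, L), c(-1, -1), lwd = 2)
  ticks <- unique(round(pretty(c(1, L), n = 8)))
  ticks <- ticks[ticks >= 1 & ticks <= L]
  for (t in c(1, ticks, L)) {
    graphics::lines(c(t, t), c(-1, -1.15))
    graphics::text(t, -1.4, t, cex = 0.7)
  }
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      y <- rows[i] - 0.35
      fwd <- df$direction[i] == "forward"
      graphics::arrows(x0 = if (fwd) df$start[i] else df$end[i],
                       x1 = if (fwd) df$end[i] else df$start[i],
                       y0 = y, y1 = y, length = 0.07, lwd = 2,
                       col = if (fwd) "steelblue4" else "darkorange3")
      graphics::text((df$start[i] + df$end[i]) / 2, y + 0.32, df$name[i],
                     cex = 0.65)
    }
  }
  glyphs <- if (nrow(df)) {
    lapply(seq_len(nrow(df)), function(i) list(
      name = df$name[i], start = df$start[i], end = df$end[i],
      direction = df$direction[i], row = rows[i]))
  } else list()
  .write_sidecar(out_path, list(
    type = "distribution_map", title = set$target_id,
    target_length = L, ruler = list(from = 1L, to = L),
    glyphs = glyphs
  ))
  invisible(out_path)
}
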