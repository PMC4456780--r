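# Coordinate mapping of designed primers back onto their targets.
#
# Every accepted primer is, by construction, an exact substring (forward) or
# reverse-complement substring (reverse) of its target, so mapping is exact
# coordinate bookkeeping; the re-extraction check below is the correctness
# gate that an alignment step would otherwise provide.  An external aligner
# would add nondeterminism without information here.

#' Map a primer onto its target and verify by re-extraction
#'
#' Returns the primer's 1-based inclusive coordinates and strand, after
#' verifying that the covered target slice (forward) or its reverse
#' complement (reverse) reproduces the primer sequence exactly.  A
#' verification failure indicates an internal design bug, never user error.
#'
#' @param primer One primer: a one-row data frame or list with fields
#'   `direction`, `start`, `end`, `seq` (as produced by [design_primers()]).
#' @param record The [seq_record()] the primer was designed from.
#' @return A list with `start`, `end` and `strand` (`"+"` forward, `"-"`
#'   reverse).
#' @export
map_primer <- function(primer, record) {
  start <- as.integer(primer$start)
  end <- as.integer(primer$end)
  slice <- substr(record$seq, start, end)
  recovered <- if (primer$direction == "forward") slice
               else reverse_complement(slice)
  if (!identical(recovered, primer$seq)) {
    stop(sprintf(
      "internal consistency error: primer '%s' at %d..%d does not re-extract from target '%s'",
      primer$seq, start, end, record$id))
  }
  list(start = start, end = end,
       strand = if (primer$direction == "forward") "+" else "-")
}

#' Build the pairwise alignment view for one primer
#'
#' The displayed window is the primer span extended by `flank` nt on each
#' side, clamped to the target.  `target_line` is the target slice;
#' `primer_line` is gap-padded outside the primer span and, inside it, equals
#' the target (forward primers) or its complement (reverse primers, whose
#' 3'->5' annealing orientation is annotated rather than re-reversed so the
#' view stays on target coordinates).  Tick labels mark the window bounds and
#' the primer bounds.
#'
#' @inheritParams map_primer
#' @param flank Non-negative flank width, nt.
#' @return An object of class `alignment_view`.
#' @export
build_alignment_view <- function(primer, record, flank = 25L) {
  stopifnot(flank >= 0)
  m <- map_primer(primer, record)
  L <- nchar(record$seq)
  ws <- max(1L, m$start - as.integer(flank))
  we <- min(L, m$end + as.integer(flank))
  target_line <- substr(record$seq, ws, we)
  span <- substr(record$seq, m$start, m$end)
  shown <- if (primer$direction == "forward") span else chartr("ACGT", "TGCA", span)
  primer_line <- paste0(strrep("-", m$start - ws), shown, strrep("-", we - m$end))
  structure(list(
    target_id = record$id, description = record$description,
    primer_name = if (!is.null(primer$name)) primer$name else as.character(m$start),
    direction = primer$direction,
    window_start = ws, window_end = we,
    primer_start = m$start, primer_end = m$end, strand = m$strand,
    target_line = target_line, primer_line = primer_line,
    tick_positions = unique(c(ws, m$start, m$end, we))
  ), class = "alignment_view")
}

#' Format an alignment view as CLUSTAL-like text
#'
#' @param view An [build_alignment_view()] result.
#' @param block_width Characters per alignment block.
#' @return A character vector of output lines.
#' @export
format_alignment_text <- function(view, block_width = 60L) {
  n <- nchar(view$target_line)
  tag_t <- sprintf("%-12s", substr(view$target_id, 1L, 12L))
  tag_p <- sprintf("%-12s", substr(paste0("primer_", view$primer_name), 1L, 12L))
  out <- c(sprintf("Primer %s (%s strand) at %d..%d on %s",
                   view$primer_name, view$strand, view$primer_start,
                   view$primer_end, view$target_id),
           sprintf("Window %d..%d", view$window_start, view$window_end), "")
  for (off in seq.int(1L, n, by = block_width)) {
    to <- min(n, off + block_width - 1L)
    seg_t <- substr(view$target_line, off, to)
    seg_p <- substr(view$primer_line, off, to)
    match_line <- paste(ifelse(
      strsplit(seg_t, "")[[1]] == strsplit(seg_p, "")[[1]], "*", " "),
      collapse = "")
    out <- c(out,
             paste0(tag_t, seg_t, "  ", view$window_start + to - 1L),
             paste0(tag_p, seg_p),
             paste0(strrep(" ", 12L), match_line), "")
  }
  out
}

#' @export
print.alignment_view <- function(x, ...) {
  writeLines(format_alignment_text(x))
  invisible(x)
}
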