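#' Read a multi-FASTA file of DNA sequences
#'
#' Parses a FASTA file (LF or CRLF, wrapped or unwrapped) and returns one
#' record per entry.  Sequences are normalized to uppercase and `U` is mapped
#' to `T` so transcript-derived FASTA works; any other non-`ACGT` character is
#' rejected with its position.  Soft-masking (lowercase) information is
#' discarded by the case fold.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A list of `seq_record` objects, in file order.  Each has fields
#'   `id` (first whitespace-delimited header token), `description` (remainder
#'   of the header, possibly `""`) and `seq` (uppercase string over `ACGT`).
#' @examples
#' fa <- system.file("extdata", "test_seqs.fasta", package = "primap")
#' recs <- read_fasta(fa)
#' recs[[1]]$id
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("input file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_input(sprintf("no records could be read from '%s': %s",
                                           path, conditionMessage(e)))
  )
  if (length(set) == 0L) stop_input(sprintf("no records in '%s'", path))

  headers <- trimws(names(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), trimws(sub("^\\S+\\s*", "", headers)), "")
  if (any(ids == "")) stop_input("FASTA header with empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_input(sprintf("duplicate record id(s): %s", paste(dup, collapse = ", ")))
  }

  seqs <- toupper(as.character(set))
  seqs <- gsub("[ \t\r]", "", seqs)
  seqs <- chartr("U", "T", seqs)
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- seqs[[i]]
    if (nchar(s) == 0L) {
      stop_input(sprintf("record '%s' has a zero-length sequence", ids[[i]]))
    }
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0L) {
      stop_input(sprintf(
        "record '%s' contains non-IUPAC-unambiguous character '%s' at position %d (ambiguity codes are rejected)",
        ids[[i]], substr(s, bad, bad), bad))
    }
    records[[i]] <- seq_record(ids[[i]], s, desc[[i]])
  }
  records
}

#' Construct a sequence record
#'
#' @param id Non-empty identifier, unique within a dataset.
#' @param seq Uppercase DNA string over `ACGT`.
#' @param description Optional free-text remainder of the FASTA header.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), nzchar(id), is.character(seq), nzchar(seq))
  structure(list(id = id, description = description, seq = seq),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt%s)\n", x$id, nchar(x$seq),
              if (nzchar(x$description)) paste0("; ", x$description) else ""))
  invisible(x)
}

#' Write sequence records to a FASTA file
#'
#' Headers are `id` plus a space and the description when one is present;
#' sequence lines are wrapped at 70 characters.
#'
#' @param records A list of [seq_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

.check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop_input("expected a single non-empty DNA string")
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop_input(sprintf("invalid DNA character '%s' at position %d",
                       substr(seq, bad, bad), bad))
  }
  invisible(seq)
}

#' Watson-Crick reverse complement
#'
#' @param seq Uppercase DNA string over `ACGT`.
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Bulk reverse complement via Biostrings, for candidate enumeration.
.reverse_complement_many <- function(seqs) {
  if (!length(seqs)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' GC content of a DNA string, in percent
#'
#' `100 * (#G + #C) / length`; the ratio is formed from integer counts so the
#' result is exact up to one float division.
#'
#' @param seq Non-empty uppercase DNA string.
#' @return Percent GC in `[0, 100]`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  .check_dna(seq)
  n_gc <- nchar(seq) - nchar(gsub("[GC]", "", seq))
  100 * n_gc / nchar(seq)
}

# Vectorized GC percent for enumeration (Biostrings letter counting).
.gc_content_many <- function(seqs) {
  if (!length(seqs)) return(numeric(0))
  set <- Biostrings::DNAStringSet(seqs)
  100 * as.vector(Biostrings::letterFrequency(set, "GC")) / nchar(seqs)
}
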