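# Deterministic synthetic-FASTA generator: every test and demo runs without
# downloading data.  All randomness goes through one explicitly seeded RNG
# scope (withr::with_seed), so the global random state is never touched and
# the same spec always yields the same bytes.

#' Specification for a synthetic FASTA dataset
#'
#' @param n_records Number of records.
#' @param length_range `c(min, max)` record length in nt (inclusive).
#' @param gc_target Per-base GC probability, percent.
#' @param seed Integer seed; same spec, same output bytes.
#' @param plant Optional list of `list(record, position, oligo)` insertions:
#'   `oligo` overwrites the record's bases starting at `position`, enabling
#'   constructed duplicate-site specificity cases.
#' @param id_prefix Record-id prefix (`<prefix>_<index>`).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_records = 10L, length_range = c(300L, 600L),
                           gc_target = 50, seed = 1L, plant = NULL,
                           id_prefix = "synth") {
  stopifnot(n_records >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2],
            gc_target >= 0, gc_target <= 100)
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 gc_target = as.numeric(gc_target), seed = as.integer(seed),
                 plant = plant, id_prefix = id_prefix),
            class = "generator_spec")
}

#' Generate a deterministic random FASTA dataset
#'
#' Draws each base independently with `P(G) = P(C) = gc_target/200` and
#' `P(A) = P(T) = (100 - gc_target)/200`, applies any planted-oligo
#' overwrites, and returns the records plus a manifest of realized lengths
#' and GC.  When `path` is given the FASTA (and a `<path>.manifest.json`
#' sidecar) is written as well.
#'
#' @param spec A [generator_spec()].
#' @param path Optional FASTA output path.
#' @return A list with `records` (list of [seq_record()]) and `manifest`
#'   (seed, spec echo, per-record realized lengths and GC, total length).
#' @examples
#' fa <- random_fasta(generator_spec(n_records = 2, seed = 7))
#' fa$manifest$total_length
#' @export
random_fasta <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  p_gc <- spec$gc_target / 100
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2, T = (1 - p_gc) / 2)
  records <- withr::with_seed(spec$seed, {
    len_choices <- seq.int(spec$length_range[1], spec$length_range[2])
    lens <- len_choices[sample.int(length(len_choices), spec$n_records,
                                   replace = TRUE)]
    lapply(seq_len(spec$n_records), function(i) {
      s <- paste(sample(names(probs), lens[i], replace = TRUE, prob = probs),
                 collapse = "")
      seq_record(sprintf("%s_%d", spec$id_prefix, i), s,
                 description = sprintf("synthetic length=%d gc_target=%g",
                                       lens[i], spec$gc_target))
    })
  })
  for (pl in spec$plant) {
    i <- pl$record
    if (i < 1L || i > length(records)) stop_usage("plant: record index out of range")
    L <- nchar(records[[i]]$seq)
    to <- pl$position + nchar(pl$oligo) - 1L
    if (pl$position < 1L || to > L) {
      stop_usage(sprintf("plant: oligo at %d..%d out of range for record %d (length %d)",
                         pl$position, to, i, L))
    }
    .check_dna(pl$oligo)
    substr(records[[i]]$seq, pl$position, to) <- pl$oligo
  }
  manifest <- list(
    seed = spec$seed,
    spec = list(n_records = spec$n_records, length_range = spec$length_range,
                gc_target = spec$gc_target, id_prefix = spec$id_prefix,
                n_planted = length(spec$plant)),
    ids = vapply(records, `[[`, character(1), "id"),
    lengths = vapply(records, function(r) nchar(r$seq), integer(1)),
    gc_realized = vapply(records, function(r) gc_content(r$seq), numeric(1)),
    total_length = sum(vapply(records, function(r) nchar(r$seq), integer(1)))
  )
  if (!is.null(path)) {
    write_fasta(records, path)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, manifest = manifest)
}

#' Synthetic dataset with a deliberately duplicated binding site
#'
#' Convenience fixture for specificity screening: six 400-800 nt records at
#' 50% GC, with one 20-mer planted near the start of records 1 and 2, so any
#' candidate containing it has two binding sites under whole-file screening.
#'
#' @param seed Integer seed.
#' @return As [random_fasta()], plus the planted `oligo`.
#' @export
planted_dataset <- function(seed = 11L) {
  oligo <- "ACGTCCTAGGATCCAAGCTG"
  spec <- generator_spec(n_records = 6L, length_range = c(400L, 800L),
                         gc_target = 50, seed = seed,
                         plant = list(list(record = 1L, position = 21L, oligo = oligo),
                                      list(record = 2L, position = 21L, oligo = oligo)),
                         id_prefix = "planted")
  out <- random_fasta(spec)
  out$oligo <- oligo
  out
}
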