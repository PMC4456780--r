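# Candidate enumeration, filtering and specificity screening: the core
# design algorithm behind the -a..-k knob set.

#' Primer design parameters
#'
#' The full knob set of the design algorithm.  Forward primers are searched in
#' the first `five_prime_window` bases of each target, reverse primers in the
#' final `three_prime_window` bases; windows larger than a target are clamped
#' to its length, so setting both to the sequence length scans everything.
#'
#' Defaults are conventional PCR values: 150 nt search windows, 18-24 nt
#' primers, 40-60% GC, 52-65 degC Tm, GC clamp required, specificity screened
#' against the whole input file.
#'
#' @param five_prime_window,three_prime_window Search window sizes, nt.
#' @param len_max,len_min Primer length bounds, nt.
#' @param gc_clamp Require a G or C at the 3' terminus?
#' @param gc_max,gc_min GC-content bounds, percent.
#' @param tm_max,tm_min Melting-temperature bounds, degrees C.
#' @param specificity_whole_file Screen specificity against the entire input
#'   file (`TRUE`) or against each primer's own target only (`FALSE`).
#' @param input_path Optional input FASTA path (recorded for the CLI).
#' @return An object of class `design_params`.
#' @export
design_params <- function(five_prime_window = 150L, three_prime_window = 150L,
                          len_max = 24L, len_min = 18L, gc_clamp = TRUE,
                          gc_max = 60, gc_min = 40, tm_max = 65, tm_min = 52,
                          specificity_whole_file = TRUE, input_path = NULL) {
  p <- list(input_path = input_path,
            five_prime_window = as.integer(five_prime_window),
            three_prime_window = as.integer(three_prime_window),
            len_max = as.integer(len_max), len_min = as.integer(len_min),
            gc_clamp = isTRUE(gc_clamp), gc_max = as.numeric(gc_max),
            gc_min = as.numeric(gc_min), tm_max = as.numeric(tm_max),
            tm_min = as.numeric(tm_min),
            specificity_whole_file = isTRUE(specificity_whole_file))
  ints <- c("five_prime_window", "three_prime_window", "len_max", "len_min")
  if (any(vapply(p[ints], function(x) is.na(x) || x < 1L, logical(1)))) {
    stop_usage("window and length parameters must be positive integers")
  }
  if (p$len_min > p$len_max) stop_usage("len_min must be <= len_max")
  if (p$gc_min > p$gc_max) stop_usage("gc_min must be <= gc_max")
  if (p$tm_min > p$tm_max) stop_usage("tm_min must be <= tm_max")
  if (p$five_prime_window < p$len_min || p$three_prime_window < p$len_min) {
    stop_usage("search windows must be >= len_min")
  }
  structure(p, class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat("<design_params>\n")
  cat(sprintf("  windows 5'/3': %d/%d nt   length: %d-%d nt\n",
              x$five_prime_window, x$three_prime_window, x$len_min, x$len_max))
  cat(sprintf("  GC: %g-%g%%   Tm: %g-%g degC   GC clamp: %s   specificity: %s\n",
              x$gc_min, x$gc_max, x$tm_min, x$tm_max,
              if (x$gc_clamp) "Y" else "N",
              if (x$specificity_whole_file) "whole file" else "own sequence"))
  invisible(x)
}

.empty_candidates <- function() {
  data.frame(target_id = character(0), direction = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             seq = character(0), tm = numeric(0), gc = numeric(0),
             stringsAsFactors = FALSE)
}

#' Enumerate all primer candidates in one search window
#'
#' Returns every substring whose span lies inside the direction's window and
#' whose length is in `[len_min, len_max]`, unfiltered, with Tm and GC%
#' populated.  Coordinates are 1-based inclusive on the target.  Reverse
#' candidates carry the reverse complement of the covered slice (their
#' synthesis-orientation sequence).
#'
#' @param record A [seq_record()].
#' @param params A [design_params()] object.
#' @param direction `"forward"` or `"reverse"`.
#' @param thermo A [thermo_parameters()] object.
#' @return A data frame with columns `target_id`, `direction`, `start`, `end`,
#'   `length`, `seq`, `tm`, `gc`, ordered by start then length.
#' @export
enumerate_candidates <- function(record, params, direction = c("forward", "reverse"),
                                 thermo = thermo_parameters()) {
  direction <- match.arg(direction)
  L <- nchar(record$seq)
  W <- min(L, if (direction == "forward") params$five_prime_window
              else params$three_prime_window)
  if (W < params$len_min) {
    warning(sprintf("record '%s': %s window (%d nt) shorter than len_min (%d); no candidates",
                    record$id, direction, W, params$len_min), call. = FALSE)
    return(.empty_candidates())
  }
  lens <- seq.int(params$len_min, min(params$len_max, W))
  grid <- do.call(rbind, lapply(lens, function(l) {
    if (direction == "forward") starts <- seq.int(1L, W - l + 1L)
    else starts <- seq.int(L - W + 1L, L - l + 1L)
    cbind(start = starts, length = l)
  }))
  grid <- grid[order(grid[, "start"], grid[, "length"]), , drop = FALSE]
  start <- as.integer(grid[, "start"])
  len <- as.integer(grid[, "length"])
  end <- start + len - 1L
  slice <- substring(record$seq, start, end)
  seq <- if (direction == "forward") slice else .reverse_complement_many(slice)
  data.frame(target_id = record$id, direction = direction, start = start,
             end = end, length = len, seq = seq,
             tm = calc_tm(seq, thermo), gc = .gc_content_many(seq),
             stringsAsFactors = FALSE)
}

.filter_names <- c("length", "gc_range", "tm_range", "gc_clamp")

#' Audit candidates against the compositional and thermodynamic filters
#'
#' Appends a `rejection_reasons` column listing, comma-separated, each of
#' `length`, `gc_range`, `tm_range`, `gc_clamp` that fails, and a logical
#' `accepted` column that is `TRUE` iff no reason was recorded.  The GC clamp
#' passes iff the 3'-terminal base of the synthesis-orientation sequence is G
#' or C.  Pure predicate: no candidate is dropped.
#'
#' @param cands Candidate data frame from [enumerate_candidates()].
#' @param params A [design_params()] object.
#' @return `cands` with `rejection_reasons` and `accepted` columns.
#' @export
passes_filters <- function(cands, params) {
  fail <- cbind(
    length = cands$length < params$len_min | cands$length > params$len_max,
    gc_range = cands$gc < params$gc_min | cands$gc > params$gc_max,
    tm_range = cands$tm < params$tm_min | cands$tm > params$tm_max,
    gc_clamp = if (params$gc_clamp) {
      !substr(cands$seq, cands$length, cands$length) %in% c("G", "C")
    } else rep(FALSE, nrow(cands))
  )
  cands$rejection_reasons <- apply(fail, 1L, function(f) {
    paste(.filter_names[f], collapse = ",")
  })
  if (!nrow(cands)) cands$rejection_reasons <- character(0)
  cands$accepted <- cands$rejection_reasons == ""
  cands
}

.records_as_set <- function(records) {
  Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "seq"))
}

.count_in_set <- function(oligo, subject_set) {
  rc <- reverse_complement(oligo)
  sum(Biostrings::vcountPattern(oligo, subject_set)) +
    sum(Biostrings::vcountPattern(rc, subject_set))
}

#' Count strand-aware exact occurrences of an oligo in a set of records
#'
#' Total exact matches of `oligo` plus exact matches of its reverse
#' complement across all records; overlapping matches are counted.  A
#' palindromic oligo therefore counts each physical site twice (once per
#' strand) by definition.
#'
#' @param oligo Non-empty DNA string.
#' @param records List of [seq_record()] objects.
#' @return Integer occurrence count.
#' @examples
#' count_occurrences("AAAAC", list(seq_record("r1", "GTTTT")))  # 1
#' @export
count_occurrences <- function(oligo, records) {
  .check_dna(oligo)
  .count_in_set(oligo, .records_as_set(records))
}

# Unique display names: bare start position, "F"/"R" appended when forward
# and reverse primers share a start, ".<length>" appended when two accepted
# lengths share a start and direction.
.name_primers <- function(df) {
  nm <- as.character(df$start)
  dup <- nm %in% nm[duplicated(nm)]
  nm[dup] <- paste0(nm[dup], ifelse(df$direction[dup] == "forward", "F", "R"))
  dup2 <- nm %in% nm[duplicated(nm)]
  nm[dup2] <- paste0(nm[dup2], ".", df$length[dup2])
  nm
}

#' Design primers for every record in a dataset
#'
#' Per record: enumerate forward and reverse candidates in their search
#' windows, apply the compositional/thermodynamic filters, then keep only
#' candidates with exactly one strand-aware binding site (their own) in the
#' screening scope -- the whole input file when
#' `params$specificity_whole_file`, otherwise the record alone.  Accepted
#' primers are named by start position and returned in deterministic order
#' (target, then start, then direction).
#'
#' @param records Non-empty list of [seq_record()] objects.
#' @param params A [design_params()] object.
#' @param thermo A [thermo_parameters()] object.
#' @param keep_audit Attach the full audited candidate table (including
#'   specificity failures, reason `"specificity"`) as attribute `"audit"`?
#' @param quiet Suppress the per-record "no primers" warnings?
#' @return A list of `primer_set` objects, one per record in input order; each
#'   has `target_id`, `target_length` and `primers` (a data frame with a
#'   unique `name` column).
#' @export
design_primers <- function(records, params = design_params(),
                           thermo = thermo_parameters(),
                           keep_audit = FALSE, quiet = FALSE) {
  if (!length(records)) stop_input("no records supplied")
  ids <- vapply(records, `[[`, character(1), "id")
  whole_set <- if (params$specificity_whole_file) .records_as_set(records)
  audit <- list()
  sets <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    cands <- rbind(enumerate_candidates(rec, params, "forward", thermo),
                   enumerate_candidates(rec, params, "reverse", thermo))
    cands <- passes_filters(cands, params)
    scope_set <- if (params$specificity_whole_file) whole_set
                 else .records_as_set(records[i])
    if (any(cands$accepted)) {
      idx <- which(cands$accepted)
      hits <- vapply(cands$seq[idx], .count_in_set, numeric(1),
                     subject_set = scope_set, USE.NAMES = FALSE)
      nonspecific <- idx[hits != 1]
      if (length(nonspecific)) {
        cands$rejection_reasons[nonspecific] <- ifelse(
          cands$rejection_reasons[nonspecific] == "", "specificity",
          paste0(cands$rejection_reasons[nonspecific], ",specificity"))
        cands$accepted[nonspecific] <- FALSE
      }
    }
    if (keep_audit) audit[[rec$id]] <<- cands
    acc <- cands[cands$accepted, , drop = FALSE]
    acc <- acc[order(acc$start, acc$direction, acc$length), , drop = FALSE]
    rownames(acc) <- NULL
    acc$name <- .name_primers(acc)
    acc$rejection_reasons <- NULL
    acc$accepted <- NULL
    if (!nrow(acc) && !quiet) {
      warning(sprintf("record '%s': no primers passed design constraints", rec$id),
              call. = FALSE)
    }
    structure(list(target_id = rec$id, target_length = nchar(rec$seq),
                   primers = acc), class = "primer_set")
  })
  names(sets) <- ids
  if (keep_audit) attr(sets, "audit") <- audit
  sets
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %s (%d nt): %d primer(s)\n",
              x$target_id, x$target_length, nrow(x$primers)))
  if (nrow(x$primers)) {
    print(x$primers[, c("name", "direction", "start", "end", "length", "tm", "gc")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
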