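# Independent brute-force oracles.  These deliberately avoid the package's
# vectorized code paths: enumeration is a naive double loop, occurrence
# counting a sliding-window scan, filtering a re-statement of the rules, and
# the Tm oracle a direct hand summation over the shipped parameter table.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

naive_rc <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[strsplit(seq, "")[[1]]])), collapse = "")
}

# Hand summation of the NN model straight from the data file.
oracle_tm <- function(seq, C_T = 2.5e-7, Na = 0.05) {
  tab <- read.delim(system.file("extdata", "nn_unified_1998.tsv", package = "primap"),
                    comment.char = "#", stringsAsFactors = FALSE)
  row <- function(k) tab[tab$key == k, ]
  dH <- 0; dS <- 0
  for (b in c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))) {
    term <- if (b %in% c("G", "C")) row("init_GC") else row("init_AT")
    dH <- dH + term$dH; dS <- dS + term$dS
  }
  for (i in seq_len(nchar(seq) - 1)) {
    st <- row(substr(seq, i, i + 1))
    dH <- dH + st$dH; dS <- dS + st$dS
  }
  x <- 4
  if (identical(seq, naive_rc(seq))) {
    dH <- dH + row("sym")$dH; dS <- dS + row("sym")$dS; x <- 1
  }
  1000 * dH / (dS + 1.987 * log(C_T / x)) - 273.15 + 16.6 * log10(Na)
}

# Naive double loop over (start, length); no vectorization.
naive_enumerate <- function(record, params, direction) {
  L <- nchar(record$seq)
  W <- min(L, if (direction == "forward") params$five_prime_window
              else params$three_prime_window)
  out <- list()
  if (W < params$len_min) return(out)
  lo <- if (direction == "forward") 1L else L - W + 1L
  hi <- if (direction == "forward") W else L
  for (start in lo:hi) {
    for (len in params$len_min:params$len_max) {
      end <- start + len - 1L
      if (end > hi) next
      slice <- substr(record$seq, start, end)
      seq <- if (direction == "forward") slice else naive_rc(slice)
      out[[length(out) + 1L]] <- list(start = start, end = end, length = len,
                                      seq = seq, direction = direction)
    }
  }
  out
}

# Independent re-statement of the four filter rules.
naive_filter_reasons <- function(seq, tm, gc, params) {
  reasons <- character(0)
  len <- nchar(seq)
  if (len < params$len_min || len > params$len_max) reasons <- c(reasons, "length")
  if (gc < params$gc_min || gc > params$gc_max) reasons <- c(reasons, "gc_range")
  if (tm < params$tm_min || tm > params$tm_max) reasons <- c(reasons, "tm_range")
  if (params$gc_clamp) {
    last <- substr(seq, len, len)
    if (last != "G" && last != "C") reasons <- c(reasons, "gc_clamp")
  }
  reasons
}

# Sliding-window strand-aware occurrence count.
naive_count <- function(oligo, seqs) {
  rc <- naive_rc(oligo)
  k <- nchar(oligo)
  total <- 0L
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) {
      win <- substr(s, i, i + k - 1)
      if (win == oligo) total <- total + 1L
      if (win == rc) total <- total + 1L
    }
  }
  total
}

# End-to-end naive pipeline: enumerate + filter + specificity count.
naive_design <- function(records, params) {
  seqs_all <- vapply(records, `[[`, character(1), "seq")
  lapply(records, function(rec) {
    cands <- c(naive_enumerate(rec, params, "forward"),
               naive_enumerate(rec, params, "reverse"))
    kept <- Filter(function(cd) {
      tm <- calc_tm(cd$seq)
      gc <- gc_content(cd$seq)
      if (length(naive_filter_reasons(cd$seq, tm, gc, params))) return(FALSE)
      scope <- if (params$specificity_whole_file) seqs_all else rec$seq
      naive_count(cd$seq, scope) == 1L
    }, cands)
    key <- vapply(kept, function(cd) {
      sprintf("%09d_%s_%02d", cd$start, cd$direction, cd$length)
    }, character(1))
    kept[order(key)]
  })
}

make_record <- function(id, seq) seq_record(id, seq)

expect_magic <- function(path, bytes) {
  got <- readBin(path, "raw", n = length(bytes))
  expect_identical(got, as.raw(bytes))
}
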