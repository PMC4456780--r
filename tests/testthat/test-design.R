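test_that("design_params validates its invariants", {
  p <- design_params()
  expect_s3_class(p, "design_params")
  expect_error(design_params(len_min = 25, len_max = 20), "len_min",
               class = "primap_usage_error")
  expect_error(design_params(gc_min = 70, gc_max = 60), "gc_min")
  expect_error(design_params(tm_min = 70, tm_max = 60), "tm_min")
  expect_error(design_params(five_prime_window = 10, len_min = 18), "windows")
  expect_error(design_params(five_prime_window = 0), "positive")
})

test_that("candidate counts match closed-form combinatorics", {
  set.seed(31)
  rec <- make_record("r", random_dna(100))
  p <- design_params(five_prime_window = 30, three_prime_window = 30,
                     len_min = 20, len_max = 20)
  fwd <- enumerate_candidates(rec, p, "forward")
  expect_equal(nrow(fwd), 11)          # 30 - 20 + 1
  expect_equal(range(fwd$start), c(1, 11))

  p2 <- design_params(five_prime_window = 25, three_prime_window = 25,
                      len_min = 18, len_max = 22)
  rev <- enumerate_candidates(rec, p2, "reverse")
  expect_equal(nrow(rev), 8 + 7 + 6 + 5 + 4)   # sum over len 18..22 of 25-len+1
  expect_true(all(rev$start >= 100 - 25 + 1 & rev$end <= 100))
})

test_that("enumeration equals the naive double-loop oracle", {
  set.seed(32)
  rec <- make_record("r", random_dna(400))
  p <- design_params()
  for (dir in c("forward", "reverse")) {
    got <- enumerate_candidates(rec, p, dir)
    want <- naive_enumerate(rec, p, dir)
    key <- function(s, l) sprintf("%04d_%02d", s, l)
    got_k <- key(got$start, got$length)
    want_k <- vapply(want, function(cd) key(cd$start, cd$length), character(1))
    expect_setequal(got_k, want_k)
    want_seq <- vapply(want, `[[`, character(1), "seq")[match(got_k, want_k)]
    expect_identical(got$seq, want_seq)
    expect_equal(got$end, got$start + got$length - 1L)
  }
})

test_that("a window shorter than len_min warns and yields no candidates", {
  rec <- make_record("tiny", "ACGTACGTACGTACGTACGTACGT")  # 24 nt
  p <- design_params(five_prime_window = 150, three_prime_window = 150,
                     len_min = 30, len_max = 35)
  expect_warning(out <- enumerate_candidates(rec, p, "forward"), "shorter than len_min")
  expect_equal(nrow(out), 0)
})

test_that("filter audit equals an independently coded predicate", {
  set.seed(33)
  p <- design_params(gc_min = 40, gc_max = 60, tm_min = 52, tm_max = 65,
                     len_min = 18, len_max = 24, gc_clamp = TRUE)
  seqs <- vapply(1:1000, function(i) random_dna(sample(15:28, 1),
                                                gc = runif(1, 0.2, 0.8)),
                 character(1))
  cands <- data.frame(target_id = "t", direction = "forward", start = 1L,
                      end = nchar(seqs), length = nchar(seqs), seq = seqs,
                      tm = calc_tm(seqs),
                      gc = vapply(seqs, gc_content, numeric(1)),
                      stringsAsFactors = FALSE)
  audited <- passes_filters(cands, p)
  for (i in seq_len(nrow(audited))) {
    want <- naive_filter_reasons(seqs[i], cands$tm[i], cands$gc[i], p)
    got <- if (audited$rejection_reasons[i] == "") character(0) else
      strsplit(audited$rejection_reasons[i], ",", fixed = TRUE)[[1]]
    expect_setequal(got, want)
    expect_equal(audited$accepted[i], length(want) == 0)
  }
  # spot checks from the rule definitions
  at_end <- passes_filters(cands[substr(seqs, nchar(seqs), nchar(seqs)) %in%
                                   c("A", "T"), ][1, ], p)
  expect_match(at_end$rejection_reasons, "gc_clamp")
})

test_that("count_occurrences is strand-aware and counts overlaps", {
  expect_equal(count_occurrences("ACGT", list(make_record("r", "ACGTACGT"))), 4)
  expect_equal(count_occurrences("AAAAC", list(make_record("r", "GTTTT"))), 1)
  expect_equal(count_occurrences("AAA", list(make_record("r", "AAAAA"))), 3)
  set.seed(34)
  recs <- lapply(1:10, function(i) make_record(paste0("r", i), random_dna(200)))
  for (i in 1:25) {
    oligo <- random_dna(sample(4:8, 1))
    expect_equal(count_occurrences(oligo, recs),
                 naive_count(oligo, vapply(recs, `[[`, character(1), "seq")))
  }
})

test_that("a forced single-window case yields exactly that primer", {
  # build a 40-nt target whose first 20-mer passes every default filter
  seed <- 35
  repeat {
    set.seed(seed)
    head20 <- random_dna(20)
    if (gc_content(head20) >= 40 && gc_content(head20) <= 60 &&
        substr(head20, 20, 20) %in% c("G", "C") &&
        calc_tm(head20) >= 52 && calc_tm(head20) <= 65) break
    seed <- seed + 1
  }
  rec <- make_record("forced", paste0(head20, random_dna(20)))
  p <- design_params(five_prime_window = 20, three_prime_window = 20,
                     len_min = 20, len_max = 20, tm_min = 0, tm_max = 100,
                     gc_min = 0, gc_max = 100, gc_clamp = FALSE)
  suppressWarnings(sets <- design_primers(list(rec), p))
  fwd <- sets[[1]]$primers[sets[[1]]$primers$direction == "forward", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 1L)
  expect_equal(fwd$seq, head20)
  expect_equal(fwd$name[1], "1")
})

test_that("duplicated records kill whole-file specificity but not per-record", {
  set.seed(36)
  s <- random_dna(300)
  recs <- list(make_record("a", s), make_record("b", s))
  p_whole <- design_params(specificity_whole_file = TRUE)
  p_self <- design_params(specificity_whole_file = FALSE)
  suppressWarnings(sets_whole <- design_primers(recs, p_whole))
  sets_self <- design_primers(recs, p_self)
  expect_equal(vapply(sets_whole, function(x) nrow(x$primers), integer(1)),
               c(a = 0L, b = 0L))
  single <- design_primers(recs[1], p_self)
  expect_equal(sets_self[["a"]]$primers[, names(single[[1]]$primers)],
               single[[1]]$primers)
})

test_that("whole-file-specific primers are a subset of per-record ones", {
  set.seed(37)
  recs <- lapply(1:4, function(i) make_record(paste0("r", i), random_dna(250)))
  suppressWarnings({
    whole <- design_primers(recs, design_params(specificity_whole_file = TRUE))
    self <- design_primers(recs, design_params(specificity_whole_file = FALSE))
  })
  for (id in names(whole)) {
    expect_true(all(whole[[id]]$primers$seq %in% self[[id]]$primers$seq))
  }
})

test_that("design_primers matches the end-to-end naive pipeline", {
  planted <- planted_dataset(seed = 11)
  p <- design_params(five_prime_window = 60, three_prime_window = 60)
  suppressWarnings(got <- design_primers(planted$records, p))
  want <- naive_design(planted$records, p)
  for (i in seq_along(got)) {
    g <- got[[i]]$primers
    expect_equal(nrow(g), length(want[[i]]))
    if (!nrow(g)) next
    expect_equal(g$start, vapply(want[[i]], function(x) x$start, integer(1)))
    expect_identical(g$seq, vapply(want[[i]], `[[`, character(1), "seq"))
    expect_identical(g$direction,
                     vapply(want[[i]], `[[`, character(1), "direction"))
  }
})

test_that("tightening any single bound never increases the accepted count", {
  set.seed(38)
  for (rep in 1:20) {
    recs <- list(make_record("r", random_dna(200)))
    base <- design_params(five_prime_window = 50, three_prime_window = 50,
                          gc_clamp = FALSE, gc_min = 30, gc_max = 70,
                          tm_min = 45, tm_max = 70)
    count <- function(p) {
      suppressWarnings(sum(vapply(design_primers(recs, p),
                                  function(s) nrow(s$primers), integer(1))))
    }
    n0 <- count(base)
    tighter <- list(
      design_params(five_prime_window = 50, three_prime_window = 50,
                    gc_clamp = FALSE, gc_min = 40, gc_max = 70, tm_min = 45, tm_max = 70),
      design_params(five_prime_window = 50, three_prime_window = 50,
                    gc_clamp = FALSE, gc_min = 30, gc_max = 60, tm_min = 45, tm_max = 70),
      design_params(five_prime_window = 50, three_prime_window = 50,
                    gc_clamp = FALSE, gc_min = 30, gc_max = 70, tm_min = 52, tm_max = 70),
      design_params(five_prime_window = 50, three_prime_window = 50,
                    gc_clamp = FALSE, gc_min = 30, gc_max = 70, tm_min = 45, tm_max = 62),
      design_params(five_prime_window = 50, three_prime_window = 50,
                    gc_clamp = TRUE, gc_min = 30, gc_max = 70, tm_min = 45, tm_max = 70))
    for (p in tighter) expect_lte(count(p), n0)
  }
})

test_that("output is invariant under record order permutation", {
  set.seed(39)
  recs <- lapply(1:5, function(i) make_record(paste0("r", i), random_dna(300)))
  suppressWarnings({
    a <- design_primers(recs, design_params())
    b <- design_primers(rev(recs), design_params())
  })
  for (id in names(a)) expect_equal(a[[id]]$primers, b[[id]]$primers)
})

test_that("primer names are unique within each set", {
  suppressWarnings(
    sets <- design_primers(read_fasta(system.file("extdata", "test_seqs.fasta",
                                                  package = "primap")),
                           design_params()))
  for (s in sets) expect_false(any(duplicated(s$primers$name)))
})
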