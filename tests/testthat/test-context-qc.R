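test_that("call_read_contexts matches the hand-enumerated example", {
  ref <- c(chr = "TTCGACCATT")
  # positions (0-based): C at 2 -> CpG; C at 5 (next C, then A) -> CHH;
  # C at 6 (next A, then T) -> CHH
  r1 <- list(rname = "chr", start = 0L, seq = "TTCGACCATT", strand = "+")
  expect_equal(call_read_contexts(r1, ref), "..Z..HH...")
  r2 <- list(rname = "chr", start = 0L, seq = "TTCGATTATT", strand = "+")
  expect_equal(call_read_contexts(r2, ref), "..Z..hh...")
  # no origin-strand Cs at all
  ref2 <- c(chr = "TTGATTGATT")
  r3 <- list(rname = "chr", start = 0L, seq = "TTGATTGATT", strand = "+")
  expect_equal(call_read_contexts(r3, ref2), "..........")
})

test_that("context of read-terminal Cs comes from the reference", {
  ref <- c(chr = "AACATTT")
  # read covers only the first 3 bases; the C at 2 needs downstream
  # reference bases A,T -> CHH
  r <- list(rname = "chr", start = 0L, seq = "AAC", strand = "+")
  expect_equal(call_read_contexts(r, ref), "..H")
  # at the very reference end the context is unresolvable
  ref2 <- c(chr = "AAC")
  expect_equal(call_read_contexts(list(rname = "chr", start = 0L,
                                       seq = "AAC", strand = "+"), ref2),
               "...")
})

test_that("reads beyond reference bounds or with indel spans error", {
  ref <- c(chr = "ACGTACGT")
  bad <- make_reads("chr", 5, "ACGT", "+")
  expect_error(add_call_strings(bad, ref), "past end")
  bad2 <- make_reads("chr", 0, "ACG", "+")
  bad2$end <- 5L
  expect_error(add_call_strings(bad2, ref), "indel")
})

test_that("count_unconverted_ch follows the definition", {
  expect_equal(count_unconverted_ch(""), 0L)
  expect_equal(count_unconverted_ch("Z.xH..X"), 2L)
  # oracle equivalence on random call strings
  set.seed(5)
  alphabet <- c("Z", "z", "X", "x", "H", "h", ".")
  strs <- vapply(1:1000, function(i)
    paste(sample(alphabet, sample(0:30, 1), replace = TRUE),
          collapse = ""), character(1))
  tally <- vapply(strsplit(strs, ""), function(ch)
    sum(ch == "X") + sum(ch == "H"), numeric(1))
  expect_equal(count_unconverted_ch(strs), as.integer(tally))
})

test_that("per-read CH counts match the independent oracle", {
  ref <- random_ref(2000, seed = 21)
  set.seed(22)
  n <- 300
  start <- sample(0:1800, n, replace = TRUE)
  len <- sample(30:100, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(ref, start + 1, start + len)
  # mutate some bases so converted/unconverted states vary
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), max(1, length(ch) %/% 5))
    ch[i] <- vapply(ch[i], function(b) switch(b, C = "T", G = "A", T = "C",
                                              A = "G"), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  reads <- make_reads("ref1", start, seqs, strand)
  reads <- add_call_strings(reads, c(ref1 = ref))
  got <- count_unconverted_ch(reads$xm)
  want <- vapply(seq_len(n), function(i)
    oracle_ch_count(seqs[i], ref, start[i], strand[i]), integer(1))
  expect_equal(got, as.integer(want))
})

test_that("classify_read_ch categories and keep decisions", {
  prof <- data.frame(n_unconverted_ch = c(0L, 2L, 3L, 7L))
  out <- classify_read_ch(prof)
  expect_equal(as.character(out$category), c("0", "2", "3+", "3+"))
  expect_equal(out$keep, c(TRUE, TRUE, FALSE, FALSE))
  # threshold configurable
  out5 <- classify_read_ch(prof, filter_config(ch_threshold = 5))
  expect_equal(out5$keep, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(filter_config(ch_threshold = 0), ">= 1")
})

test_that("dedup_reads keeps first per (ref,start,end,strand) key", {
  reads <- make_reads(c("a", "a", "a", "b"), c(5, 5, 5, 5),
                      c("ACGT", "ACGT", "ACGT", "ACGT"),
                      c("+", "+", "-", "+"))
  out <- dedup_reads(reads)
  expect_equal(nrow(out$reads), 3L)
  expect_equal(out$n_removed, 1L)
  expect_equal(out$reads$qname[1], "r001")  # first encountered retained
  # brute-force distinct-key oracle on a random duplicated set
  set.seed(8)
  n <- 400
  r2 <- make_reads(sample(c("a", "b"), n, TRUE),
                   sample(1:20, n, TRUE),
                   "AC", sample(c("+", "-"), n, TRUE))
  got <- dedup_reads(r2)
  keys <- unique(paste(r2$rname, r2$start, r2$end, r2$strand))
  expect_equal(nrow(got$reads), length(keys))
})

test_that("filter_reads partitions exhaustively and purely", {
  w <- control_world(n_frag = 400, seed = 5,
                     conv = conversion_params(err = 0))
  reads <- add_call_strings(w$reads, w$ri)
  fl <- filter_reads(reads)
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(reads))
  expect_length(intersect(fl$kept$qname, fl$removed$qname), 0)
  # kept call strings untouched
  expect_equal(fl$kept$xm,
               reads$xm[match(fl$kept$qname, reads$qname)])
  # raising the threshold weakly grows the kept set
  kept3 <- filter_reads(reads, config = filter_config(3))$kept$qname
  kept5 <- filter_reads(reads, config = filter_config(5))$kept$qname
  expect_true(all(kept3 %in% kept5))
  # all fully converted -> nothing removed
  clean <- control_world(n_frag = 100,
                         conv = conversion_params(eff = 1, rho_fail = 0,
                                                  eff_fail = 0, err = 0))
  fl2 <- filter_reads(add_call_strings(clean$reads, clean$ri))
  expect_equal(nrow(fl2$removed), 0L)
})

test_that("removal fraction tracks the analytic binomial mixture", {
  conv <- conversion_params(eff = 1, rho_fail = 0.01, eff_fail = 0.5,
                            err = 0)
  w <- control_world(n_frag = 4000, conv = conv, seed = 13)
  reads <- add_call_strings(w$reads, w$ri)
  fl <- filter_reads(reads)
  # per-read CH-site counts from the reference truth
  n_ch <- nchar(gsub("[^XHxh]", "", reads$xm))  # all CH sites seen
  p_i <- ch_removal_probability(n_ch, conv)
  expected <- mean(p_i)
  sigma <- sqrt(sum(p_i * (1 - p_i))) / length(p_i)
  expect_lt(abs(fl$summary$removal_fraction - expected), 3 * sigma)
})

test_that("ch_read_report reproduces hand arithmetic and invariances", {
  xm <- c(rep("....", 6), rep("H...", 2), "HH..", "HHH.")
  reads <- make_reads("a", 0, "ACGT", "+")[rep(1, 10), ]
  reads$xm <- xm
  rep1 <- ch_read_report(reads)
  expect_equal(unname(as.numeric(rep1$proportions)),
               c(0.6, 0.2, 0.1, 0.1))
  expect_equal(rep1$share_top_among_ch, 0.25)
  # permutation invariance
  rep2 <- ch_read_report(reads[sample(10), ])
  expect_equal(rep2$proportions, rep1$proportions)
  # degenerate cases
  reads0 <- reads; reads0$xm <- rep("....", 10)
  expect_warning(rep0 <- ch_read_report(reads0), "share")
  expect_equal(rep0$share_top_among_ch, 0)
  expect_error(ch_read_report(reads[0, ]), "no reads")
})
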