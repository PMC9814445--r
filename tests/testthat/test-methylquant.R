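test_that("aggregate_cpg tallies calls and conserves counts", {
  ref <- c(chr = "TTCGACCATT")
  # 4 Watson reads over the same span; one has the CpG converted
  seqs <- c("TTCGACCATT", "TTCGACCATT", "TTCGACCATT", "TTTGACCATT")
  reads <- make_reads("chr", 0, seqs, "+")
  reads <- add_call_strings(reads, ref)
  agg <- aggregate_cpg(reads)
  cpg <- agg$cpg
  expect_equal(nrow(cpg), 1L)
  expect_equal(cpg$pos, 2L)
  expect_equal(cpg$meth, 3L)
  expect_equal(cpg$unmeth, 1L)
  expect_equal(cpg$beta, 0.75)
  # count conservation over all sites
  n_calls <- sum(nchar(gsub("[.]", "", reads$xm)))
  expect_equal(sum(agg$cpg$meth + agg$cpg$unmeth) +
                 sum(agg$ch$meth + agg$ch$unmeth), n_calls)
  # empty input
  empty <- aggregate_cpg(reads[0, ])
  expect_equal(nrow(empty$cpg), 0L)
})

test_that("strand merging sums Watson and Crick CpG counts", {
  ref <- c(chr = "AACGTT")
  rw <- make_reads("chr", 0, "AACGTT", "+")
  rc <- make_reads("chr", 0, "AACGTT", "-")
  reads <- rbind(rw, rc)
  reads <- add_call_strings(reads, ref)
  sep <- aggregate_cpg(reads)$cpg
  expect_equal(nrow(sep), 2L)          # C at 2 (+), G at 3 (-)
  merged <- aggregate_cpg(reads, merge_strands = TRUE)$cpg
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$pos, 2L)
  expect_equal(merged$meth, 2L)
})

test_that("CpG-methylated control yields beta 1 under perfect conversion", {
  w <- control_world(n_frag = 200,
                     conv = conversion_params(eff = 1, rho_fail = 0,
                                              eff_fail = 0, err = 0))
  reads <- add_call_strings(w$reads, w$ri)
  agg <- aggregate_cpg(reads)
  puc <- agg$cpg[agg$cpg$rname == "puc19_synth", ]
  expect_gt(nrow(puc), 50)
  expect_true(all(puc$beta == 1))
  lam <- agg$cpg[agg$cpg$rname == "lambda_synth", ]
  expect_true(all(lam$beta == 0))
})

test_that("classify_sites uses strict thresholds", {
  rec <- data.frame(beta = c(0, 1, 0.01, 0.5, 0.009, 0.81))
  out <- classify_sites(rec)
  expect_equal(as.character(out$class),
               c("hypo", "hyper", "intermediate", "intermediate",
                 "hypo", "hyper"))
  expect_error(site_class_config(hypo = 0.9, hyper = 0.5), "hypo < hyper")
})

test_that("conversion_efficiency arithmetic, errors and invariance", {
  rec <- data.frame(meth = c(0, 0), unmeth = c(600, 400))
  expect_equal(conversion_efficiency(rec)$efficiency, 1)
  rec2 <- data.frame(meth = c(1, 1), unmeth = c(499, 499))
  est <- conversion_efficiency(rec2)
  expect_equal(est$efficiency, 0.998)
  expect_true(est$ci[1] <= 0.998 && est$ci[2] >= 0.998)
  expect_error(conversion_efficiency(data.frame(meth = 0, unmeth = 0)),
               "no calls")
  # invariant to record order
  expect_equal(conversion_efficiency(rec2[2:1, ])$efficiency,
               est$efficiency)
})

test_that("conversion_efficiency recovers the simulated rate", {
  ref <- random_ref(3000, seed = 31)
  reads <- simulate_control_run(
    ref_index(c(lambda_synth = ref)),
    list(lambda_synth = methylome_unmethylated(ref)),
    fragment_params(n_fragments = 1200),
    conversion_params(eff = 0.998, rho_fail = 0, eff_fail = 0.5, err = 0),
    seed = 17)
  reads <- add_call_strings(reads, c(lambda_synth = ref))
  agg <- aggregate_cpg(reads)
  est <- conversion_efficiency(rbind(agg$cpg, agg$ch))
  sigma <- sqrt(0.998 * 0.002 / est$n_calls)
  expect_lt(abs(est$efficiency - 0.998), 3 * sigma)
})

test_that("hotspot detection applies the window rule exactly", {
  cpg <- data.frame(rname = "chr", pos = 100L, strand = "+",
                    context = "CpG", meth = 2L, unmeth = 98L, beta = 0.02)
  ch <- data.frame(rname = "chr", pos = 120L, strand = "+",
                   context = "CHH", meth = 3L, unmeth = 97L, beta = 0.03)
  hit <- detect_incomplete_conversion_hotspots(cpg, ch, window = 50)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$pos, 100L)
  expect_equal(hit$support_pos, "120")
  expect_equal(nrow(detect_incomplete_conversion_hotspots(cpg, ch,
                                                          window = 10)),
               0L)
  # all-zero betas -> empty
  cpg0 <- transform(cpg, beta = 0); ch0 <- transform(ch, beta = 0)
  expect_equal(nrow(detect_incomplete_conversion_hotspots(cpg0, ch0)), 0L)
  # different contig is never support
  ch2 <- transform(ch, rname = "other")
  expect_equal(nrow(detect_incomplete_conversion_hotspots(cpg, ch2)), 0L)
  # sorted by CpG beta descending
  cpg2 <- rbind(cpg, transform(cpg, pos = 130L, beta = 0.09))
  hits <- detect_incomplete_conversion_hotspots(cpg2, ch, window = 50)
  expect_equal(hits$beta, c(0.09, 0.02))
})

test_that("compare_filtering_effect: identical inputs and degenerate sets", {
  rec <- data.frame(rname = "chr", pos = c(1L, 5L, 9L), strand = "+",
                    beta = c(0.001, 0.002, 0.9))
  cls <- data.frame(rname = "chr", pos = c(1L, 5L, 9L), strand = "+",
                    class = c("hypo", "hypo", "hyper"))
  out <- compare_filtering_effect(rec, rec, cls)
  expect_true(all(out$mean_delta == 0))
  expect_true(all(is.na(out$t)))
  rec2 <- transform(rec, pos = pos + 100L)
  expect_error(compare_filtering_effect(rec, rec2, cls), "no sites")
})

test_that("filtering lowers apparent methylation only where it should", {
  conv <- conversion_params(eff = 0.998, rho_fail = 0.03, eff_fail = 0.5,
                            err = 0)
  w <- control_world(n_frag = 3000, conv = conv, seed = 19)
  reads <- add_call_strings(w$reads, w$ri)
  before <- aggregate_cpg(reads)$cpg
  after <- aggregate_cpg(filter_reads(reads)$kept)$cpg
  # truth classes from the simulation design
  cls <- data.frame(rname = before$rname, pos = before$pos,
                    strand = before$strand,
                    class = ifelse(before$rname == "lambda_synth",
                                   "hypo", "hyper"))
  cmp <- compare_filtering_effect(before, after, cls)
  hypo <- cmp[cmp$class == "hypo", ]
  hyper <- cmp[cmp$class == "hyper", ]
  expect_lt(hypo$mean_after, hypo$mean_before)      # strict decrease
  expect_lt(abs(hyper$mean_delta), 0.005)           # essentially unchanged
})
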