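test_that("differential tests recover planted effects and nulls", {
  set.seed(41)
  n <- 20
  labels <- rep(c("HCC", "ctrl"), each = n / 2)
  expr <- matrix(rnorm(50 * n, 8, 0.3), 50, n,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  # identical groups in expectation -> log2FC near 0; exact for constant row
  expr["g01", ] <- 5
  de0 <- differential_expression(expr, labels)
  expect_equal(de0$log2fc[de0$gene == "g01"], 0)
  expect_true(de0$zero_variance[de0$gene == "g01"])
  expect_equal(de0$p[de0$gene == "g01"], 1)
  # planted 4-fold shift (2 on log2 scale)
  expr["g02", labels == "HCC"] <- expr["g02", labels == "HCC"] + 2
  de <- differential_expression(expr, labels)
  row <- de[de$gene == "g02", ]
  expect_equal(row$log2fc, 2, tolerance = 0.25)
  expect_lt(row$fdr, 0.05)

  beta <- matrix(runif(40 * n, 0.1, 0.2), 40, n,
                 dimnames = list(sprintf("c%02d", 1:40), NULL))
  beta["c05", labels == "HCC"] <- beta["c05", labels == "HCC"] + 0.4
  dm <- differential_methylation(beta, labels)
  expect_equal(dm$delta_beta[dm$cpg == "c05"], 0.4, tolerance = 0.1)
  expect_lt(dm$fdr[dm$cpg == "c05"], 0.05)
})

test_that("null p-values are approximately uniform", {
  set.seed(42)
  n <- 40
  labels <- sample(rep(c("HCC", "ctrl"), each = n / 2))
  beta <- matrix(runif(400 * n), 400, n,
                 dimnames = list(sprintf("c%03d", 1:400), NULL))
  dm <- differential_methylation(beta, labels)
  expect_gt(mean(dm$p), 0.42)
  expect_lt(mean(dm$p), 0.58)
  expect_lt(mean(dm$p < 0.05), 0.12)
})

test_that("BH FDR equals the brute-force step-up oracle", {
  set.seed(43)
  p <- runif(20)
  labels <- rep(c("HCC", "ctrl"), each = 5)
  # the implementation's adjustment on arbitrary p equals the oracle
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  # and the same holds inside differential_methylation output
  beta <- matrix(runif(20 * 10), 20, 10,
                 dimnames = list(sprintf("c%02d", 1:20), NULL))
  dm <- differential_methylation(beta, labels)
  expect_equal(dm$fdr, oracle_bh(dm$p), tolerance = 1e-12)
})

test_that("equal-variance t matches the textbook formula row-wise", {
  set.seed(44)
  labels <- rep(c("HCC", "ctrl"), c(5, 5))
  m <- matrix(rnorm(30), 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  dm <- differential_methylation(m, labels)
  for (i in 1:3) {
    expect_equal(dm$t[i], oracle_t(m[i, 1:5], m[i, 6:10]),
                 tolerance = 1e-12)
  }
})

test_that("select_hcc_markers applies all four rules", {
  de <- data.frame(gene = c("gA", "gB", "gC"),
                   log2fc = c(-2, 2, -2), p = 0.001,
                   fdr = c(0.001, 0.001, 0.2))
  dm <- data.frame(cpg = c("c1", "c2", "c3", "c4"),
                   delta_beta = c(0.4, 0.4, 0.4, 0.1), p = 0.001,
                   fdr = 0.001)
  map <- data.frame(cpg = c("c1", "c2", "c3", "c4"),
                    gene = c("gA", "gB", "gA", "gA"))
  out <- select_hcc_markers(de, dm, map)
  expect_true(out$selected[out$cpg == "c1"])    # all four rules met
  expect_false(out$selected[out$cpg == "c2"])   # upregulated gene
  expect_false(out$selected[out$cpg == "c4"])   # delta beta too small
  # gene with high FDR fails
  de2 <- transform(de, fdr = c(0.2, 0.001, 0.2))
  out2 <- select_hcc_markers(de2, dm, map)
  expect_false(out2$selected[out2$cpg == "c1"])
  # unmapped CpGs are skipped with a message
  expect_message(select_hcc_markers(de, dm, map[1:2, ]), "skipped")
})

test_that("selection is monotone in every threshold", {
  set.seed(45)
  n <- 200
  de <- data.frame(gene = sprintf("g%03d", 1:n),
                   log2fc = rnorm(n, 0, 2), fdr = runif(n))
  dm <- data.frame(cpg = sprintf("c%03d", 1:n),
                   delta_beta = runif(n, -1, 1), fdr = runif(n))
  map <- data.frame(cpg = dm$cpg, gene = de$gene)
  strict <- selection_thresholds()
  loose <- selection_thresholds(fdr_expr = 0.2, abs_log2fc = 0.5,
                                fdr_meth = 0.2, abs_delta_beta = 0.1)
  s1 <- select_hcc_markers(de, dm, map, strict)
  s2 <- select_hcc_markers(de, dm, map, loose)
  expect_true(all(s1$cpg[s1$selected] %in% s2$cpg[s2$selected]))
})

test_that("blood_filter removes exactly the blood-high markers", {
  cand <- data.frame(cpg = c("c1", "c2", "c3"))
  blood <- matrix(c(0.9, 0.55, 0.2), 3, 4,
                  dimnames = list(c("c1", "c2", "c3"), NULL))
  hcc <- matrix(0.5, 3, 4, dimnames = list(c("c1", "c2", "c3"), NULL))
  out <- blood_filter(cand, blood, hcc)
  expect_setequal(out$cpg, c("c2", "c3"))      # 0.05 <= 0.1 retained
  expect_equal(attr(out, "removed")$cpg, "c1")
  # absent from blood matrix -> retained with warning
  cand2 <- data.frame(cpg = c("c1", "cX"))
  expect_warning(out2 <- blood_filter(cand2, blood, hcc), "absent")
  expect_true("cX" %in% out2$cpg)
  # brute-force re-check on random matrices
  set.seed(46)
  ids <- sprintf("m%02d", 1:30)
  b <- matrix(runif(30 * 5), 30, 5, dimnames = list(ids, NULL))
  h <- matrix(runif(30 * 5), 30, 5, dimnames = list(ids, NULL))
  got <- blood_filter(data.frame(cpg = ids), b, h)
  want <- ids[!(rowMeans(b) - rowMeans(h) > 0.1)]
  expect_setequal(got$cpg, want)
})

test_that("in_silico_convert matches hand-converted examples", {
  expect_equal(in_silico_convert("ACGTCA", "watson", "unmethylated"),
               "ATGTTA")
  expect_equal(in_silico_convert("ACGTCA", "watson", "cpg_methylated"),
               "ACGTTA")
  expect_equal(in_silico_convert("ACGTCA", "crick", "cpg_methylated"),
               "TGACGT")
  expect_equal(in_silico_convert("ACGTCA", "crick", "unmethylated"),
               "TGATGT")
  expect_equal(in_silico_convert("ACNGT", "watson", "unmethylated"),
               "ATNGT")
  expect_error(in_silico_convert("ACGU", "watson", "unmethylated"),
               "A/C/G/T/N")
})

test_that("probe sets satisfy the conversion-difference invariants", {
  ref <- random_ref(600, seed = 47)
  ri <- ref_index(c(chr = ref))
  cpgs <- which(ri[[1]]$watson == "Z") - 1L   # 0-based
  pos <- cpgs[cpgs > 100 & cpgs < 500][1:5]
  for (p in pos) {
    ps <- design_probe_set(p, c(chr = ref), id = "x")
    expect_length(ps, 5L)
    expect_true(all(nchar(ps) == 120))
    orig <- strsplit(ps[["x_orig"]], "")[[1]]
    mW <- strsplit(ps[["x_mW"]], "")[[1]]
    uW <- strsplit(ps[["x_uW"]], "")[[1]]
    cpos <- which(orig == "C")
    cpg_c <- cpos[orig[pmin(cpos + 1, 120)] == "G" & cpos < 120]
    # methylated Watson differs from the original only at non-CpG Cs
    expect_equal(which(mW != orig), setdiff(cpos, cpg_c))
    # unmethylated Watson differs exactly at all C positions
    expect_equal(which(uW != orig), cpos)
    expect_false(any(uW == "C"))
    # deterministic
    expect_identical(ps, design_probe_set(p, c(chr = ref), id = "x"))
  }
  expect_error(design_probe_set(10, c(chr = substr(ref, 1, 60))),
               "shorter")
})

test_that("probe windows shift at reference edges and FASTA writes", {
  ref <- random_ref(300, seed = 48)
  ri <- ref_index(c(chr = ref))
  cpgs <- which(ri[[1]]$watson == "Z") - 1L
  edge <- cpgs[cpgs < 50][1]
  expect_message(ps <- design_probe_set(edge, c(chr = ref)), "shifted")
  expect_true(all(nchar(ps) == 120))
  tf <- tempfile(fileext = ".fasta")
  probes <- design_probe_panel(cpgs[cpgs > 100][1:2], c(chr = ref),
                               fasta = tf)
  back <- read_reference_fasta(tf)
  expect_equal(unname(back), unname(probes))
  expect_equal(length(back), 10L)
})
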