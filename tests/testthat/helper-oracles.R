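# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's ref_index/call-string machinery so that
# oracle checks exercise a second code path.

# Naive per-read unconverted-CH count: regex-scan the reference for
# cytosines whose two downstream origin-strand bases resolve a CH context
# (first base A/C/T, second base any of ACGT), then check whether the read
# retains C there. Crick reads are handled by reverse-complementing.
oracle_ch_count <- function(read_seq, ref_seq, start, strand) {
  len <- nchar(read_seq)
  if (strand == "+") {
    win <- substr(ref_seq, start + 1, start + len + 2)  # 2 bases context
    m <- gregexpr("C(?=[ACT][ACGT])", win, perl = TRUE)[[1]]
    if (m[1] == -1) return(0L)
    offs <- m[m <= len]
    sum(substring(read_seq, offs, offs) == "C")
  } else {
    # Crick C = G on forward; context is upstream on forward coordinates
    wstart <- max(0L, start - 2L)
    win <- substr(ref_seq, wstart + 1, start + len)
    rc <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                                     collapse = ""))
    winrc <- rc(win)
    m <- gregexpr("C(?=[ACT][ACGT])", winrc, perl = TRUE)[[1]]
    if (m[1] == -1) return(0L)
    # winrc index j maps to forward position start+len-j (0-based), i.e.
    # read offset len - j + 1 (1-based); pad-region matches fall out of range
    fwd <- len - m + 1
    fwd <- fwd[fwd >= 1 & fwd <= len]
    sum(substring(read_seq, fwd, fwd) == "G")
  }
}

# Number of CH-context cytosines (origin strand) under a read span,
# counted from the reference alone — the truth quantity entering the
# analytic binomial-mixture removal probability.
oracle_ch_sites <- function(len, ref_seq, start, strand) {
  if (strand == "+") {
    win <- substr(ref_seq, start + 1, start + len + 2)
    m <- gregexpr("C(?=[ACT][ACGT])", win, perl = TRUE)[[1]]
    if (m[1] == -1) return(0L)
    sum(m <= len)
  } else {
    wstart <- max(0L, start - 2L)
    win <- substr(ref_seq, wstart + 1, start + len)
    rc <- chartr("ACGTN", "TGCAN",
                 paste(rev(strsplit(win, "")[[1]]), collapse = ""))
    m <- gregexpr("C(?=[ACT][ACGT])", rc, perl = TRUE)[[1]]
    if (m[1] == -1) return(0L)
    sum(m <= len)
  }
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# AUC by exhaustive pair counting (ties at half weight).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Equal-variance two-sample t by the textbook formula.
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Build a converted_reads data.frame from parallel vectors.
make_reads <- function(rname, start, seq, strand, qname = NULL) {
  n <- length(start)
  out <- data.frame(
    qname = if (is.null(qname)) sprintf("r%03d", seq_len(n)) else qname,
    rname = rname, start = as.integer(start),
    end = as.integer(start) + nchar(seq), strand = strand,
    mate = "single", seq = seq)
  class(out) <- c("converted_reads", "data.frame")
  out
}

# Random reference of given length (uniform ACGT).
random_ref <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small standard control world used by several tests.
control_world <- function(n_frag = 1500, lambda_len = 4000, puc_len = 1500,
                          conv = conversion_params(err = 0), seed = 3) {
  refs <- synthetic_control_refs(lambda_length = lambda_len,
                                 puc_length = puc_len, seed = seed)
  ri <- ref_index(refs)
  meth <- list(lambda_synth = methylome_unmethylated(ri["lambda_synth"]),
               puc19_synth = methylome_cpg_methylated(ri["puc19_synth"]))
  reads <- simulate_control_run(
    ri, meth, fragment_params(n_fragments = n_frag), conv, seed = seed)
  list(refs = refs, ri = ri, meth = meth, reads = reads, conv = conv)
}

# Fast training configuration for unit tests (single grid point).
fast_config <- function(seed = 1, folds = 3) {
  train_config(folds = folds,
               grid = data.frame(n_trees = 60, max_depth = 2,
                                 learning_rate = 0.1),
               rfe_step_frac = 0.3, seed = seed)
}
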