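## Marker-selection rules and the five-probe in-silico-converted capture
## panel designer.
##
## Selection screens tumor-vs-non-tumor tissue for CpGs that are
## hypermethylated while their linked gene is downregulated, then drops
## markers that are already methylated in whole blood (the dominant cfDNA
## background).

#' Marker selection thresholds
#'
#' @param fdr_expr,abs_log2fc differential-expression screen: FDR < 0.05 and
#'   |log2 fold change| > 1.
#' @param fdr_meth,abs_delta_beta differential-methylation screen: FDR < 0.05
#'   and |delta beta| > 0.2.
#' @param blood_delta a CpG is dropped when mean blood beta exceeds mean
#'   tumor-tissue beta by more than this (default 0.1).
#' @return a `selection_thresholds` list.
#' @export
selection_thresholds <- function(fdr_expr = 0.05, abs_log2fc = 1,
                                 fdr_meth = 0.05, abs_delta_beta = 0.2,
                                 blood_delta = 0.1) {
  stopifnot(fdr_expr > 0, fdr_expr < 1, fdr_meth > 0, fdr_meth < 1,
            abs_log2fc > 0, abs_delta_beta > 0, blood_delta > 0)
  structure(list(fdr_expr = fdr_expr, abs_log2fc = abs_log2fc,
                 fdr_meth = fdr_meth, abs_delta_beta = abs_delta_beta,
                 blood_delta = blood_delta), class = "selection_thresholds")
}

## Vectorised equal-variance two-sample t test across matrix rows.
## Returns effect (mean A - mean B), t, p; zero-variance rows get p = 1 and
## a flag, so uninformative features can never look significant.
row_t_test <- function(mat, labels, case) {
  a <- labels == case
  if (sum(a) < 2 || sum(!a) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  n1 <- sum(a); n2 <- sum(!a)
  m1 <- rowMeans(mat[, a, drop = FALSE])
  m2 <- rowMeans(mat[, !a, drop = FALSE])
  v1 <- apply(mat[, a, drop = FALSE], 1, var)
  v2 <- apply(mat[, !a, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- !is.finite(se) | se == 0
  p[zero_var] <- 1
  tstat[zero_var] <- NA_real_
  data.frame(effect = m1 - m2, t = tstat, p = p, zero_variance = zero_var)
}

#' Differential expression between tumor and non-tumor tissue
#'
#' Per-gene equal-variance two-sample t test on log2 expression with
#' Benjamini-Hochberg FDR. The matrix is expected on the log2 scale already
#' (set `log2_input = FALSE` to have `log2(x + 1)` applied). Sex-chromosome
#' genes are expected to have been excluded upstream.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param labels character/factor per sample; `case` names the tumor group.
#' @param case label of the tumor group (default `"HCC"`).
#' @param log2_input is `expr` already log2-transformed?
#' @return data.frame: `gene`, `log2fc` (case minus control), `t`, `p`,
#'   `fdr`, `zero_variance`.
#' @export
differential_expression <- function(expr, labels, case = "HCC",
                                    log2_input = TRUE) {
  if (!log2_input) expr <- log2(expr + 1)
  res <- row_t_test(expr, labels, case)
  data.frame(gene = rownames(expr), log2fc = res$effect, t = res$t,
             p = res$p, fdr = p.adjust(res$p, "BH"),
             zero_variance = res$zero_variance, row.names = NULL)
}

#' Differential methylation between tumor and non-tumor tissue
#'
#' Per-CpG equal-variance two-sample t test on beta values with BH FDR;
#' the effect is the raw difference of group mean betas (delta beta).
#'
#' @param beta CpGs x samples matrix of beta values with rownames.
#' @param labels,case as in [differential_expression()].
#' @return data.frame: `cpg`, `delta_beta`, `t`, `p`, `fdr`,
#'   `zero_variance`.
#' @export
differential_methylation <- function(beta, labels, case = "HCC") {
  res <- row_t_test(beta, labels, case)
  data.frame(cpg = rownames(beta), delta_beta = res$effect, t = res$t,
             p = res$p, fdr = p.adjust(res$p, "BH"),
             zero_variance = res$zero_variance, row.names = NULL)
}

#' Select candidate markers: hypermethylated CpGs of downregulated genes
#'
#' Keeps CpGs with delta beta > `abs_delta_beta` at FDR below `fdr_meth`
#' whose linked gene is downregulated in tumor (log2FC < -`abs_log2fc`) at
#' FDR below `fdr_expr`. CpGs without a gene mapping are skipped (count
#' messaged).
#'
#' @param de output of [differential_expression()].
#' @param dm output of [differential_methylation()].
#' @param map data.frame linking markers to genes: columns `cpg`, `gene`.
#' @param thresholds a [selection_thresholds()].
#' @return data.frame of candidates with per-rule flags and a `selected`
#'   column; one row per mapped CpG.
#' @export
select_hcc_markers <- function(de, dm, map, thresholds =
                                 selection_thresholds()) {
  unmapped <- setdiff(dm$cpg, map$cpg)
  if (length(unmapped))
    message(length(unmapped), " CpG(s) without gene mapping skipped")
  cand <- merge(merge(dm, map, by = "cpg"), de, by = "gene",
                suffixes = c("_meth", "_expr"))
  cand$pass_meth <- cand$delta_beta > thresholds$abs_delta_beta &
    cand$fdr_meth < thresholds$fdr_meth
  cand$pass_expr <- cand$log2fc < -thresholds$abs_log2fc &
    cand$fdr_expr < thresholds$fdr_expr
  cand$selected <- cand$pass_meth & cand$pass_expr
  cand[order(cand$cpg), c("cpg", "gene", "delta_beta", "fdr_meth",
                          "log2fc", "fdr_expr", "pass_meth", "pass_expr",
                          "selected")]
}

#' Remove markers methylated in whole blood
#'
#' A candidate CpG is removed iff its mean beta in non-tumor blood exceeds
#' its mean beta in tumor tissue by more than `blood_delta`. CpGs absent
#' from the blood matrix are retained with a warning.
#'
#' @param candidates data.frame with a `cpg` column (e.g. the selected rows
#'   of [select_hcc_markers()]).
#' @param blood_beta CpGs x samples beta matrix for blood.
#' @param hcc_beta CpGs x samples beta matrix for tumor tissue.
#' @param blood_delta threshold (default 0.1, strict >).
#' @return `candidates` with `blood_mean`, `hcc_mean`, `blood_removed`
#'   columns, restricted to retained rows; removed rows are attached as
#'   attribute `"removed"`.
#' @export
blood_filter <- function(candidates, blood_beta, hcc_beta,
                         blood_delta = 0.1) {
  missing_blood <- setdiff(candidates$cpg, rownames(blood_beta))
  if (length(missing_blood))
    warning(length(missing_blood),
            " candidate(s) absent from blood matrix; retained")
  bm <- rowMeans(blood_beta)[candidates$cpg]
  hm <- rowMeans(hcc_beta)[candidates$cpg]
  candidates$blood_mean <- unname(bm)
  candidates$hcc_mean <- unname(hm)
  rem <- !is.na(bm) & !is.na(hm) & (bm - hm > blood_delta)
  candidates$blood_removed <- rem
  out <- candidates[!rem, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- candidates[rem, , drop = FALSE]
  out
}

#' Convert a probe sequence in silico
#'
#' Emulates full conversion of one strand under a methylation assumption.
#' Watson: under `"unmethylated"` every C becomes T; under
#' `"cpg_methylated"` every C becomes T except a C immediately followed by
#' G. Crick: the same rules applied to the reverse complement of the input
#' (the returned sequence is the converted Crick strand 5'->3'). `N` bases
#' are preserved.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param strand `"watson"` or `"crick"`.
#' @param assumption `"cpg_methylated"` or `"unmethylated"`.
#' @return converted sequence (string).
#' @export
in_silico_convert <- function(seq,
                              strand = c("watson", "crick"),
                              assumption = c("cpg_methylated",
                                             "unmethylated")) {
  strand <- match.arg(strand)
  assumption <- match.arg(assumption)
  if (grepl("[^ACGTN]", seq <- toupper(seq)))
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  s <- if (strand == "crick") revcomp(seq) else seq
  if (assumption == "unmethylated") {
    gsub("C", "T", s, fixed = TRUE)
  } else {
    gsub("C(?!G)", "T", s, perl = TRUE)
  }
}

#' Design the five-probe set for one CpG
#'
#' Builds a 120-bp window centered on the CpG and derives the five capture
#' probes: (1) the original unconverted sequence, (2)/(3) the converted
#' CpG-methylated Watson and Crick strands, (4)/(5) the converted
#' unmethylated Watson and Crick strands. If the CpG sits closer than half a
#' probe length to a reference end the window is shifted to fit (messaged).
#'
#' @param cpg_pos 0-based position of the CpG's Watson-strand C.
#' @param ref single reference (string or one-reference `ref_index`).
#' @param probe_length probe length in bp (default 120).
#' @param id optional CpG id used to name the probes
#'   (`<id>_orig/_mW/_mC/_uW/_uC`).
#' @return named character vector of the 5 probes.
#' @export
design_probe_set <- function(cpg_pos, ref, probe_length = 120,
                             id = NULL) {
  ri <- one_ref(ref)
  if (ri$length < probe_length)
    stop("reference shorter than probe length", call. = FALSE)
  if (is.na(ri$watson[cpg_pos + 1L]) || ri$watson[cpg_pos + 1L] != "Z")
    stop("position is not a Watson-strand CpG cytosine", call. = FALSE)
  start <- cpg_pos - floor(probe_length / 2) + 1L   # center the CpG dinucleotide
  shifted <- FALSE
  if (start < 0L) { start <- 0L; shifted <- TRUE }
  if (start + probe_length > ri$length) {
    start <- ri$length - probe_length; shifted <- TRUE
  }
  if (shifted) message("probe window shifted to fit the reference")
  orig <- substr(ri$seq, start + 1L, start + probe_length)
  if (is.null(id)) id <- sprintf("cpg_%d", cpg_pos)
  setNames(
    c(orig,
      in_silico_convert(orig, "watson", "cpg_methylated"),
      in_silico_convert(orig, "crick", "cpg_methylated"),
      in_silico_convert(orig, "watson", "unmethylated"),
      in_silico_convert(orig, "crick", "unmethylated")),
    paste0(id, c("_orig", "_mW", "_mC", "_uW", "_uC")))
}

#' Design probe sets for many CpGs and optionally write a FASTA
#'
#' @param cpg_pos integer vector of 0-based Watson CpG positions.
#' @param ref single reference.
#' @param probe_length probe length (default 120).
#' @param ids optional ids, recycled against `cpg_pos`.
#' @param fasta optional output path; probes are written as a FASTA with 5
#'   records per CpG.
#' @return named character vector of all probes (5 per CpG), invisibly if
#'   `fasta` is written.
#' @export
design_probe_panel <- function(cpg_pos, ref, probe_length = 120,
                               ids = NULL, fasta = NULL) {
  if (is.null(ids)) ids <- sprintf("cpg_%d", cpg_pos)
  probes <- unlist(lapply(seq_along(cpg_pos), function(i)
    design_probe_set(cpg_pos[i], ref, probe_length, ids[i])))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(probes), fasta)
    return(invisible(probes))
  }
  probes
}
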