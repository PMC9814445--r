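## Per-read methylation-context calling, unconverted-CH counting, and the
## >=3-CH incomplete-conversion read filter.
##
## Call-string symbols follow the de-facto methylation-call-tag convention:
##   Z/z methylated/unmethylated CpG, X/x CHG, H/h CHH, '.' no cytosine on
##   the origin strand (or unresolvable context). Uppercase means the read
##   retains C at that position, i.e. the site was NOT converted.

#' Read-filtering configuration
#'
#' @param ch_threshold reads with at least this many unconverted CH sites are
#'   removed (default 3).
#' @param min_base_quality minimum base quality for a call; 0 disables
#'   quality masking (qualities are optional in this implementation).
#' @param paired_overlap policy for overlapping mates in quantification:
#'   `"first"` keeps the first mate's call at overlapping positions.
#' @return a `filter_config` list.
#' @export
filter_config <- function(ch_threshold = 3, min_base_quality = 0,
                          paired_overlap = c("first")) {
  check_count(ch_threshold, "ch_threshold", 1L)
  structure(list(ch_threshold = as.integer(ch_threshold),
                 min_base_quality = min_base_quality,
                 paired_overlap = match.arg(paired_overlap)),
            class = "filter_config")
}

CH_CATEGORIES <- c("0", "1", "2", "3+")

#' Call methylation contexts for one read
#'
#' For each reference cytosine on the read's origin strand under the aligned
#' span, emits one call symbol: CpG (`Z`/`z`), CHG (`X`/`x`) or CHH (`H`/`h`),
#' uppercase iff the read retains the cytosine (unconverted). Context is taken
#' from the reference (up to two bases downstream in origin-strand sense), so
#' read-terminal cytosines are classifiable; contexts running past the
#' reference end or through an `N` give `'.'`. Read bases other than C/T
#' (Watson sense) at a cytosine position — e.g. sequencing errors — also give
#' `'.'`.
#'
#' @param read list or one-row data.frame with `rname`, `start` (0-based),
#'   `seq`, `strand` (`"+"`/`"-"`).
#' @param ref references (`ref_index` or coercible).
#' @return single call string, same length as the read.
#' @export
call_read_contexts <- function(read, ref) {
  ri <- ref_index(ref)
  df <- as.data.frame(read[c("rname", "start", "seq", "strand")])
  df$end <- df$start + nchar(df$seq)
  add_call_strings(df, ri)$xm
}

#' Compute call strings for a read table
#'
#' Vectorised version of [call_read_contexts()]: adds (or replaces) the `xm`
#' column of a `converted_reads` table. Reads whose sequence length does not
#' match their alignment span are rejected (no indel support).
#'
#' @param reads `converted_reads` data.frame (`rname`, `start`, `end`,
#'   `strand`, `seq`).
#' @param refs references.
#' @param trust_xm if `TRUE` and an `xm` column is already present, it is
#'   kept untouched.
#' @return `reads` with an `xm` character column.
#' @export
add_call_strings <- function(reads, refs, trust_xm = FALSE) {
  if (trust_xm && !is.null(reads$xm) && !anyNA(reads$xm)) return(reads)
  ri <- ref_index(refs)
  n <- nrow(reads)
  xm <- character(n)
  if (n == 0L) { reads$xm <- xm; return(reads) }
  if (!all(reads$rname %in% names(ri)))
    stop("reads reference missing contig(s): ",
         paste(setdiff(unique(reads$rname), names(ri)), collapse = ", "),
         call. = FALSE)
  span <- reads$end - reads$start
  if (any(nchar(reads$seq) != span))
    stop("read sequence length differs from alignment span ",
         "(indels are not supported)", call. = FALSE)
  if (any(reads$start < 0))
    stop("negative alignment start", call. = FALSE)
  seq_chars <- strsplit(reads$seq, "", fixed = TRUE)
  for (i in seq_len(n)) {
    r <- ri[[reads$rname[i]]]
    if (reads$end[i] > r$length)
      stop(sprintf("read %d extends past end of reference '%s'",
                   i, reads$rname[i]), call. = FALSE)
    idx <- (reads$start[i] + 1L):reads$end[i]
    rb <- seq_chars[[i]]
    calls <- rep(".", length(rb))
    if (reads$strand[i] == "+") {
      ctx <- r$watson[idx]
      site <- which(!is.na(ctx))
      if (length(site)) {
        up <- rb[site] == "C"
        lo <- rb[site] == "T"
        calls[site[up]] <- ctx[site[up]]
        calls[site[lo]] <- tolower(ctx[site[lo]])
      }
    } else {
      ctx <- r$crick[idx]
      site <- which(!is.na(ctx))
      if (length(site)) {
        up <- rb[site] == "G"
        lo <- rb[site] == "A"
        calls[site[up]] <- ctx[site[up]]
        calls[site[lo]] <- tolower(ctx[site[lo]])
      }
    }
    xm[i] <- paste(calls, collapse = "")
  }
  reads$xm <- xm
  reads
}

#' Count unconverted CH sites in call strings
#'
#' The quantity the incomplete-conversion filter acts on: the number of
#' uppercase `X` (CHG) plus `H` (CHH) symbols, i.e. non-CpG cytosines that
#' failed to convert.
#'
#' @param calls character vector of call strings.
#' @return integer vector of counts.
#' @export
count_unconverted_ch <- function(calls) {
  nchar(gsub("[^XH]", "", calls))
}

#' Per-read CH profile
#'
#' @param reads `converted_reads` table; call strings are computed if absent.
#' @param refs references (needed only if `xm` is absent).
#' @param config a [filter_config()].
#' @return data.frame: `qname`, `n_unconverted_ch`, `n_converted_ch`,
#'   `n_cpg_meth`, `n_cpg_unmeth`, `category` (factor `0`/`1`/`2`/`3+`).
#' @export
read_ch_profile <- function(reads, refs = NULL, config = filter_config()) {
  if (is.null(reads$xm)) {
    if (is.null(refs)) stop("need 'refs' to compute call strings",
                            call. = FALSE)
    reads <- add_call_strings(reads, refs)
  }
  n_uch <- count_unconverted_ch(reads$xm)
  data.frame(
    qname = if (is.null(reads$qname)) as.character(seq_len(nrow(reads)))
            else reads$qname,
    n_unconverted_ch = n_uch,
    n_converted_ch = nchar(gsub("[^xh]", "", reads$xm)),
    n_cpg_meth = nchar(gsub("[^Z]", "", reads$xm)),
    n_cpg_unmeth = nchar(gsub("[^z]", "", reads$xm)),
    category = ch_category(n_uch, config$ch_threshold))
}

#' Categorise unconverted-CH counts
#'
#' @param n integer vector of unconverted-CH counts.
#' @param threshold counts at or above this collapse into the `"3+"`-style
#'   top category.
#' @return factor with levels `0`, `1`, `2`, `3+` (for the default
#'   threshold 3; in general `0 ... threshold-1, "threshold+"`).
#' @export
ch_category <- function(n, threshold = 3) {
  lev <- c(as.character(seq_len(threshold) - 1L), paste0(threshold, "+"))
  factor(ifelse(n >= threshold, paste0(threshold, "+"), as.character(n)),
         levels = lev)
}

#' Classify reads and decide removal
#'
#' A read is removed iff its unconverted-CH count is at or above
#' `config$ch_threshold` (the top category).
#'
#' @param profile output of [read_ch_profile()] (or any data.frame with an
#'   `n_unconverted_ch` column).
#' @param config a [filter_config()].
#' @return `profile` with `category` and logical `keep` columns.
#' @export
classify_read_ch <- function(profile, config = filter_config()) {
  profile$category <- ch_category(profile$n_unconverted_ch,
                                  config$ch_threshold)
  profile$keep <- profile$n_unconverted_ch < config$ch_threshold
  profile
}

#' Remove coordinate duplicates
#'
#' Among reads sharing (reference, start, end, origin strand) only the first
#' encountered is retained, mirroring standard alignment deduplication.
#'
#' @param reads `converted_reads` table.
#' @return list with `reads` (deduplicated, original class kept) and
#'   `n_removed`.
#' @export
dedup_reads <- function(reads) {
  key <- paste(reads$rname, reads$start, reads$end, reads$strand,
               sep = "\r")
  dup <- duplicated(key)
  out <- reads[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = sum(dup))
}

#' Filter incompletely converted reads
#'
#' Partitions a read set into kept and removed reads by the unconverted-CH
#' threshold. The partition is exhaustive and disjoint and kept reads' call
#' strings are untouched (pure selection).
#'
#' @param reads `converted_reads` table.
#' @param refs references (used if call strings are absent).
#' @param config a [filter_config()].
#' @return list: `kept`, `removed` (both with `xm` and profile columns) and
#'   `summary` (category counts, `n_total`, `removal_fraction`).
#' @export
filter_reads <- function(reads, refs = NULL, config = filter_config()) {
  if (is.null(reads$xm)) reads <- add_call_strings(reads, refs)
  n_uch <- count_unconverted_ch(reads$xm)
  reads$n_unconverted_ch <- n_uch
  reads$category <- ch_category(n_uch, config$ch_threshold)
  keep <- n_uch < config$ch_threshold
  counts <- table(reads$category)
  summary <- list(
    category_counts = as.integer(counts),
    categories = names(counts),
    n_total = nrow(reads),
    n_removed = sum(!keep),
    removal_fraction = if (nrow(reads)) sum(!keep) / nrow(reads) else 0)
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE],
       summary = summary)
}

#' Category proportions and the share of heavily unconverted reads
#'
#' Reports the proportion of reads in each unconverted-CH category among all
#' reads, and the share of top-category reads among CH-containing reads
#' (reads with at least one unconverted CH) — the headline statistic used to
#' compare conversion chemistries.
#'
#' @param reads `converted_reads` table (call strings computed if absent).
#' @param refs references.
#' @param config a [filter_config()].
#' @return list: `proportions` (named, sums to 1), `n_reads`,
#'   `share_top_among_ch` = n(top category) / n(>=1 unconverted CH).
#' @export
ch_read_report <- function(reads, refs = NULL, config = filter_config()) {
  if (nrow(reads) == 0L) stop("no reads", call. = FALSE)
  if (is.null(reads$xm)) reads <- add_call_strings(reads, refs)
  n_uch <- count_unconverted_ch(reads$xm)
  cat <- ch_category(n_uch, config$ch_threshold)
  counts <- table(cat)
  n_ch_reads <- sum(n_uch >= 1)
  top <- paste0(config$ch_threshold, "+")
  if (n_ch_reads == 0L) {
    warning("no CH-containing reads; share defined as 0")
    share <- 0
  } else {
    share <- unname(counts[top]) / n_ch_reads
  }
  list(proportions = counts / nrow(reads), n_reads = nrow(reads),
       n_ch_reads = n_ch_reads, share_top_among_ch = share)
}
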