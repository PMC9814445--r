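## Aggregation of per-read calls into per-cytosine methylation levels,
## control-site classification, conversion-efficiency estimation, and
## incomplete-conversion hotspot detection.

#' Control-site classification thresholds
#'
#' @param hypo sites with beta strictly below this are "hypomethylated"
#'   (default 0.01, i.e. < 1 percent).
#' @param hyper sites with beta strictly above this are "hypermethylated"
#'   (default 0.80).
#' @return a `site_class_config` list.
#' @export
site_class_config <- function(hypo = 0.01, hyper = 0.80) {
  if (!(hypo > 0 && hypo < hyper && hyper < 1))
    stop("need 0 < hypo < hyper < 1", call. = FALSE)
  structure(list(hypo = hypo, hyper = hyper), class = "site_class_config")
}

#' Aggregate read calls into per-cytosine methylation records
#'
#' Tallies uppercase (methylated / unconverted) and lowercase (unmethylated /
#' converted) calls per reference cytosine, separately per strand, and
#' computes beta = meth / (meth + unmeth). Zero-coverage sites are omitted.
#' Deduplication and filtering are expected to have been applied already.
#'
#' @param reads `converted_reads` table with `xm` call strings (computed via
#'   [add_call_strings()] if absent and `refs` given).
#' @param refs references (only needed to compute missing call strings).
#' @param merge_strands if `TRUE`, Watson and Crick counts of one CpG are
#'   summed onto the Watson C position (Crick CpG position minus 1). CH
#'   records are never merged.
#' @return list with data.frames `cpg` and `ch`, each with columns `rname`,
#'   `pos` (0-based, strand-resolved C position), `strand`, `context`
#'   (`CpG`/`CHG`/`CHH`), `meth`, `unmeth`, `beta`.
#' @export
aggregate_cpg <- function(reads, refs = NULL, merge_strands = FALSE) {
  if (is.null(reads$xm)) reads <- add_call_strings(reads, refs)
  empty <- data.frame(rname = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth = integer(), unmeth = integer(), beta = numeric())
  if (nrow(reads) == 0L) return(list(cpg = empty, ch = empty))
  chars <- strsplit(reads$xm, "", fixed = TRUE)
  lens <- lengths(chars)
  sym <- unlist(chars, use.names = FALSE)
  pos <- unlist(lapply(seq_along(chars),
                       function(i) reads$start[i] + seq_len(lens[i]) - 1L),
                use.names = FALSE)
  keep <- sym != "."
  dt <- data.table(
    rname = rep(reads$rname, lens)[keep],
    pos = pos[keep],
    strand = rep(reads$strand, lens)[keep],
    sym = sym[keep])
  dt[, `:=`(meth = sym %in% c("Z", "X", "H"),
            context = c(Z = "CpG", z = "CpG", X = "CHG", x = "CHG",
                        H = "CHH", h = "CHH")[sym])]
  agg <- dt[, .(meth = sum(meth), unmeth = sum(!meth)),
            by = .(rname, pos, strand, context)]
  if (merge_strands) {
    cpg <- agg[context == "CpG"]
    cpg[strand == "-", pos := pos - 1L]
    cpg <- cpg[, .(meth = sum(meth), unmeth = sum(unmeth)),
               by = .(rname, pos)]
    cpg[, `:=`(strand = "*", context = "CpG")]
    agg <- rbind(cpg[, .(rname, pos, strand, context, meth, unmeth)],
                 agg[context != "CpG"])
  }
  agg[, beta := meth / (meth + unmeth)]
  setorder(agg, rname, pos, strand)
  cpg <- as.data.frame(agg[context == "CpG"])
  ch <- as.data.frame(agg[context != "CpG"])
  list(cpg = cpg, ch = ch)
}

#' Classify sites as hypo-, hyper- or intermediately methylated
#'
#' Strict inequalities on both ends: hypo iff beta < `hypo`, hyper iff beta >
#' `hyper`; a beta exactly at a threshold is "intermediate".
#'
#' @param records methylation record data.frame with a `beta` column.
#' @param config a [site_class_config()].
#' @return `records` with a `class` factor column
#'   (`hypo`/`intermediate`/`hyper`).
#' @export
classify_sites <- function(records, config = site_class_config()) {
  if (anyNA(records$beta))
    stop("beta undefined (zero coverage) for some records", call. = FALSE)
  records$class <- factor(
    ifelse(records$beta < config$hypo, "hypo",
           ifelse(records$beta > config$hyper, "hyper", "intermediate")),
    levels = c("hypo", "intermediate", "hyper"))
  records
}

#' Estimate conversion efficiency from an unmethylated control
#'
#' All cytosines of the control are truth-unmethylated, so every uppercase
#' (unconverted) call is a conversion failure: efficiency = 1 - sum(meth) /
#' sum(meth + unmeth), pooled over all contexts passed in. The confidence
#' interval is the normal approximation to the binomial.
#'
#' @param records methylation records from the unmethylated control (CpG and
#'   CH records may be row-bound to pool all cytosines).
#' @param conf confidence level (default 0.95).
#' @return list: `efficiency`, `ci` (length-2, clipped to [0,1]),
#'   `n_calls`, `n_unconverted`.
#' @export
conversion_efficiency <- function(records, conf = 0.95) {
  n <- sum(records$meth) + sum(records$unmeth)
  if (n == 0) stop("no calls; cannot estimate conversion efficiency",
                   call. = FALSE)
  fail <- sum(records$meth)
  eff <- 1 - fail / n
  z <- qnorm(1 - (1 - conf) / 2)
  hw <- z * sqrt(eff * (1 - eff) / n)
  list(efficiency = eff,
       ci = c(max(0, eff - hw), min(1, eff + hw)),
       n_calls = n, n_unconverted = fail)
}

#' Detect incomplete-conversion hotspots
#'
#' On an unmethylated control, a CpG showing apparent methylation above
#' `signal_thresh` that is accompanied by at least one CH site with beta
#' above the same threshold within `window` bp is flagged as an
#' incomplete-conversion hotspot (sequence-context-driven conversion
#' failure), rather than genuine methylation.
#'
#' @param cpg_records,ch_records record data.frames (same layout as
#'   [aggregate_cpg()] output).
#' @param signal_thresh beta threshold (strict >) for both the CpG and its
#'   supporting CH sites; default 0.01.
#' @param window maximum CpG-to-CH distance in bp (default 50).
#' @return data.frame sorted by CpG beta descending: `rname`, `pos`, `beta`,
#'   `n_support`, `support_pos` (comma-separated CH positions), `window`.
#' @export
detect_incomplete_conversion_hotspots <- function(cpg_records, ch_records,
                                                  signal_thresh = 0.01,
                                                  window = 50) {
  empty <- data.frame(rname = character(), pos = integer(), beta = numeric(),
                      n_support = integer(), support_pos = character(),
                      window = numeric())
  cand <- cpg_records[!is.na(cpg_records$beta) &
                        cpg_records$beta > signal_thresh, , drop = FALSE]
  chs <- ch_records[!is.na(ch_records$beta) &
                      ch_records$beta > signal_thresh, , drop = FALSE]
  if (nrow(cand) == 0L || nrow(chs) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    sup <- chs[chs$rname == cand$rname[i] &
                 abs(chs$pos - cand$pos[i]) <= window, , drop = FALSE]
    if (nrow(sup) == 0L) return(NULL)
    data.frame(rname = cand$rname[i], pos = cand$pos[i],
               beta = cand$beta[i], n_support = nrow(sup),
               support_pos = paste(sort(sup$pos), collapse = ","),
               window = window)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$beta, out$rname, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare methylation before and after read filtering
#'
#' Joins two record sets on (reference, position, strand), restricts to sites
#' present in both, and summarises the filtering effect per site class with a
#' paired Student's t test. With identical inputs the t statistic is
#' undefined and flagged `NA`.
#'
#' @param before,after record data.frames (e.g. [aggregate_cpg()] `$cpg`
#'   before and after [filter_reads()]).
#' @param classes data.frame assigning a `class` to sites: columns `rname`,
#'   `pos`, `strand`, `class` (e.g. from [classify_sites()] on a reference
#'   measurement).
#' @return data.frame per class: `class`, `n_sites`, `mean_before`,
#'   `mean_after`, `mean_delta` (after - before), `t`, `p`.
#' @export
compare_filtering_effect <- function(before, after, classes) {
  key <- function(d) paste(d$rname, d$pos, d$strand, sep = "\r")
  m <- merge(
    data.frame(k = key(before), beta_before = before$beta),
    data.frame(k = key(after), beta_after = after$beta), by = "k")
  if (nrow(m) == 0L)
    stop("'before' and 'after' share no sites", call. = FALSE)
  m <- merge(m, data.frame(k = key(classes), class = classes$class),
             by = "k")
  if (nrow(m) == 0L)
    stop("no classified sites among the shared sites", call. = FALSE)
  out <- lapply(split(m, m$class, drop = FALSE), function(d) {
    if (nrow(d) == 0L) return(NULL)
    delta <- d$beta_after - d$beta_before
    tt <- if (nrow(d) >= 2 && sd(delta) > 0) {
      ht <- t.test(d$beta_after, d$beta_before, paired = TRUE)
      c(ht$statistic, ht$p.value)
    } else c(NA_real_, NA_real_)
    data.frame(class = d$class[1], n_sites = nrow(d),
               mean_before = mean(d$beta_before),
               mean_after = mean(d$beta_after),
               mean_delta = mean(delta), t = tt[1], p = tt[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
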