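## Confusion-matrix metrics, ROC/AUC with DeLong confidence intervals, the
## normal-approximation proportion CI, subgroup positive-rate reports, group
## tests and fragment-length profiling.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v))
      stop("counts must be single non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). Percent
#' display values are rounded half up to the integer (the convention of
#' published clinical tables). A zero denominator yields `NA` with an
#' explicit `undefined` marker, never 0.
#'
#' @param counts a [confusion_counts()] (or the four counts as arguments
#'   via `...` passed to `confusion_counts`).
#' @return list: `sensitivity`, `specificity` (proportions, `NA` when
#'   undefined), `sensitivity_pct`, `specificity_pct` (integer percent),
#'   `undefined` (character vector naming undefined metrics).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  undef <- character()
  sens <- if (counts$tp + counts$fn == 0) {
    undef <- c(undef, "sensitivity"); NA_real_
  } else counts$tp / (counts$tp + counts$fn)
  spec <- if (counts$tn + counts$fp == 0) {
    undef <- c(undef, "specificity"); NA_real_
  } else counts$tn / (counts$tn + counts$fp)
  list(sensitivity = sens, specificity = spec,
       sensitivity_pct = if (is.na(sens)) NA_real_ else
         round_half_up(100 * sens),
       specificity_pct = if (is.na(spec)) NA_real_ else
         round_half_up(100 * spec),
       undefined = undef)
}

#' Normal-approximation confidence interval for a proportion
#'
#' p +/- 1.96 * sqrt(p (1 - p) / n) at the default 95 percent level,
#' clipped to [0, 1].
#'
#' @param p observed proportion in [0, 1].
#' @param n sample size (>= 1).
#' @param conf confidence level.
#' @return numeric length-2 vector (lower, upper).
#' @export
proportion_ci <- function(p, n, conf = 0.95) {
  check_prob(p, "p")
  check_count(n, "n", 1L)
  z <- qnorm(1 - (1 - conf) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - hw), upper = min(1, p + hw))
}

## Rank AUC (Mann-Whitney with tie correction). labels TRUE/1 = positive.
auc_rank <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)            # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with DeLong 95 percent confidence interval
#'
#' AUC is the Mann-Whitney rank statistic (ties at half weight); the CI uses
#' DeLong's placement-based variance with a normal approximation, clipped to
#' [0, 1].
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (positive = 1/TRUE/second factor level).
#' @param conf confidence level.
#' @return list: `auc`, `ci` (length 2), `var`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  y <- as_binary(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  auc <- auc_rank(scores, y)
  ## DeLong placements
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / m,
                numeric(1))
  s <- (if (m > 1) var(v10) / m else 0) + (if (n > 1) var(v01) / n else 0)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * sqrt(s)), min(1, auc + z * sqrt(s)))
  list(auc = auc, ci = ci, var = s, n_pos = m, n_neg = n)
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold (predict positive iff score >=
#' threshold) and returns sensitivity/specificity at each operating point,
#' plus the endpoints.
#'
#' @param scores,labels as in [roc_auc()].
#' @return data.frame: `threshold`, `sensitivity`, `specificity`, ordered by
#'   decreasing threshold.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & y == 1) / sum(y == 1),
               specificity = sum(!pred & y == 0) / sum(y == 0))
  })
  do.call(rbind, out)
}

#' Positive rates per subgroup
#'
#' @param positive logical vector of positive predictions.
#' @param subgroup vector assigning each sample to a subgroup (a partition).
#' @return data.frame per subgroup: `subgroup`, `k` (positives), `n`,
#'   `percent` (100 k/n rounded to 2 decimals; `NA` for empty subgroups).
#' @export
subgroup_positive_rates <- function(positive, subgroup) {
  stopifnot(length(positive) == length(subgroup))
  sg <- if (is.factor(subgroup)) subgroup else factor(subgroup)
  out <- lapply(levels(sg), function(l) {
    sel <- sg == l & !is.na(sg)
    n <- sum(sel); k <- sum(positive[sel])
    data.frame(subgroup = l, k = k, n = n,
               percent = if (n == 0) NA_real_ else
                 round_half_up(100 * k / n, 2))
  })
  do.call(rbind, out)
}

#' Two-sample Student's t test
#'
#' Equal-variance two-sided t test (the classical form), wrapped so that a
#' zero pooled variance is an explicit error rather than NaN.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list: `t`, `p`, `df`, `mean_diff`.
#' @export
group_difference_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (var(a) == 0 && var(b) == 0)
    stop("zero pooled variance", call. = FALSE)
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(a) - mean(b))
}

#' Fragment length profile
#'
#' Histogram at 1-bp bins, the modal length, and the spacing of the
#' sub-modal periodic peaks (the cfDNA 10-bp ladder) estimated from the
#' autocorrelation of the detrended histogram below the mode. The mode is
#' the argmax of a 5-bp moving average of the histogram (robust against
#' single-bin counting noise around a broad peak); the raw histogram is
#' returned alongside.
#'
#' @param lengths integer vector of fragment lengths (>= 1 value).
#' @return list: `histogram` (data.frame `length`, `count`), `mode`,
#'   `peak_spacing` (`NA` when the sub-modal region is too short).
#' @export
fragment_length_profile <- function(lengths) {
  if (length(lengths) == 0) stop("no fragment lengths", call. = FALSE)
  lengths <- as.integer(lengths)
  rng <- range(lengths)
  bins <- rng[1]:rng[2]
  counts <- tabulate(lengths - rng[1] + 1L, nbins = length(bins))
  padded <- c(0, 0, counts, 0, 0)
  smooth <- vapply(seq_along(counts),
                   function(i) mean(padded[i:(i + 4L)]), numeric(1))
  mode <- bins[which.max(smooth)]
  ## periodicity: detrend the sub-modal histogram with a moving average
  ## wider than one ladder period, then take the autocorrelation peak among
  ## plausible nucleosomal spacings (5-15 bp)
  sub <- counts[bins < mode - 2]
  spacing <- NA_real_
  if (length(sub) >= 25) {
    ma <- stats::filter(sub, rep(1 / 11, 11), sides = 2)
    det <- sub - ma
    det[is.na(det)] <- 0
    ac <- acf(as.numeric(det), lag.max = min(15, length(sub) - 1),
              plot = FALSE)$acf[-1]
    if (length(ac) >= 15) spacing <- which.max(ac[5:15]) + 4
  }
  list(histogram = data.frame(length = bins, count = counts),
       mode = mode, peak_spacing = spacing)
}
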