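## Simulation of post-conversion reads from control and cfDNA-like molecules.
##
## The failure model has two modes, mirroring what enzymatic conversion data
## shows: sporadic single-site failures in otherwise normal molecules (rate
## 1 - eff per site) and molecule-level "conversion-compromised" events (a
## molecule is drawn compromised with probability rho_fail, and every
## unmethylated C in it then converts only with probability eff_fail),
## which produce clustered unconverted CH sites within single reads.

#' Methylome specification for a reference
#'
#' Maps every cytosine position of a reference (both strands) to a
#' methylation probability. Convenience constructors cover the two control
#' truth states: fully unmethylated (lambda-like) and CpG-methylated
#' (pUC19-like, probability 1 at CpG cytosines on both strands, 0 at CH
#' cytosines).
#'
#' @param ref single reference sequence (string) or a one-reference
#'   `ref_index`.
#' @param watson,crick optional named numeric vectors mapping 0-based
#'   positions to methylation probabilities; positions must be cytosines on
#'   the stated strand. Unlisted cytosines get probability 0.
#' @return a `methylome_spec`: list with full-length probability vectors
#'   `watson` and `crick` (NA where the base is not a C on that strand).
#' @export
methylome_spec <- function(ref, watson = NULL, crick = NULL) {
  ri <- one_ref(ref)
  wp <- rep(NA_real_, ri$length); wp[ri$bases == "C"] <- 0
  cp <- rep(NA_real_, ri$length); cp[ri$bases == "G"] <- 0
  fill <- function(base_vec, probs, strand) {
    if (is.null(probs)) return(base_vec)
    pos <- as.integer(names(probs)) + 1L  # 0-based -> 1-based
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > ri$length))
      stop("methylome positions out of reference bounds", call. = FALSE)
    if (any(is.na(base_vec[pos])))
      stop(sprintf("some positions are not cytosines on the %s strand",
                   strand), call. = FALSE)
    if (any(probs < 0 | probs > 1))
      stop("methylation probabilities must lie in [0, 1]", call. = FALSE)
    base_vec[pos] <- unname(probs)
    base_vec
  }
  structure(list(watson = fill(wp, watson, "Watson"),
                 crick = fill(cp, crick, "Crick"),
                 length = ri$length),
            class = "methylome_spec")
}

#' @rdname methylome_spec
#' @export
methylome_unmethylated <- function(ref) methylome_spec(ref)

#' @rdname methylome_spec
#' @export
methylome_cpg_methylated <- function(ref) {
  ri <- one_ref(ref)
  m <- methylome_spec(ref)
  m$watson[which(ri$watson == "Z")] <- 1
  m$crick[which(ri$crick == "Z")] <- 1
  m
}

one_ref <- function(ref) {
  if (inherits(ref, "ref_index")) {
    if (length(ref) != 1L)
      stop("expected a single reference", call. = FALSE)
    return(ref[[1]])
  }
  ref_index(ref)[[1]]
}

#' Conversion failure parameters
#'
#' @param eff per-site conversion probability for an unmethylated C in a
#'   normal molecule.
#' @param rho_fail probability that a molecule is conversion-compromised.
#' @param eff_fail per-site conversion probability within a compromised
#'   molecule; must not exceed `eff`.
#' @param err per-base sequencing error rate (uniform substitution).
#' @param seed integer seed used by simulators consuming these parameters.
#' @return a `conversion_params` list.
#' @export
conversion_params <- function(eff = 0.998, rho_fail = 0.01, eff_fail = 0.5,
                              err = 0.001, seed = NULL) {
  check_prob(eff, "eff"); check_prob(rho_fail, "rho_fail")
  check_prob(eff_fail, "eff_fail"); check_prob(err, "err")
  if (eff_fail > eff)
    stop("'eff_fail' must be <= 'eff'", call. = FALSE)
  structure(list(eff = eff, rho_fail = rho_fail, eff_fail = eff_fail,
                 err = err, seed = seed), class = "conversion_params")
}

#' Fragment length and position model
#'
#' Fragment lengths follow a mixture of a modal Gaussian (cfDNA mononucleosome
#' peak, default mean 167 bp, sd 10) and optional narrow sub-peaks spaced
#' 10 bp below the mode (the nucleosomal ladder). Lengths are truncated to
#' `[min_length, max_length]`; start positions are uniform over the
#' reference; strand is Bernoulli(`p_watson`).
#'
#' @param n_fragments number of fragments to draw.
#' @param mean_length,sd_length modal Gaussian parameters (bp).
#' @param periodic_weights mixture weights of the sub-peaks at
#'   `mean_length - periodic_spacing * k`, k = 1, 2, ...; `NULL` disables
#'   them. The main peak gets the remaining weight.
#' @param periodic_spacing,periodic_sd sub-peak spacing and width (bp).
#' @param min_length,max_length hard truncation bounds (bp).
#' @param p_watson probability a fragment originates from the Watson strand.
#' @param seed integer seed.
#' @return a `fragment_params` list.
#' @export
fragment_params <- function(n_fragments, mean_length = 167, sd_length = 10,
                            periodic_weights = c(0.035, 0.02, 0.01),
                            periodic_spacing = 10, periodic_sd = 2,
                            min_length = 70, max_length = 300,
                            p_watson = 0.5, seed = NULL) {
  check_count(n_fragments, "n_fragments", 0L)
  check_prob(p_watson, "p_watson")
  if (min_length > max_length)
    stop("'min_length' must be <= 'max_length'", call. = FALSE)
  if (!is.null(periodic_weights) && sum(periodic_weights) >= 1)
    stop("'periodic_weights' must sum to < 1", call. = FALSE)
  structure(list(n_fragments = as.integer(n_fragments),
                 mean_length = mean_length, sd_length = sd_length,
                 periodic_weights = periodic_weights,
                 periodic_spacing = periodic_spacing,
                 periodic_sd = periodic_sd,
                 min_length = min_length, max_length = max_length,
                 p_watson = p_watson, seed = seed),
            class = "fragment_params")
}

#' Simulate cfDNA-like fragments from one reference
#'
#' @param ref single reference sequence (string, one-entry named vector, or
#'   one-reference `ref_index`).
#' @param params a [fragment_params()] object.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"` Watson / `"-"` Crick) and `length`.
#' @export
simulate_fragments <- function(ref, params) {
  stopifnot(inherits(params, "fragment_params"))
  ri <- one_ref(ref)
  if (ri$length < params$min_length)
    stop(sprintf("reference (%d bp) shorter than minimum fragment length %d",
                 ri$length, params$min_length), call. = FALSE)
  n <- params$n_fragments
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer()))
  }
  with_seed(params$seed, {
    w_sub <- params$periodic_weights
    if (is.null(w_sub)) w_sub <- numeric()
    means <- c(params$mean_length,
               params$mean_length - params$periodic_spacing *
                 seq_along(w_sub))
    sds <- c(params$sd_length, rep(params$periodic_sd, length(w_sub)))
    wts <- c(1 - sum(w_sub), w_sub)
    comp <- sample.int(length(wts), n, replace = TRUE, prob = wts)
    len <- as.integer(round(rnorm(n, means[comp], sds[comp])))
    len <- pmin(pmax(len, params$min_length), params$max_length)
    len <- pmin(len, ri$length)
    start <- as.integer(floor(runif(n) * (ri$length - len + 1)))
    strand <- ifelse(runif(n) < params$p_watson, "+", "-")
    data.frame(start = start, end = start + len, strand = strand,
               length = len)
  })
}

## Core conversion engine, vectorised over fragments of one reference.
## Uses the current RNG state; callers fix the seed.
convert_fragments_engine <- function(ri, meth, frags, params) {
  n <- nrow(frags)
  reads <- character(n)
  compromised <- runif(n) < params$rho_fail
  bases <- ri$bases
  for (i in seq_len(n)) {
    span <- (frags$start[i] + 1L):frags$end[i]
    b <- bases[span]
    if (frags$strand[i] == "+") {
      cidx <- which(b == "C")
      probs <- meth$watson[span[cidx]]
      to <- "T"
    } else {
      cidx <- which(b == "G")
      probs <- meth$crick[span[cidx]]
      to <- "A"
    }
    if (length(cidx)) {
      probs[is.na(probs)] <- 0
      is_meth <- runif(length(cidx)) < probs
      p_conv <- if (compromised[i]) params$eff_fail else params$eff
      converts <- !is_meth & (runif(length(cidx)) < p_conv)
      b[cidx[converts]] <- to
    }
    if (params$err > 0) {
      sub <- which(runif(length(b)) < params$err & b != "N")
      if (length(sub)) {
        for (j in sub) {
          b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1L)
        }
      }
    }
    reads[i] <- paste(b, collapse = "")
  }
  list(seq = reads, compromised = compromised)
}

#' Convert a single molecule
#'
#' Applies the conversion model to one fragment: methylation states are drawn
#' per cytosine from the methylome, the molecule is drawn compromised with
#' probability `rho_fail`, every unmethylated C on the origin strand converts
#' (C to T; seen as G to A in forward coordinates for Crick molecules) with
#' probability `eff` (normal) or `eff_fail` (compromised), and uniform
#' sequencing errors are applied last at rate `err`. Methylated cytosines are
#' never converted; `N` bases are untouched. Uses the current RNG state; set
#' a seed beforehand for reproducibility.
#'
#' @param ref single reference (string or one-reference `ref_index`).
#' @param start 0-based fragment start on the reference.
#' @param end 0-based exclusive fragment end.
#' @param strand `"+"` (Watson) or `"-"` (Crick origin).
#' @param methylome a [methylome_spec()].
#' @param params a [conversion_params()].
#' @return list with `seq` (read in forward-reference orientation),
#'   `compromised` flag, `start`, `end`, `strand`.
#' @export
convert_molecule <- function(ref, start, end, strand, methylome, params) {
  stopifnot(inherits(methylome, "methylome_spec"),
            inherits(params, "conversion_params"))
  ri <- one_ref(ref)
  if (start < 0 || end > ri$length || start >= end)
    stop("fragment out of reference bounds", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'",
                                     call. = FALSE)
  frags <- data.frame(start = as.integer(start), end = as.integer(end),
                      strand = strand)
  out <- convert_fragments_engine(ri, methylome, frags, params)
  list(seq = out$seq, compromised = out$compromised[1],
       start = as.integer(start), end = as.integer(end), strand = strand)
}

#' Simulate a full control sequencing run
#'
#' Draws fragments from each control reference, converts them under the
#' failure model, and returns the mixed read set with per-read truth
#' (origin reference, compromised flag). The typical use is a two-reference
#' run: an unmethylated lambda-like control and a CpG-methylated pUC19-like
#' control (see [synthetic_control_refs()]).
#'
#' @param refs references (`ref_index`, `DNAStringSet` or named character
#'   vector); usually the two controls.
#' @param methylomes named list of [methylome_spec()] objects, one per
#'   reference in `refs`.
#' @param frag_params a single [fragment_params()] applied to every
#'   reference, or a named list with one per reference.
#' @param conv_params a [conversion_params()].
#' @param seed single top-level seed governing all randomness (fragment
#'   sampling and conversion); overrides seeds inside the parameter objects.
#' @return a `converted_reads` data.frame: `qname`, `rname`, `start`, `end`,
#'   `strand`, `mate`, `seq`, `compromised`.
#' @export
simulate_control_run <- function(refs, methylomes, frag_params, conv_params,
                                 seed = 1) {
  ri <- ref_index(refs)
  if (!all(names(ri) %in% names(methylomes)))
    stop("every reference needs a methylome_spec in 'methylomes'",
         call. = FALSE)
  if (inherits(frag_params, "fragment_params")) {
    frag_params <- setNames(rep(list(frag_params), length(ri)), names(ri))
  }
  pieces <- vector("list", length(ri))
  for (k in seq_along(ri)) {
    nm <- names(ri)[k]
    fp <- frag_params[[nm]]
    fp$seed <- derive_seed(seed, 2L * k - 1L)
    frags <- simulate_fragments(ri[nm], fp)
    if (nrow(frags) == 0L) {
      pieces[[k]] <- data.frame(qname = character(), rname = character(),
                                start = integer(), end = integer(),
                                strand = character(), mate = character(),
                                seq = character(), compromised = logical())
      next
    }
    conv <- with_seed(derive_seed(seed, 2L * k), {
      convert_fragments_engine(ri[[nm]], methylomes[[nm]], frags,
                               conv_params)
    })
    pieces[[k]] <- data.frame(
      qname = sprintf("%s_read%06d", nm, seq_len(nrow(frags))),
      rname = nm, start = frags$start, end = frags$end,
      strand = frags$strand, mate = "single",
      seq = conv$seq, compromised = conv$compromised)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("zero reads requested; empty read set")
  class(out) <- c("converted_reads", "data.frame")
  out
}

#' Probability that a read is removed by the CH filter, in closed form
#'
#' For a read whose fragment covers `n_ch` origin-strand CH cytosines, all
#' truth-unmethylated, the number of unconverted CH sites is a mixture of two
#' binomials: Binom(n_ch, 1 - eff_fail) with probability `rho_fail`
#' (compromised molecule) and Binom(n_ch, 1 - eff) otherwise. Returns the
#' mixture probability of at least `threshold` unconverted CH sites,
#' vectorised over `n_ch`. Sequencing error is not modelled (use err = 0 when
#' comparing simulations against this).
#'
#' @param n_ch integer vector of per-read CH-site counts.
#' @param params a [conversion_params()].
#' @param threshold removal threshold (default 3).
#' @return numeric vector of removal probabilities.
#' @export
ch_removal_probability <- function(n_ch, params, threshold = 3) {
  p_norm <- pbinom(threshold - 1, n_ch, 1 - params$eff, lower.tail = FALSE)
  p_fail <- pbinom(threshold - 1, n_ch, 1 - params$eff_fail,
                   lower.tail = FALSE)
  params$rho_fail * p_fail + (1 - params$rho_fail) * p_norm
}
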