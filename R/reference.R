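#' Pre-compute cytosine context classes for a set of references
#'
#' For every cytosine on either strand of each reference, the dinucleotide /
#' trinucleotide context class is resolved once: `Z` (CpG), `X` (CHG) or `H`
#' (CHH), with `NA` where the context is unresolvable (runs past the reference
#' end or contains an `N`). All read-level context calling and all simulators
#' index into this structure, so it is built once per reference set.
#'
#' @param refs a `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or an existing `ref_index` (returned unchanged).
#' @return a `ref_index` object: per reference a list with `seq` (string),
#'   `bases` (character vector), `watson` and `crick` (context class per
#'   position; `watson[i]` is non-NA iff base i is C, `crick[i]` iff base i is
#'   G, i.e. a C on the reverse strand).
#' @export
ref_index <- function(refs) {
  if (inherits(refs, "ref_index")) return(refs)
  seqs <- as_ref_strings(refs)
  out <- lapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(b)
    nxt1 <- c(b[-1], NA)              # base at i+1
    nxt2 <- c(b[-(1:2)], NA, NA)      # base at i+2
    prv1 <- c(NA, b[-L])              # base at i-1
    prv2 <- c(NA, NA, b[seq_len(max(L - 2L, 0L))])

    watson <- rep(NA_character_, L)
    isC <- b == "C"
    watson[isC & nxt1 == "G"] <- "Z"
    hs <- isC & nxt1 %in% c("A", "C", "T")
    watson[hs & nxt2 == "G"] <- "X"
    watson[hs & nxt2 %in% c("A", "C", "T")] <- "H"

    ## Crick-strand C = G on the forward sequence; its downstream context is
    ## upstream on forward coordinates, read in complement sense.
    crick <- rep(NA_character_, L)
    isG <- b == "G"
    crick[isG & prv1 == "C"] <- "Z"
    gs <- isG & prv1 %in% c("A", "G", "T")
    crick[gs & prv2 == "C"] <- "X"
    crick[gs & prv2 %in% c("A", "G", "T")] <- "H"

    list(seq = s, bases = b, length = L, watson = watson, crick = crick)
  })
  structure(out, class = "ref_index")
}

#' @export
`[.ref_index` <- function(x, i) {
  structure(unclass(x)[i], class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("ref_index of", length(x), "reference(s):\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d bp, %d Watson C, %d Crick C\n", nm, x[[nm]]$length,
                sum(!is.na(x[[nm]]$watson)), sum(!is.na(x[[nm]]$crick))))
  }
  invisible(x)
}

#' Generate synthetic spike-in control references
#'
#' Builds a pair of random references standing in for the classic conversion
#' controls: an unmethylated phage-lambda-like sequence and a CpG-methylated
#' pUC19-like plasmid sequence. Sequences are uniform random ACGT at the given
#' GC content; they are synthetic stand-ins, not the real genomes.
#'
#' @param lambda_length,puc_length reference lengths in bp (defaults 20000 and
#'   2686, the true pUC19 size).
#' @param gc GC fraction.
#' @param seed integer seed; same seed, same references.
#' @return named character vector with elements `lambda_synth`, `puc19_synth`.
#' @export
synthetic_control_refs <- function(lambda_length = 20000, puc_length = 2686,
                                   gc = 0.5, seed = 1) {
  check_prob(gc, "gc")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draw <- function(n) paste(sample(names(p), n, replace = TRUE, prob = p),
                              collapse = "")
    c(lambda_synth = draw(lambda_length), puc19_synth = draw(puc_length))
  })
}
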