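## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical tables almost
#' universally round half up (e.g. 88.9 -> 89). Used for percent display only,
#' never for computation.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 88.89), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## Probability in [0,1] check with informative error.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

## Coerce reference input (DNAStringSet, named character vector, or a single
## string) to a named character vector of uppercase sequences.
as_ref_strings <- function(refs) {
  if (inherits(refs, "ref_index")) {
    return(vapply(refs, function(r) r$seq, character(1)))
  }
  if (inherits(refs, "DNAStringSet")) {
    out <- as.character(refs)
    if (is.null(names(out))) names(out) <- paste0("ref", seq_along(out))
    return(toupper(out))
  }
  if (is.character(refs)) {
    out <- toupper(refs)
    if (is.null(names(out))) {
      names(out) <- if (length(out) == 1L) "ref1" else
        paste0("ref", seq_along(out))
    }
    return(out)
  }
  stop("references must be a DNAStringSet or a named character vector",
       call. = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Deterministic child seeds derived from one top-level seed, kept < 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}
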