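## Readers and writers: FASTA, SAM (+ BAM via Rsamtools), bedGraph,
## per-cytosine report, TSV sample sheets / matrices, JSON pipeline config
## and model bundles. All emissions are deterministic given their inputs
## (stable coordinate ordering).

#' Read references from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write references to FASTA
#'
#' @param refs named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_reference_fasta <- function(refs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(as_ref_strings(refs)), path)
  invisible(path)
}

#' Write converted reads as SAM
#'
#' Emits an unsorted SAM with one record per read: flag 0 (Watson) or 16
#' (Crick origin), CIGAR `<len>M`, and optional tags `XM:Z:` (call string),
#' `XC:i:` (truth compromised flag, 0/1). Sequences are stored in forward
#' reference orientation, as the SAM convention requires.
#'
#' @param reads `converted_reads` table.
#' @param refs references (for `@SQ` header lines).
#' @param path output `.sam` path.
#' @export
write_sam <- function(reads, refs, path) {
  ri <- ref_index(refs)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(names(ri), function(nm)
             sprintf("@SQ\tSN:%s\tLN:%d", nm, ri[[nm]]$length),
             character(1)),
           sprintf("@PG\tID:emscreen\tPN:emscreen\tVN:%s",
                   as.character(packageVersion("emscreen"))))
  rec <- character(0)
  if (nrow(reads) > 0L) {
    flag <- ifelse(reads$strand == "+", 0L, 16L)
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                   reads$qname, flag, reads$rname, reads$start + 1L,
                   nchar(reads$seq), reads$seq)
    if (!is.null(reads$xm)) rec <- paste0(rec, "\tXM:Z:", reads$xm)
    if (!is.null(reads$compromised))
      rec <- paste0(rec, "\tXC:i:", as.integer(reads$compromised))
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read aligned converted reads from SAM/BAM
#'
#' Uses Rsamtools (SAM files are converted to a temporary BAM first). Only
#' pure-match alignments are accepted (no indel support); records with
#' other CIGAR operations raise an error naming the record. An embedded
#' `XM` call-string tag is kept when `trust_xm = TRUE`, otherwise call
#' strings must be recomputed against the reference with
#' [add_call_strings()].
#'
#' @param path `.sam` or `.bam` file.
#' @param refs optional references; when given, read contigs are checked
#'   against them and missing contigs raise an error naming the contig.
#' @param trust_xm keep an embedded `XM` tag (default `TRUE`).
#' @return a `converted_reads` data.frame.
#' @export
read_alignments <- function(path, refs = NULL, trust_xm = TRUE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading alignments requires the Rsamtools package",
         call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("XM", "XC"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- data.frame(qname = character(), rname = character(),
                      start = integer(), end = integer(),
                      strand = character(), mate = character(),
                      seq = character())
    class(out) <- c("converted_reads", "data.frame")
    return(out)
  }
  bad <- which(!grepl("^[0-9]+M$", res$cigar))
  if (length(bad))
    stop(sprintf("record %d (%s): unsupported CIGAR '%s'", bad[1],
                 res$qname[bad[1]], res$cigar[bad[1]]), call. = FALSE)
  out <- data.frame(
    qname = res$qname,
    rname = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + as.integer(sub("M", "", res$cigar)),
    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
    mate = ifelse(bitwAnd(res$flag, 1L) > 0L,
                  ifelse(bitwAnd(res$flag, 64L) > 0L, "R1", "R2"),
                  "single"),
    seq = as.character(res$seq))
  if (trust_xm && !is.null(res$tag$XM)) out$xm <- res$tag$XM
  if (!is.null(res$tag$XC)) out$compromised <- res$tag$XC == 1L
  if (!is.null(refs)) {
    ri <- ref_index(refs)
    missing <- setdiff(unique(out$rname), names(ri))
    if (length(missing))
      stop("reference is missing contig(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("converted_reads", "data.frame")
  out
}

#' Write per-cytosine methylation outputs
#'
#' Writes a bedGraph (0-based half-open intervals, beta in percent) and a
#' per-cytosine report (1-based position; columns chrom, pos, strand,
#' methylated count, unmethylated count, context), both ordered by
#' coordinate.
#'
#' @param records methylation records (e.g. row-bound `cpg` and `ch` from
#'   [aggregate_cpg()]).
#' @param bedgraph,report output paths (`NULL` skips that file).
#' @return invisible list of written paths.
#' @export
write_methylation_outputs <- function(records, bedgraph = NULL,
                                      report = NULL) {
  records <- records[order(records$rname, records$pos, records$strand), ,
                     drop = FALSE]
  if (!is.null(bedgraph)) {
    lines <- sprintf("%s\t%d\t%d\t%s", records$rname, records$pos,
                     records$pos + 1L,
                     formatC(100 * records$beta, format = "fg",
                             digits = 6))
    writeLines(lines, bedgraph)
  }
  if (!is.null(report)) {
    ctx <- c(CpG = "CG", CHG = "CHG", CHH = "CHH")[records$context]
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s", records$rname,
                     records$pos + 1L, records$strand, records$meth,
                     records$unmeth, ctx)
    writeLines(lines, report)
  }
  invisible(list(bedgraph = bedgraph, report = report))
}

#' Read a per-cytosine report written by [write_methylation_outputs()]
#'
#' @param path report path.
#' @return methylation record data.frame (0-based `pos`, `beta` recomputed).
#' @export
read_cytosine_report <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("rname", "pos", "strand", "meth", "unmeth",
                                "ctx"),
                  colClasses = c("character", "integer", "character",
                                 "integer", "integer", "character"))
  data.frame(rname = d$rname, pos = d$pos - 1L, strand = d$strand,
             context = c(CG = "CpG", CHG = "CHG", CHH = "CHH")[d$ctx],
             meth = d$meth, unmeth = d$unmeth,
             beta = d$meth / (d$meth + d$unmeth), row.names = NULL)
}

#' Write / read a beta matrix as TSV
#'
#' Markers in rows (first column `marker`), samples in columns.
#'
#' @param beta markers x samples matrix.
#' @param path TSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  d <- data.frame(marker = rownames(beta), beta, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write / read a cohort sample sheet as TSV
#'
#' @param samples sample data.frame (`id`, `class`, `stage`, `afp`,
#'   `pivka`, `split`, ...).
#' @param path TSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c(id = "character"), check.names = FALSE)
}

PIPELINE_CONFIG_KEYS <- c("seed", "paths", "filter", "site_class",
                          "selection", "cohort", "train", "outdir")

#' Read / write the pipeline configuration
#'
#' The configuration is one structured JSON file with the top-level blocks
#' `seed`, `paths`, `filter`, `site_class`, `selection`, `cohort`, `train`,
#' `outdir`; unknown top-level keys are rejected. Writing then reading a
#' config round-trips losslessly.
#'
#' @param path JSON file.
#' @return named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config named list of config blocks.
#' @export
write_pipeline_config <- function(config, path) {
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize / restore a stacked model as versioned JSON
#'
#' Trees, combiner coefficients, threshold and feature lists serialize
#' losslessly to JSON (numbers at full precision).
#'
#' @param result a `stack_model` with layer-1 models attached (e.g.
#'   `run_full_training()$model`).
#' @param path JSON path.
#' @export
save_stack_model <- function(result, path) {
  stopifnot(inherits(result, "stack_model"))
  ser_l1 <- function(m) {
    list(kind = m$kind, features = m$features,
         grid = as.list(m$grid), cv_auc = m$cv_auc,
         model = list(trees = m$model$trees, base = m$model$base,
                      importance = as.list(m$model$importance),
                      features = m$model$features,
                      params = m$model$params))
  }
  obj <- list(format = "emscreen_stack_model", version = 1L,
              package_version = as.character(packageVersion("emscreen")),
              w = as.list(result$w), b = result$b, lambda = result$lambda,
              threshold = result$threshold,
              hn = ser_l1(result$hn), hl = ser_l1(result$hl))
  ## 17 significant digits: doubles round-trip bit-exactly through decimal
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_stack_model
#' @export
load_stack_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "emscreen_stack_model"))
    stop("not an emscreen model bundle", call. = FALSE)
  des_l1 <- function(m) {
    trees <- lapply(m$model$trees, function(tr) {
      list(feature = vapply(tr$feature, as.integer, 1L),
           threshold = vapply(tr$threshold, as.numeric, 1),
           left = vapply(tr$left, as.integer, 1L),
           right = vapply(tr$right, as.integer, 1L),
           value = vapply(tr$value, as.numeric, 1))
    })
    feats <- unlist(m$model$features)
    fit <- structure(list(trees = trees, base = m$model$base,
                          importance = setNames(unlist(m$model$importance),
                                                names(m$model$importance)),
                          features = feats,
                          params = lapply(m$model$params, unlist)),
                     class = "gbdt_model")
    structure(list(kind = m$kind, features = unlist(m$features),
                   model = fit, cv_auc = m$cv_auc,
                   grid = as.data.frame(lapply(m$grid, unlist))),
              class = "layer_one_model")
  }
  structure(list(hn = des_l1(obj$hn), hl = des_l1(obj$hl),
                 w = setNames(unlist(obj$w), c("hn", "hl")), b = obj$b,
                 lambda = obj$lambda, threshold = obj$threshold),
            class = "stack_model")
}

#' Read target regions from BED
#'
#' Minimal three-plus-column BED reader (0-based half-open).
#'
#' @param path BED file.
#' @return data.frame: `rname`, `start`, `end`, optional `name`.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = "character")
  out <- data.frame(rname = d[[1]], start = as.integer(d[[2]]),
                    end = as.integer(d[[3]]))
  if (ncol(d) >= 4) out$name <- d[[4]]
  out
}
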