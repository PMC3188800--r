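#' Load read alignments from SAM, BAM or the package's TSV dialect
#'
#' Produces a minimal `alignment_set`: one row per alignment record with the
#' reference span, SAM flag decomposition and the read's mean base quality.
#' The aligned length is the number of reference bases consumed by the CIGAR
#' (M/=/X/D/N operations). SAM/BAM positions are converted from 1-based to
#' the package's 0-based convention on ingest.
#'
#' The TSV dialect (emitted by [emit_reads] and [write_alignments_tsv]) has
#' columns `contig`, `start0`, `aligned_length`, `mapq`, `mean_qual`,
#' `flags`, with `#`-prefixed metadata lines allowed before the header.
#'
#' @param path Path to the alignment file.
#' @param dialect One of `"auto"` (by extension), `"sam"`, `"bam"`, `"tsv"`.
#' @return An `alignment_set` data frame with columns `contig`, `start`
#'   (0-based), `aligned_length`, `mapq`, `mean_qual`, `flags`, `is_mapped`,
#'   `is_secondary`, `is_duplicate`.
#' @export
load_alignments <- function(path, dialect = c("auto", "sam", "bam", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
                      sam = "sam", bam = "bam", "tsv")
  }
  if (dialect == "tsv") return(load_alignments_tsv(path))

  bam <- path
  if (dialect == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar", "mapq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$flag)
  if (n == 0L) stop("no alignment records in ", path)
  flag <- rec$flag
  is_mapped <- bitwAnd(flag, 4L) == 0L
  alen <- rep(0L, n)
  has_cigar <- is_mapped & !is.na(rec$cigar)
  if (any(has_cigar)) {
    alen[has_cigar] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$cigar[has_cigar])
  }
  mean_qual <- rep(NA_real_, n)
  ql <- methods::as(rec$qual, "IntegerList")
  has_q <- lengths(ql) > 0L
  mean_qual[has_q] <- vapply(ql[has_q], mean, numeric(1))
  out <- data.frame(
    contig = as.character(rec$rname),
    start = ifelse(is.na(rec$pos), NA_integer_, rec$pos - 1L),
    aligned_length = alen,
    mapq = ifelse(is.na(rec$mapq), 0L, rec$mapq),
    mean_qual = mean_qual,
    flags = flag,
    is_mapped = is_mapped,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_duplicate = bitwAnd(flag, 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_set", "data.frame")
  out
}

load_alignments_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("contig", "start0", "aligned_length", "mapq", "mean_qual", "flags")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("TSV alignment file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  ok <- !is.na(d$contig) & !is.na(d$start0) & !is.na(d$aligned_length) &
    d$start0 >= 0 & d$aligned_length >= 0
  n_bad <- sum(!ok)
  if (n_bad == nrow(d)) stop("all ", n_bad, " records malformed in ", path)
  if (n_bad > 0L) {
    warning("skipped ", n_bad, " malformed record(s) in ", path)
    d <- d[ok, , drop = FALSE]
  }
  flag <- as.integer(d$flags)
  out <- data.frame(
    contig = as.character(d$contig),
    start = as.integer(d$start0),
    aligned_length = as.integer(d$aligned_length),
    mapq = as.integer(d$mapq),
    mean_qual = as.numeric(d$mean_qual),
    flags = flag,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_duplicate = bitwAnd(flag, 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Filter an alignment set to the records that enter statistics
#'
#' Usable records are mapped, primary, non-duplicate, with MAPQ at or above
#' the threshold (default 0, i.e. no MAPQ filter).
#'
#' @param aln An `alignment_set`.
#' @param min_mapq Minimum mapping quality.
#' @return The filtered `alignment_set`.
#' @export
usable_alignments <- function(aln, min_mapq = 0L) {
  stopifnot(inherits(aln, "alignment_set") || is.data.frame(aln))
  keep <- aln$is_mapped & !aln$is_secondary & !aln$is_duplicate &
    aln$mapq >= min_mapq & aln$aligned_length > 0L
  out <- aln[keep, , drop = FALSE]
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Write an alignment set in the package's TSV dialect
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path, meta = NULL) {
  d <- data.frame(contig = aln$contig, start0 = aln$start,
                  aligned_length = aln$aligned_length, mapq = aln$mapq,
                  mean_qual = aln$mean_qual, flags = aln$flags)
  write_tsv_with_meta(d, path, meta)
}

#' Write an alignment set as SAM
#'
#' Emits a valid SAM file whose records reproduce the alignment set exactly:
#' CIGAR is `<aligned_length>M`, SEQ is taken from the reference at the
#' record's coordinates, and every base quality equals the record's (integer)
#' mean base quality, so a round trip through [load_alignments] preserves all
#' statistics bit for bit.
#'
#' @param aln An `alignment_set` (with integer `mean_qual`).
#' @param ref The [reference_set] the records align to.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  lens <- contig_lengths(ref)
  bad <- setdiff(unique(aln$contig), names(lens))
  if (length(bad)) stop("contigs absent from reference: ",
                        paste(bad, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(aln) > 0L) {
    seqs <- character(nrow(aln))
    for (ct in unique(aln$contig)) {
      i <- which(aln$contig == ct)
      v <- Biostrings::Views(ref$seq[[ct]], start = aln$start[i] + 1L,
                             width = aln$aligned_length[i])
      seqs[i] <- as.character(v)
    }
    q <- as.integer(round(aln$mean_qual))
    quals <- vapply(seq_len(nrow(aln)), function(i) {
      strrep(rawToChar(as.raw(q[i] + 33L)), aln$aligned_length[i])
    }, character(1))
    writeLines(sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                       seq_len(nrow(aln)), aln$flags, aln$contig,
                       aln$start + 1L, aln$mapq, aln$aligned_length,
                       seqs, quals), con)
  }
  invisible(path)
}
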