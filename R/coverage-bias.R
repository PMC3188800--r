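#' Assign reads to GC windows by alignment-span midpoint
#'
#' Reads (typically 101 bases) span several 50-bp windows, so each usable
#' read is counted once, in the single window containing the midpoint of its
#' alignment span (for even spans the left-of-middle base, i.e. ties go to
#' the left). When several windows contain the midpoint (sliding windows),
#' the window whose center is nearest the midpoint wins, ties again to the
#' left. Reads whose midpoint falls in no valid window are dropped and
#' counted.
#'
#' @param aln An `alignment_set`.
#' @param windows A `window_table` over the same reference.
#' @param min_mapq Minimum MAPQ for a read to be usable.
#' @param detail If TRUE, also return the per-read window row index.
#' @return Integer vector of per-window read counts (length `nrow(windows)`),
#'   with attributes `n_used`, `n_dropped`; if `detail`, a list with
#'   `counts`, `read_window` (NA for dropped reads) and `used` (row index
#'   into `aln` of the usable reads).
#' @export
assign_reads_to_windows <- function(aln, windows, min_mapq = 0L,
                                    detail = FALSE) {
  stopifnot(inherits(windows, "window_table"))
  use <- usable_alignments(aln, min_mapq)
  used_idx <- which(aln$is_mapped & !aln$is_secondary & !aln$is_duplicate &
                      aln$mapq >= min_mapq & aln$aligned_length > 0L)
  unmatched <- setdiff(unique(use$contig), unique(windows$contig))
  if (length(unmatched)) {
    stop("alignment contigs not present in window table: ",
         paste(unmatched, collapse = ", "))
  }
  mid <- use$start + (use$aligned_length - 1L) %/% 2L
  assign <- rep(NA_integer_, nrow(use))
  for (ct in unique(use$contig)) {
    ri <- which(use$contig == ct)
    wi <- which(windows$contig == ct & windows$valid)
    if (length(wi) == 0L) next
    wr <- IRanges::IRanges(start = windows$start[wi] + 1L,
                           width = windows$length[wi])
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mid[ri] + 1L, width = 1L), wr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # window center on the same scale as mid (0-based base index)
    ctr <- windows$start[wi[sh]] + (windows$length[wi[sh]] - 1L) / 2
    dist <- abs(ctr - mid[ri[qh]])
    ord <- order(qh, dist, windows$start[wi[sh]])
    first <- !duplicated(qh[ord])
    assign[ri[qh[ord][first]]] <- wi[sh[ord][first]]
  }
  counts <- tabulate(assign, nbins = nrow(windows))
  attr(counts, "n_used") <- sum(!is.na(assign))
  attr(counts, "n_dropped") <- sum(is.na(assign))
  if (detail) {
    list(counts = counts, read_window = assign, used = used_idx)
  } else {
    counts
  }
}

#' Observed/expected GC-bias curve
#'
#' The central statistic: for every percent-GC bin, the number of reads
#' assigned to windows in that bin is divided by the number of valid windows
#' in the bin (the expected weight under perfectly even coverage), and the
#' resulting ratios are normalized so that their mean over the anchor bins
#' (default 48-52% GC) equals 1 exactly. Values are stored on the linear
#' scale; log10 is a presentation choice only.
#'
#' Bins with zero windows are absent from the curve; bins with windows but
#' zero reads are present with relative value 0, so depletion at the GC
#' extremes stays visible to [plateau] and [fold_change].
#'
#' @param counts Per-window read counts from [assign_reads_to_windows].
#' @param windows The `window_table` the counts refer to.
#' @param histogram Optional `gc_histogram`; computed from `windows` if NULL.
#' @param anchor Anchor bin values in percent (default `c(48, 50, 52)`).
#' @return A `bias_curve` data frame with columns `bin_percent`,
#'   `observed_reads`, `expected_windows`, `relative_value`, `masked`,
#'   `mask_reason`; attributes `anchor` and `n_reads`.
#' @export
bias_curve <- function(counts, windows, histogram = NULL,
                       anchor = c(48, 50, 52)) {
  stopifnot(inherits(windows, "window_table"))
  if (length(counts) != nrow(windows)) {
    stop("'counts' must have one entry per window")
  }
  if (is.null(histogram)) histogram <- gc_histogram(windows)
  w <- attr(windows, "window_length")
  vi <- windows$valid
  # aggregate on the integer GC count so bin matching is exact
  reads_by_count <- tapply(counts[vi], windows$gc_count[vi], sum)
  bins <- histogram$bin_percent
  bin_k <- as.integer(round(bins * w / 100))
  m <- match(as.integer(names(reads_by_count)), bin_k)
  if (anyNA(m)) stop("histogram bins do not cover all bins present in counts")
  obs <- rep(0, length(bins))
  obs[m] <- as.numeric(reads_by_count)
  keep <- histogram$count > 0
  bins <- bins[keep]; obs <- obs[keep]
  wins <- histogram$count[keep]
  ratio <- obs / wins
  ai <- match(anchor, bins)
  if (anyNA(ai)) {
    stop("anchor undefined: anchor bin(s) ",
         paste(anchor[is.na(ai)], collapse = ", "),
         " have no valid windows")
  }
  if (sum(obs[ai]) == 0) stop("anchor undefined: zero reads in all anchor bins")
  anchor_mean <- mean(ratio[ai])
  out <- data.frame(
    bin_percent = bins,
    observed_reads = obs,
    expected_windows = wins,
    relative_value = ratio / anchor_mean,
    masked = FALSE,
    mask_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(out, "anchor") <- anchor
  attr(out, "n_reads") <- sum(obs)
  class(out) <- c("bias_curve", "data.frame")
  out
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("bias_curve:", nrow(x), "bins,", attr(x, "n_reads"),
      "reads, anchor", paste(attr(x, "anchor"), collapse = "/"), "%GC\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Per-base read coverage profile
#'
#' Counts, for every base of the reference, the number of usable reads whose
#' alignment span covers it. Ambiguous (masked) bases are excluded from the
#' genome-wide mean and from all downstream fractions.
#'
#' @param aln An `alignment_set`.
#' @param ref The [reference_set] the alignments refer to.
#' @param min_mapq Minimum MAPQ.
#' @return A `coverage_profile`: list with `coverage` (per-contig
#'   [S4Vectors::Rle] of counts), `mask`, `genome_mean`, `n_unmasked`.
#' @export
per_base_coverage <- function(aln, ref, min_mapq = 0L) {
  stopifnot(inherits(ref, "reference_set"))
  use <- usable_alignments(aln, min_mapq)
  lens <- contig_lengths(ref)
  bad <- setdiff(unique(use$contig), names(lens))
  if (length(bad)) stop("contigs absent from reference: ",
                        paste(bad, collapse = ", "))
  cov <- vector("list", length(lens))
  names(cov) <- names(lens)
  total <- 0
  n_unmasked <- 0L
  for (ct in names(lens)) {
    i <- which(use$contig == ct)
    cv <- IRanges::coverage(
      IRanges::IRanges(start = use$start[i] + 1L,
                       width = use$aligned_length[i]),
      width = lens[[ct]])
    cov[[ct]] <- cv
    unm <- !ref$mask[[ct]]
    n_unmasked <- n_unmasked + sum(unm)
    total <- total + sum(as.numeric(cv[unm]))
  }
  if (n_unmasked == 0L) stop("reference has no unambiguous bases")
  structure(list(coverage = cov, mask = ref$mask,
                 genome_mean = total / n_unmasked,
                 n_unmasked = n_unmasked),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %d contig(s), mean %.3f over %d unambiguous bases\n",
              length(x$coverage), x$genome_mean, x$n_unmasked))
  invisible(x)
}

#' Fraction of the genome covered below a fraction of the mean
#'
#' The coverage-evenness summary: the fraction of non-ambiguous bases whose
#' per-base read count is strictly less than `threshold_fraction` times the
#' genome-wide mean (default one-tenth).
#'
#' @param profile A `coverage_profile`.
#' @param threshold_fraction Fraction of the genome mean (default 0.1).
#' @return The under-covered fraction, in `[0, 1]`.
#' @export
under_coverage_fraction <- function(profile, threshold_fraction = 0.1) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (profile$genome_mean <= 0) stop("no coverage")
  thr <- threshold_fraction * profile$genome_mean
  n_below <- 0
  for (ct in names(profile$coverage)) {
    unm <- !profile$mask[[ct]]
    n_below <- n_below + sum(as.numeric(profile$coverage[[ct]][unm] < thr))
  }
  n_below / profile$n_unmasked
}

#' Relative representation of loci in sequencing coverage
#'
#' Compares the mean per-base coverage of each locus (or of all loci pooled)
#' to the genome-wide mean. Pooled mode computes a single mean over every
#' base of every locus before dividing, the appropriate statistic when
#' per-locus depth is too shallow to be meaningful on its own.
#'
#' @param profile A `coverage_profile`.
#' @param loci Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and optionally `id`.
#' @param mode `"per_locus"` or `"pooled"`.
#' @return `per_locus`: data frame `id`, `contig`, `start`, `end`,
#'   `mean_coverage`, `relative_value`; `pooled`: a single number.
#' @export
locus_representation <- function(profile, loci,
                                 mode = c("per_locus", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "coverage_profile"))
  if (nrow(loci) == 0L) stop("empty locus list")
  if (any(loci$end <= loci$start)) stop("empty locus (end <= start)")
  bad <- setdiff(unique(loci$contig), names(profile$coverage))
  if (length(bad)) stop("loci on unknown contig(s): ",
                        paste(bad, collapse = ", "))
  sums <- numeric(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    cv <- profile$coverage[[loci$contig[i]]]
    sums[i] <- sum(as.numeric(
      S4Vectors::window(cv, start = loci$start[i] + 1L, end = loci$end[i])))
  }
  lens <- loci$end - loci$start
  if (mode == "pooled") {
    return(sum(sums) / sum(lens) / profile$genome_mean)
  }
  data.frame(
    id = if ("id" %in% names(loci)) loci$id else seq_len(nrow(loci)),
    contig = loci$contig, start = loci$start, end = loci$end,
    mean_coverage = sums / lens,
    relative_value = sums / lens / profile$genome_mean,
    stringsAsFactors = FALSE
  )
}

#' Mask bias-curve bins whose reads fall below a base-quality threshold
#'
#' The bin statistic is the mean over its assigned reads of each read's mean
#' base quality; bins below the Phred threshold (default Q20, 1% error) are
#' flagged but keep their values, so presentation code can plot them as open
#' symbols or drop them. Bins with no reads are masked with reason
#' `"no reads"`.
#'
#' @param aln The `alignment_set` the curve was computed from.
#' @param windows The `window_table` used.
#' @param curve The `bias_curve` to annotate.
#' @param q_threshold Phred threshold (default 20).
#' @param min_mapq Minimum MAPQ (must match the curve's).
#' @return The curve with `masked`/`mask_reason` updated and a new column
#'   `mean_read_quality`.
#' @export
quality_mask <- function(aln, windows, curve, q_threshold = 20,
                         min_mapq = 0L) {
  stopifnot(inherits(curve, "bias_curve"))
  det <- assign_reads_to_windows(aln, windows, min_mapq, detail = TRUE)
  use <- usable_alignments(aln, min_mapq)
  ok <- !is.na(det$read_window)
  k_of_read <- windows$gc_count[det$read_window[ok]]
  qual <- use$mean_qual[ok]
  mq <- tapply(qual, k_of_read, mean)
  w <- attr(windows, "window_length")
  m <- match(as.integer(round(curve$bin_percent * w / 100)),
             as.integer(names(mq)))
  curve$mean_read_quality <- as.numeric(mq)[m]
  no_reads <- is.na(curve$mean_read_quality)
  low_q <- !no_reads & curve$mean_read_quality < q_threshold
  curve$masked <- curve$masked | no_reads | low_q
  curve$mask_reason[no_reads & is.na(curve$mask_reason)] <- "no reads"
  curve$mask_reason[low_q & is.na(curve$mask_reason)] <-
    paste0("mean quality < Q", q_threshold)
  curve
}

#' Per-bin ratio of two bias curves
#'
#' The fold change in relative coverage between two libraries, bin by bin.
#' Both curves must be anchored the same way; the ratio of anchor-bin means
#' is then 1 by construction. Masks propagate (union); bins where the
#' denominator is zero are flagged undefined.
#'
#' @param curve_a,curve_b `bias_curve` objects over shared bins.
#' @return Data frame `bin_percent`, `value_a`, `value_b`, `ratio`,
#'   `masked`, `mask_reason`, `undefined`.
#' @export
fold_change <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "bias_curve"), inherits(curve_b, "bias_curve"))
  if (!identical(attr(curve_a, "anchor"), attr(curve_b, "anchor"))) {
    stop("curves use different anchor definitions")
  }
  shared <- intersect(curve_a$bin_percent, curve_b$bin_percent)
  if (length(shared) == 0L) stop("curves have disjoint bins")
  a <- curve_a[match(shared, curve_a$bin_percent), ]
  b <- curve_b[match(shared, curve_b$bin_percent), ]
  undef <- b$relative_value == 0
  out <- data.frame(
    bin_percent = shared,
    value_a = a$relative_value,
    value_b = b$relative_value,
    ratio = ifelse(undef, NA_real_, a$relative_value / b$relative_value),
    masked = a$masked | b$masked,
    mask_reason = ifelse(a$masked, a$mask_reason,
                         ifelse(b$masked, b$mask_reason, NA_character_)),
    undefined = undef,
    stringsAsFactors = FALSE
  )
  out
}

#' Pool several read sets into one bias curve
#'
#' Reads are concatenated before binning (count-level pooling, not averaging
#' of curves) and the pooled curve is re-anchored. All sets must align to the
#' same reference as the window table.
#'
#' @param read_sets List of `alignment_set` objects (length >= 2, or 1+ with
#'   repeats).
#' @param windows,histogram,anchor As in [bias_curve].
#' @param min_mapq Minimum MAPQ.
#' @return A `bias_curve`.
#' @export
pool_curves <- function(read_sets, windows, histogram = NULL,
                        anchor = c(48, 50, 52), min_mapq = 0L) {
  if (length(read_sets) < 1L) stop("no read sets supplied")
  wct <- unique(windows$contig)
  for (i in seq_along(read_sets)) {
    extra <- setdiff(unique(read_sets[[i]]$contig), wct)
    if (length(extra)) {
      stop("read set ", i, " aligned to a different reference (contigs: ",
           paste(extra, collapse = ", "), ")")
    }
  }
  pooled <- do.call(rbind, lapply(read_sets, as.data.frame))
  class(pooled) <- c("alignment_set", "data.frame")
  counts <- assign_reads_to_windows(pooled, windows, min_mapq)
  bias_curve(counts, windows, histogram, anchor)
}
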