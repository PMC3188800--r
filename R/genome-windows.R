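#' Windowed GC content of a reference
#'
#' Slides (or tiles) fixed-length windows along every contig and records the
#' number of G/C bases in each. Windows never span contigs. A window is
#' `valid` only if it contains no ambiguous base; invalid windows are
#' excluded from both the observed and the expected side of downstream
#' bias-curve normalization so numerator and denominator stay consistent.
#'
#' @param ref A [reference_set].
#' @param window_length Window size in bases (50 reproduces the standard
#'   50-bp analysis granularity; bins are then 2 percentage points wide).
#' @param step Distance between successive window starts. `step = 1` gives
#'   sliding windows (the default), `step = window_length` a tiling.
#' @return A `window_table` data frame with columns `contig`, `start`
#'   (0-based), `length`, `gc_count`, `gc_percent` (exact rational times
#'   100), `valid`; attributes `window_length` and `step`.
#' @export
window_gc <- function(ref, window_length = 50L, step = 1L) {
  stopifnot(inherits(ref, "reference_set"))
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 1L) stop("window_length must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  res <- vector("list", length(ref$seq))
  for (i in seq_along(ref$seq)) {
    s <- ref$seq[[i]]
    L <- length(s)
    if (L < window_length) {
      res[[i]] <- NULL  # contig shorter than the window: no windows, not an error
      next
    }
    starts1 <- seq.int(1L, L - window_length + 1L, by = step)
    if (step == 1L) {
      gc <- Biostrings::letterFrequencyInSlidingView(s, window_length, "GC")[, 1L]
      at <- Biostrings::letterFrequencyInSlidingView(s, window_length, "AT")[, 1L]
    } else {
      v <- Biostrings::Views(s, start = starts1, width = window_length)
      gc <- Biostrings::letterFrequency(v, "GC")[, 1L]
      at <- Biostrings::letterFrequency(v, "AT")[, 1L]
    }
    gc <- as.integer(gc)
    valid <- gc + at == window_length
    res[[i]] <- data.frame(
      contig = rep(names(ref$seq)[i], length(starts1)),
      start = starts1 - 1L,
      length = window_length,
      gc_count = gc,
      gc_percent = 100 * gc / window_length,
      valid = valid,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      length = integer(0), gc_count = integer(0),
                      gc_percent = numeric(0), valid = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "window_length") <- window_length
  attr(out, "step") <- step
  class(out) <- c("window_table", "data.frame")
  out
}

#' Map a window GC count to its percent-GC bin
#'
#' The natural bin granularity for windows of length `w` is `100/w` percent
#' (2 percent for 50-bp windows), and the mapping is exact: bin =
#' `100 * gc_count / window_length` with no floating-point rounding before
#' binning.
#'
#' @param gc_count Integer count(s) of G/C bases, `0..window_length`.
#' @param window_length Window size in bases.
#' @return Numeric bin value(s) in percent.
#' @examples
#' gc_bin(25, 50)  # 50
#' gc_bin(45, 50)  # 90
#' @export
gc_bin <- function(gc_count, window_length) {
  window_length <- as.integer(window_length)
  if (window_length < 1L) stop("window_length must be >= 1")
  if (any(gc_count < 0 | gc_count > window_length)) {
    stop("gc_count out of range [0, ", window_length, "]")
  }
  100 * gc_count / window_length
}

#' Histogram of valid windows by percent-GC bin
#'
#' Counts valid windows per GC bin at the window table's natural granularity.
#' Bins with zero windows inside the observed range are present with count 0
#' so depleted bins remain visible downstream.
#'
#' @param windows A `window_table` from [window_gc].
#' @return A `gc_histogram` data frame with columns `bin_percent`, `count`;
#'   attribute `window_length`.
#' @export
gc_histogram <- function(windows) {
  stopifnot(inherits(windows, "window_table"))
  if (nrow(windows) == 0L) stop("empty window table")
  w <- attr(windows, "window_length")
  v <- windows[windows$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid windows")
  counts <- tabulate(v$gc_count + 1L, nbins = w + 1L)
  kk <- range(which(counts > 0L)) - 1L
  idx <- kk[1]:kk[2]
  out <- data.frame(bin_percent = 100 * idx / w, count = counts[idx + 1L])
  attr(out, "window_length") <- w
  class(out) <- c("gc_histogram", "data.frame")
  out
}

#' GC content of the sequence context around a locus
#'
#' Computes the percent GC of a fixed-length window centered on the midpoint
#' of a locus (default 250 bases, the conventional local-context span for
#' short amplicons). Windows running off a contig edge are clipped, not
#' discarded; the realized span is reported.
#'
#' @param ref A [reference_set].
#' @param contig Contig name.
#' @param start,end Locus coordinates, 0-based half-open.
#' @param context_length Context window length in bases.
#' @return List with `gc_percent`, `start`, `end` (0-based half-open realized
#'   window) and `length` (realized span, `<= context_length` when clipped).
#' @export
context_gc <- function(ref, contig, start, end, context_length = 250L) {
  stopifnot(inherits(ref, "reference_set"))
  if (!contig %in% names(ref$seq)) stop("unknown contig: ", contig)
  L <- length(ref$seq[[contig]])
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > L || end <= start) {
    stop("locus [", start, ",", end, ") outside contig '", contig,
         "' (length ", L, ")")
  }
  mid <- (start + end) %/% 2L
  ws <- mid - as.integer(context_length) %/% 2L
  we <- ws + as.integer(context_length)
  ws <- max(0L, ws)
  we <- min(L, we)
  v <- Biostrings::subseq(ref$seq[[contig]], start = ws + 1L, end = we)
  gc <- Biostrings::letterFrequency(v, "GC")[1L]
  list(gc_percent = 100 * as.numeric(gc) / (we - ws),
       start = ws, end = we, length = we - ws)
}
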