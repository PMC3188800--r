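# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: plain character/loop arithmetic.

# per-window GC and validity by character counting
oracle_window_gc <- function(seq_string, w, step = 1L) {
  chars <- strsplit(seq_string, "")[[1]]
  L <- length(chars)
  if (L < w) return(data.frame(start = integer(0), gc = integer(0),
                               valid = logical(0)))
  starts <- seq(0L, L - w, by = step)
  gc <- integer(length(starts))
  valid <- logical(length(starts))
  for (i in seq_along(starts)) {
    win <- chars[(starts[i] + 1):(starts[i] + w)]
    gc[i] <- sum(win %in% c("G", "C"))
    valid[i] <- all(win %in% c("A", "C", "G", "T"))
  }
  data.frame(start = starts, gc = gc, valid = valid)
}

# O(n^2) plateau scan over every contiguous run, same tie-break rules:
# longest run, then the run containing the point nearest 50% GC, then the
# lower-GC run
oracle_plateau <- function(g, v, floor = 0.7, max_below = 1L) {
  o <- order(g); g <- g[o]; v <- v[o]
  n <- length(g)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      nb <- sum(v[i:j] < floor)
      if (nb > max_below) next
      len <- j - i + 1L
      score <- min(abs(g[i:j] - 50))
      if (is.null(best) || len > best$len ||
          (len == best$len && score < best$score)) {
        best <- list(i = i, j = j, len = len, nb = nb, score = score)
      }
    }
  }
  if (is.null(best)) {
    return(list(gc_low = NA_real_, gc_high = NA_real_, n_points = 0L,
                n_below = 0L))
  }
  list(gc_low = g[best$i], gc_high = g[best$j], n_points = best$len,
       n_below = as.integer(best$nb))
}

# per-base coverage and under-coverage fraction by explicit base loop
oracle_undercov <- function(starts, lens, genome_len, mask, threshold = 0.1) {
  cov <- integer(genome_len)
  for (k in seq_along(starts)) {
    idx <- (starts[k] + 1):(starts[k] + lens[k])
    cov[idx] <- cov[idx] + 1L
  }
  unm <- !mask
  m <- sum(cov[unm]) / sum(unm)
  sum(cov[unm] < threshold * m) / sum(unm)
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal alignment_set constructor for hand-built fixtures
make_aln <- function(contig, start, len, mapq = 60L, mean_qual = 35,
                     flags = 0L) {
  n <- max(length(contig), length(start), length(len))
  d <- data.frame(contig = rep_len(contig, n), start = rep_len(start, n),
                  aligned_length = rep_len(len, n),
                  mapq = rep_len(mapq, n),
                  mean_qual = rep_len(mean_qual, n),
                  flags = rep_len(flags, n), stringsAsFactors = FALSE)
  d$is_mapped <- bitwAnd(d$flags, 4L) == 0L
  d$is_secondary <- bitwAnd(d$flags, 256L) != 0L
  d$is_duplicate <- bitwAnd(d$flags, 1024L) != 0L
  class(d) <- c("alignment_set", "data.frame")
  d
}
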