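#' Generate one synthetic genome component with block-wise GC structure
#'
#' Emulates a genome of a given overall GC content with GC varying from
#' block to block: for each block a GC fraction is drawn from
#' `Normal(gc_target, gc_block_sd)` (clipped to `[0, 1]`) and the block's
#' bases are then drawn independently with that GC. The block structure
#' produces a realistically broad window-GC distribution with spatial
#' coherence (AT-rich and GC-rich regions, not just binomial noise around
#' the mean), which is what makes fragment-level and window-level GC agree
#' the way they do in real genomes.
#'
#' @param name Contig name.
#' @param length Sequence length in bases.
#' @param gc_target Target genome-wide GC fraction, in `[0, 1]`.
#' @param block_length Block size in bases over which GC is constant.
#' @param gc_block_sd Standard deviation of the block GC fractions.
#' @param rng_seed Integer seed (mandatory; the draw is bit-reproducible).
#' @return A single-contig [reference_set].
#' @export
generate_component <- function(name, length, gc_target, block_length = 500L,
                               gc_block_sd = 0.05, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (length < block_length) stop("length must be >= block_length")
  set.seed(rng_seed)
  n_blocks <- ceiling(length / block_length)
  block_gc <- pmin(1, pmax(0, stats::rnorm(n_blocks, gc_target, gc_block_sd)))
  sizes <- rep(block_length, n_blocks)
  sizes[n_blocks] <- length - block_length * (n_blocks - 1L)
  blocks <- vapply(seq_len(n_blocks), function(i) {
    gcb <- block_gc[i]
    paste(sample(c("A", "C", "G", "T"), sizes[i], replace = TRUE,
                 prob = c((1 - gcb) / 2, gcb / 2, gcb / 2, (1 - gcb) / 2)),
          collapse = "")
  }, character(1))
  reference_set(stats::setNames(paste(blocks, collapse = ""), name))
}

#' Synthetic scaled three-component composite test genome
#'
#' Builds a desk-scale stand-in for a composite test genome pooling three
#' components with mean GC near 19%, 51% and 69% in length proportions
#' 23 : 4.6 : 4.6 (an AT-rich eukaryote-like component making up ~71% of the
#' composite, flanked by a mid-GC and a GC-rich bacterial-like component).
#' The default `scale = 0.01` gives a 322-kb composite that runs in seconds.
#' The AT-rich component gets a broader block-GC spread than the bacterial
#' ones, mirroring the much wider window-GC distribution of AT-rich genomes.
#'
#' @param scale Length scale relative to the full-size 32-Mb composite.
#' @param rng_seed Integer seed; per-component seeds are derived from it.
#' @param block_length Block size passed to [generate_component].
#' @param gc_block_sd Per-component block-GC standard deviations.
#' @return A three-contig [reference_set] (contigs `pfal_syn`, `ecol_syn`,
#'   `rsph_syn`).
#' @export
scaled_per_reference <- function(scale = 0.01, rng_seed, block_length = 500L,
                                 gc_block_sd = c(0.08, 0.04, 0.04)) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  lens <- round(scale * c(23e6, 4.6e6, 4.6e6))
  if (any(lens < block_length)) {
    stop("scale too small for the block structure (component lengths ",
         paste(lens, collapse = ", "), " vs block_length ", block_length, ")")
  }
  gc <- c(0.19, 0.51, 0.69)
  nm <- c("pfal_syn", "ecol_syn", "rsph_syn")
  comps <- lapply(1:3, function(i) {
    generate_component(nm[i], lens[i], gc[i], block_length, gc_block_sd[i],
                       rng_seed = rng_seed + i)
  })
  build_composite(comps)
}

#' Shear a reference into a random fragment pool
#'
#' Fragment lengths follow a discretized gamma distribution parameterized by
#' its mode and standard deviation (sonication produces a positive, unimodal
#' length distribution; only the mode is usually reported, so the spread is
#' a free parameter). Start positions are uniform over valid placements.
#' Every fragment starts with copy number 1.
#'
#' @param ref A [reference_set].
#' @param n_fragments Number of fragments to draw.
#' @param mode_length Modal fragment length in bases (225 emulates a typical
#'   short sonication setting).
#' @param length_sd Standard deviation of fragment length.
#' @param rng_seed Integer seed (mandatory).
#' @return A `fragment_pool` data frame with columns `contig`, `start`
#'   (0-based), `length`, `gc_percent`, `copy_number`.
#' @export
fragment_genome <- function(ref, n_fragments, mode_length = 225,
                            length_sd = 60, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  stopifnot(inherits(ref, "reference_set"))
  lens <- contig_lengths(ref)
  if (mode_length >= min(lens)) {
    stop("mode_length must be smaller than the shortest contig")
  }
  set.seed(rng_seed)
  # gamma with given mode m and sd s: scale = (-m + sqrt(m^2 + 4 s^2)) / 2
  th <- (-mode_length + sqrt(mode_length^2 + 4 * length_sd^2)) / 2
  k <- mode_length / th + 1
  fl <- pmax(1L, as.integer(round(stats::rgamma(n_fragments, shape = k,
                                                scale = th))))
  ct <- sample(names(lens), n_fragments, replace = TRUE,
               prob = lens / sum(lens))
  L <- as.integer(lens[ct])
  fl <- pmin(fl, L)
  start <- as.integer(floor(stats::runif(n_fragments) * (L - fl + 1L)))
  gc <- numeric(n_fragments)
  for (c1 in unique(ct)) {
    i <- which(ct == c1)
    v <- Biostrings::Views(ref$seq[[c1]], start = start[i] + 1L, width = fl[i])
    gc[i] <- 100 * Biostrings::letterFrequency(v, "GC")[, 1] / fl[i]
  }
  out <- data.frame(contig = ct, start = start, length = fl,
                    gc_percent = gc, copy_number = 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_pool", "data.frame")
  out
}

#' Apparent gel excision window for a desired insert size
#'
#' Library molecules run on a gel carry adapters, so the excised apparent
#' size window sits `adapter_offset` (90 bp for standard paired-end
#' adapters) above the desired insert range:
#' `(target - tolerance + offset, target + tolerance + offset)`.
#'
#' @param insert_target Desired insert size in bases.
#' @param tolerance Half-width of the insert window.
#' @param adapter_offset Total adapter length added to the apparent size.
#' @return Numeric vector `c(low, high)` of apparent sizes.
#' @examples
#' gel_window(180, 20)  # c(250, 290)
#' @export
gel_window <- function(insert_target, tolerance, adapter_offset = 90) {
  if (tolerance >= insert_target) stop("tolerance must be < insert_target")
  c(low = insert_target - tolerance + adapter_offset,
    high = insert_target + tolerance + adapter_offset)
}

#' Size-select a fragment pool
#'
#' Retains fragments whose (insert) length lies in
#' `[insert_target - tolerance, insert_target + tolerance]`, the insert
#' range corresponding to the gel window of [gel_window].
#'
#' @param pool A `fragment_pool`.
#' @param insert_target,tolerance Insert size window.
#' @return The filtered `fragment_pool`.
#' @export
size_select <- function(pool, insert_target, tolerance) {
  if (nrow(pool) == 0L) stop("empty fragment pool")
  keep <- pool$length >= insert_target - tolerance &
    pool$length <= insert_target + tolerance
  if (!any(keep)) {
    stop(sprintf(
      "size selection [%g, %g] retains no fragments (observed lengths %d-%d)",
      insert_target - tolerance, insert_target + tolerance,
      min(pool$length), max(pool$length)))
  }
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_pool", "data.frame")
  out
}

#' Amplify a fragment pool with a protocol profile
#'
#' Convenience wrapper running [simulate_pcr] on the pool's copy numbers
#' using each fragment's whole-fragment GC (amplification acts on library
#' molecules, so fragment GC, not window GC, drives the efficiency).
#'
#' @param pool A `fragment_pool`.
#' @param profile An [efficiency_profile] or preset name.
#' @param n_cycles Number of PCR cycles.
#' @param rng_seed Integer seed.
#' @return The pool with updated `copy_number`.
#' @export
amplify_pool <- function(pool, profile, n_cycles, rng_seed) {
  if (is.character(profile)) profile <- protocol_preset(profile)
  pool$copy_number <- simulate_pcr(pool$copy_number, profile,
                                   pool$gc_percent, n_cycles, rng_seed)
  pool
}

#' Sequencing simulation parameters
#'
#' @param rng_seed Integer seed (mandatory for any stochastic step).
#' @param read_length Read length in bases (default 101).
#' @param paired Emit both fragment ends as an inward-facing pair.
#' @param n_reads Number of reads to emit.
#' @param insert_target,insert_tolerance Size-selection window in bases.
#' @param adapter_offset Adapter length for [gel_window] bookkeeping.
#' @param quality_mean,quality_sd Per-read mean base-quality model (Phred).
#' @param quality_gc_slope Linear change in mean quality per percent GC away
#'   from 50 (negative values let GC-rich reads droop below Q20, exercising
#'   [quality_mask]); default 0.
#' @param qpcr_noise_sd Cq noise (cycles) for [emulate_qpcr].
#' @return A `sim_config` list.
#' @export
sim_config <- function(rng_seed, read_length = 101L, paired = TRUE,
                       n_reads = 1e5, insert_target = 180L,
                       insert_tolerance = 20L, adapter_offset = 90L,
                       quality_mean = 35, quality_sd = 2,
                       quality_gc_slope = 0, qpcr_noise_sd = 0.2) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  stopifnot(read_length >= 1, n_reads >= 1)
  structure(list(rng_seed = as.integer(rng_seed),
                 read_length = as.integer(read_length), paired = paired,
                 n_reads = as.integer(n_reads),
                 insert_target = as.integer(insert_target),
                 insert_tolerance = as.integer(insert_tolerance),
                 adapter_offset = as.integer(adapter_offset),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 quality_gc_slope = quality_gc_slope,
                 qpcr_noise_sd = qpcr_noise_sd),
            class = "sim_config")
}

#' Emit reads from an (amplified) fragment pool with ground-truth alignments
#'
#' Fragments are sampled with replacement proportional to their copy number;
#' each sampled fragment yields one read at its 5' end (and, in paired mode,
#' a second, reverse-strand read at its 3' end, so the mate span equals the
#' fragment length). Emitted coordinates are ground truth: read sequences
#' match the reference at their coordinates, so no aligner is needed. Each
#' read gets an integer mean base quality drawn from the quality model
#' (rounded, clipped to `[2, 41]`), applied uniformly to its bases, which
#' makes the SAM and TSV representations of the same reads exactly
#' equivalent downstream.
#'
#' @param pool A `fragment_pool` with positive total copy number.
#' @param config A [sim_config] (supplies seed, read length, pairing and the
#'   quality model).
#' @return An `alignment_set` with extra columns `fragment_id` and `mate`.
#' @export
emit_reads <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pool) == 0L || sum(pool$copy_number) <= 0) {
    stop("fragment pool has no copies to sequence")
  }
  set.seed(config$rng_seed)
  n_pairs <- if (config$paired) ceiling(config$n_reads / 2) else config$n_reads
  idx <- sample.int(nrow(pool), n_pairs, replace = TRUE,
                    prob = pool$copy_number)
  rl <- pmin(config$read_length, pool$length[idx])
  q_mean <- config$quality_mean +
    config$quality_gc_slope * (pool$gc_percent[idx] - 50)
  draw_q <- function() {
    pmin(41L, pmax(2L, as.integer(round(
      stats::rnorm(n_pairs, q_mean, config$quality_sd)))))
  }
  r1 <- data.frame(
    contig = pool$contig[idx],
    start = pool$start[idx],
    aligned_length = rl,
    mapq = 60L,
    mean_qual = as.numeric(draw_q()),
    flags = if (config$paired) 99L else 0L,
    fragment_id = idx,
    mate = 1L,
    stringsAsFactors = FALSE
  )
  out <- r1
  if (config$paired) {
    r2 <- data.frame(
      contig = pool$contig[idx],
      start = pool$start[idx] + pool$length[idx] - rl,
      aligned_length = rl,
      mapq = 60L,
      mean_qual = as.numeric(draw_q()),
      flags = 147L,
      fragment_id = idx,
      mate = 2L,
      stringsAsFactors = FALSE
    )
    out <- rbind(r1, r2)
  }
  out$is_mapped <- TRUE
  out$is_secondary <- FALSE
  out$is_duplicate <- FALSE
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Write simulated reads as FASTQ
#'
#' Sequences are taken from the reference at the read's ground-truth
#' coordinates; mate-2 reads are reverse-complemented (inward-facing pair).
#' Every base gets the read's integer mean quality.
#'
#' @param reads An `alignment_set` from [emit_reads].
#' @param ref The [reference_set] the reads were drawn from.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  n <- nrow(reads)
  seqs <- character(n)
  for (ct in unique(reads$contig)) {
    i <- which(reads$contig == ct)
    v <- Biostrings::Views(ref$seq[[ct]], start = reads$start[i] + 1L,
                           width = reads$aligned_length[i])
    seqs[i] <- as.character(v)
  }
  rev <- bitwAnd(reads$flags, 16L) != 0L
  if (any(rev)) {
    seqs[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
  }
  q <- as.integer(round(reads$mean_qual))
  quals <- vapply(seq_len(n), function(i) {
    strrep(rawToChar(as.raw(q[i] + 33L)), reads$aligned_length[i])
  }, character(1))
  mate <- if ("mate" %in% names(reads)) reads$mate else rep(1L, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@r", sprintf("%06d", seq_len(n)), "/", mate, "\n",
                    seqs, "\n+\n", quals), con)
  invisible(path)
}

#' Emulate a qPCR run from known true quantities
#'
#' Generates replicate Cq values from the log-linear model
#' `Cq = intercept + slope * log10(quantity) + Normal(0, noise_sd)` together
#' with a noiseless five-fold dilution standard series from the same curve,
#' enabling full quantify-filter-average-normalize round trips against known
#' truth. A locus with true quantity 0 yields no-amplification records
#' (Cq = NA), the encoding also used for the per-locus no-template controls.
#'
#' @param true_quantities Named numeric vector of per-locus true quantities.
#' @param slope,intercept Standard-curve parameters (default slope
#'   `-log2(10)`, i.e. 100% efficiency; intercept 38 cycles at quantity 1).
#' @param noise_sd Cq noise standard deviation in cycles.
#' @param replicates Replicates per locus (default 2, the usual duplicate).
#' @param rng_seed Integer seed (mandatory).
#' @param sample_id Sample label for the measurement rows.
#' @param standard_quantities Quantities of the dilution series (default a
#'   five-fold series from 75125 down to ~5 genome equivalents).
#' @param ntc_quantity True background quantity of the no-template controls
#'   (default 0 = no amplification).
#' @return A `qpcr_run`: list with `measurements` (columns `locus_id`,
#'   `sample_id`, `replicate`, `cq`, `is_ntc`) and `standards` (`quantity`,
#'   `cq`).
#' @export
emulate_qpcr <- function(true_quantities, slope = -log2(10), intercept = 38,
                         noise_sd = 0.2, replicates = 2L, rng_seed,
                         sample_id = "sample1",
                         standard_quantities = 75125 / 5^(0:6),
                         ntc_quantity = 0) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (is.null(names(true_quantities))) {
    stop("true_quantities must be named by locus id")
  }
  if (any(true_quantities < 0)) stop("quantities must be >= 0")
  set.seed(rng_seed)
  cq_of <- function(q) intercept + slope * log10(q)
  loci <- names(true_quantities)
  rows <- list()
  for (i in seq_along(loci)) {
    q <- true_quantities[[i]]
    for (r in seq_len(replicates)) {
      cq <- if (q > 0) cq_of(q) + stats::rnorm(1, 0, noise_sd) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci[i], sample_id = sample_id, replicate = r,
        cq = cq, is_ntc = FALSE, stringsAsFactors = FALSE)
    }
    ntc_cq <- if (ntc_quantity > 0) {
      cq_of(ntc_quantity) + stats::rnorm(1, 0, noise_sd)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = loci[i], sample_id = "NTC", replicate = 1L,
      cq = ntc_cq, is_ntc = TRUE, stringsAsFactors = FALSE)
  }
  structure(
    list(measurements = do.call(rbind, rows),
         standards = data.frame(quantity = standard_quantities,
                                cq = cq_of(standard_quantities))),
    class = "qpcr_run"
  )
}

#' Convert a DNA mass to haploid genome equivalents
#'
#' `copies = mass / (genome_length * mass_per_bp)` with the average mass of
#' one base pair `650 / 6.0221e23` grams (650 g/mol per bp over Avogadro's
#' number; 660 g/mol is an equally common convention and can be supplied).
#'
#' @param mass DNA mass in grams.
#' @param genome_length Haploid genome length in base pairs.
#' @param mass_per_bp Mass of one base pair in grams.
#' @return Number of haploid genome copies.
#' @examples
#' genome_equivalents(170e-15, 32e6)  # ~4.9, i.e. 5 genome equivalents
#' @export
genome_equivalents <- function(mass, genome_length,
                               mass_per_bp = 650 / 6.0221e23) {
  if (any(mass <= 0) || any(genome_length <= 0) || mass_per_bp <= 0) {
    stop("all inputs must be positive")
  }
  mass / (genome_length * mass_per_bp)
}
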