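test_that("SAM, BAM-style and TSV dialects load with correct spans", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:500",
    paste("r1", 0, "chr1", 101, 60, "10M1I10M", "*", 0, 0,
          strrep("A", 21), strrep("I", 21), sep = "\t"),
    paste("r2", 4, "chr1", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r3", 1024, "chr1", 11, 60, "20M", "*", 0, 0,
          strrep("A", 20), strrep("5", 20), sep = "\t")
  ), sam)
  aln <- load_alignments(sam, "sam")
  expect_equal(nrow(aln), 3L)
  expect_equal(aln$aligned_length[1], 20L)  # 10M1I10M consumes 20 ref bases
  expect_equal(aln$start[1], 100L)          # 1-based 101 -> 0-based 100
  expect_equal(aln$mean_qual[1], 40)        # 'I' = Q40
  expect_false(aln$is_mapped[2])
  expect_true(aln$is_duplicate[3])
  expect_equal(nrow(usable_alignments(aln)), 1L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tstart0\taligned_length\tmapq\tmean_qual\tflags",
               "chr1\t100\t101\t60\t35.0\t0"), tsv)
  a2 <- load_alignments(tsv, "tsv")
  expect_equal(a2$start, 100L)
  expect_equal(a2$aligned_length, 101L)

  writeLines(c("contig\tstart0\taligned_length\tmapq\tmean_qual\tflags",
               "chr1\t-5\t101\t60\t35.0\t0",
               "chr1\t10\t50\t60\t35.0\t0"), tsv)
  expect_warning(a3 <- load_alignments(tsv, "tsv"), "skipped 1")
  expect_equal(nrow(a3), 1L)
  writeLines(c("contig\tstart0\taligned_length\tmapq\tmean_qual\tflags",
               "chr1\t-5\t101\t60\t35.0\t0"), tsv)
  expect_error(load_alignments(tsv, "tsv"), "malformed")
})

test_that("SAM and TSV representations of simulated reads give identical curves", {
  ref <- generate_component("c", 20000, 0.5, rng_seed = 31)
  pool <- fragment_genome(ref, 4000, rng_seed = 32)
  reads <- emit_reads(size_select(pool, 180, 40),
                      sim_config(rng_seed = 33, n_reads = 4000))
  sam <- tempfile(fileext = ".sam")
  tsv <- tempfile(fileext = ".tsv")
  write_sam(reads, ref, sam)
  write_alignments_tsv(reads, tsv)
  a_sam <- load_alignments(sam)
  a_tsv <- load_alignments(tsv)
  w <- window_gc(ref, 50, 50)
  c_sam <- bias_curve(assign_reads_to_windows(a_sam, w), w)
  c_tsv <- bias_curve(assign_reads_to_windows(a_tsv, w), w)
  expect_identical(c_sam$relative_value, c_tsv$relative_value)
  expect_identical(c_sam$observed_reads, c_tsv$observed_reads)
  # quality statistics survive the SAM round trip exactly too
  expect_equal(sort(a_sam$mean_qual), sort(reads$mean_qual))
})

test_that("midpoint assignment matches the brute-force rule", {
  ref <- reference_set(c(chr1 = strrep("ACGT", 250)))  # 1000 bases
  w <- window_gc(ref, 50, 50)
  # read [100, 201): span 101, midpoint base 150 -> window starting at 150
  one <- make_aln("chr1", 100L, 101L)
  counts <- assign_reads_to_windows(one, w)
  expect_equal(which(counts == 1L), which(w$start == 150L))
  # read entirely inside one window stays there
  inside <- make_aln("chr1", 210L, 30L)
  expect_equal(which(assign_reads_to_windows(inside, w) == 1L),
               which(w$start == 200L))
  # even span: tie to the left window
  even <- make_aln("chr1", 75L, 50L)  # bases 75..124, midpoint base 99
  expect_equal(which(assign_reads_to_windows(even, w) == 1L),
               which(w$start == 50L))

  set.seed(55)
  n <- 10000
  starts <- sample(0:(1000 - 101), n, replace = TRUE)
  aln <- make_aln("chr1", starts, 101L)
  counts <- assign_reads_to_windows(aln, w)
  mid <- starts + 50L
  brute <- tabulate(mid %/% 50L + 1L, nbins = nrow(w))
  expect_equal(as.integer(counts), brute)
  expect_equal(attr(counts, "n_used"), n)

  expect_error(assign_reads_to_windows(make_aln("chrX", 0L, 10L), w), "chrX")
})

test_that("bias curve implements the observed/expected anchor normalization", {
  # hand-built window table: 5 windows at 20%, 10 at 50%, 5 at 80%
  ref <- reference_set(c(x = strrep("A", 1000)))
  w <- window_gc(ref, 50, 50)
  w$gc_count <- rep(c(10L, 25L, 40L), c(5L, 10L, 5L))
  w$gc_percent <- 100 * w$gc_count / 50
  h <- gc_histogram(w)
  counts <- rep(c(5L, 10L, 2L), c(5L, 10L, 5L))  # 25, 100, 10 reads
  cv <- bias_curve(counts, w, h, anchor = 50)
  expect_equal(cv$relative_value[match(c(20, 50, 80), cv$bin_percent)],
               c(0.5, 1.0, 0.2))
  # anchor mean is exactly 1 whatever the anchor set
  cv3 <- bias_curve(counts, w, h, anchor = c(20, 50, 80))
  expect_equal(mean(cv3$relative_value[match(c(20, 50, 80),
                                             cv3$bin_percent)]), 1)
  # zero-read bins are reported as 0, not dropped
  counts2 <- rep(c(0L, 10L, 0L), c(5L, 10L, 5L))
  cv2 <- bias_curve(counts2, w, h, anchor = 50)
  expect_equal(cv2$relative_value[cv2$bin_percent == 80], 0)
  expect_error(bias_curve(rep(0L, 20), w, h, anchor = 50), "anchor undefined")
  expect_error(bias_curve(counts, w, h, anchor = 48), "anchor undefined")
})

test_that("per-base coverage counts overlapping reads and excludes masked bases", {
  ref <- reference_set(c(x = strrep("ACGTA", 2)))
  prof <- per_base_coverage(make_aln("x", 0L, 10L), ref)
  expect_equal(as.integer(prof$coverage$x), rep(1L, 10))
  expect_equal(prof$genome_mean, 1)

  two <- make_aln("x", c(0L, 4L), c(6L, 6L))
  prof2 <- per_base_coverage(two, ref)
  expect_equal(as.integer(prof2$coverage$x),
               c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L))

  # masked bases are excluded from the mean
  refN <- reference_set(c(x = paste0(strrep("A", 5), strrep("N", 5))))
  profN <- per_base_coverage(make_aln("x", 0L, 10L), refN)
  expect_equal(profN$n_unmasked, 5L)
  expect_equal(profN$genome_mean, 1)

  set.seed(77)
  L <- 2000L
  refL <- reference_set(c(x = random_dna(L)))
  starts <- sample(0:(L - 80), 100, replace = TRUE)
  lens <- sample(40:80, 100, replace = TRUE)
  prof3 <- per_base_coverage(make_aln("x", starts, lens), refL)
  brute <- integer(L)
  for (k in 1:100) brute[(starts[k] + 1):(starts[k] + lens[k])] <-
      brute[(starts[k] + 1):(starts[k] + lens[k])] + 1L
  expect_equal(as.integer(prof3$coverage$x), brute)
})

test_that("under-coverage fraction uses a strict threshold on unmasked bases", {
  ref <- reference_set(c(x = strrep("A", 100)))
  unif <- make_aln("x", rep(0L, 10), 100L)
  expect_equal(under_coverage_fraction(per_base_coverage(unif, ref)), 0)

  # bases 0-79 at 10x, 80-99 at 0x: mean 8, threshold 0.8, fraction 0.20
  part <- make_aln("x", rep(0L, 10), 80L)
  expect_equal(under_coverage_fraction(per_base_coverage(part, ref)), 0.20)

  # every base exactly at the threshold: strict "<" keeps the fraction at 0
  ref10 <- reference_set(c(x = strrep("A", 10)))
  at_thr <- make_aln("x", rep(0L, 10), 10L)
  expect_equal(under_coverage_fraction(per_base_coverage(at_thr, ref10), 1.0),
               0)
  empty <- usable_alignments(make_aln("x", 0L, 10L, flags = 4L))
  expect_error(
    under_coverage_fraction(per_base_coverage(empty, ref10)), "no coverage")
})

test_that("locus representation relative to the genome mean, per locus and pooled", {
  ref <- reference_set(c(x = strrep("A", 100)))
  unif <- make_aln("x", rep(0L, 4), 100L)
  prof <- per_base_coverage(unif, ref)
  loci <- data.frame(contig = "x", start = c(10L, 60L), end = c(30L, 80L))
  lr <- locus_representation(prof, loci)
  expect_equal(lr$relative_value, c(1, 1))

  # one locus at 2x, one at 6x the genome mean, equal lengths -> pooled 2x...
  # coverage: genome mean from 100 bases
  aln <- make_aln("x", c(rep(0L, 2), rep(50L, 6)), 50L)
  prof2 <- per_base_coverage(aln, ref)  # mean = (2*50+6*50)/100 = 4
  loci2 <- data.frame(contig = "x", start = c(0L, 50L), end = c(50L, 100L))
  lr2 <- locus_representation(prof2, loci2)
  expect_equal(lr2$relative_value, c(0.5, 1.5))
  expect_equal(locus_representation(prof2, loci2, "pooled"), 1)
  # pooled value of equal-length loci at 1x and 3x of the mean is 2x
  loci3 <- data.frame(contig = "x", start = c(0L, 50L), end = c(25L, 75L))
  aln3 <- make_aln("x", c(rep(0L, 25), rep(50L, 75)), 25L)
  prof3 <- per_base_coverage(aln3, ref)  # mean 25; locus1 25x, locus2 75x
  expect_equal(locus_representation(prof3, loci3, "pooled"), 2)
  expect_error(locus_representation(prof3,
    data.frame(contig = "x", start = 5L, end = 5L)), "empty locus")
})

test_that("quality masking flags bins by mean of per-read mean qualities", {
  ref <- reference_set(c(x = strrep("ACGT", 500)))
  w <- window_gc(ref, 50, 50)
  h <- gc_histogram(w)  # all windows at 50% GC
  aln <- make_aln("x", seq(0L, 1900L, by = 100L), 50L, mean_qual = 35)
  cv <- bias_curve(assign_reads_to_windows(aln, w), w, h, anchor = 50)
  masked <- quality_mask(aln, w, cv)
  expect_false(any(masked$masked))
  expect_equal(masked$mean_read_quality, 35)

  # all reads at Q19.9: below the Q20 boundary -> masked
  low <- make_aln("x", seq(0L, 1900L, by = 100L), 50L, mean_qual = 19.9)
  cvl <- quality_mask(low, w, bias_curve(assign_reads_to_windows(low, w),
                                         w, h, anchor = 50))
  expect_true(all(cvl$masked))
  expect_match(cvl$mask_reason[1], "Q20")

  # mixed qualities across two GC bins match a brute-force per-bin mean
  refm <- reference_set(c(x = paste0(strrep("AT", 500), strrep("GC", 500))))
  wm <- window_gc(refm, 50, 50)
  set.seed(3)
  starts <- c(sample(0:950, 40, TRUE), sample(1000:1950, 40, TRUE))
  quals <- round(c(rnorm(40, 30, 4), rnorm(40, 18, 2)))
  alnm <- make_aln("x", starts, 50L, mean_qual = quals)
  cvm <- bias_curve(assign_reads_to_windows(alnm, wm), wm,
                    anchor = c(0, 100))
  mm <- quality_mask(alnm, wm, cvm)
  in_low <- (starts + 24L) %/% 50L < 20L
  expect_equal(mm$mean_read_quality[mm$bin_percent == 0],
               mean(quals[in_low]))
  expect_equal(mm$mean_read_quality[mm$bin_percent == 100],
               mean(quals[!in_low]))
  expect_equal(mm$masked[mm$bin_percent == 100],
               mean(quals[!in_low]) < 20)
})

test_that("fold change divides curves bin-wise with mask propagation", {
  ref <- reference_set(c(x = strrep("A", 1000)))
  w <- window_gc(ref, 50, 50)
  w$gc_count <- rep(c(25L, 40L), each = 10L)
  w$gc_percent <- 100 * w$gc_count / 50
  h <- gc_histogram(w)
  a <- bias_curve(rep(c(10L, 5L), each = 10L), w, h, anchor = 50)
  b <- bias_curve(rep(c(20L, 5L), each = 10L), w, h, anchor = 50)
  self <- fold_change(a, a)
  expect_true(all(self$ratio == 1))
  fc <- fold_change(a, b)
  expect_equal(fc$ratio[fc$bin_percent == 50], 1)
  expect_equal(fc$ratio[fc$bin_percent == 80], 2)
  # a zero denominator is flagged undefined, not an Inf
  bz <- bias_curve(rep(c(20L, 0L), each = 10L), w, h, anchor = 50)
  fz <- fold_change(a, bz)
  expect_true(fz$undefined[fz$bin_percent == 80])
  expect_true(is.na(fz$ratio[fz$bin_percent == 80]))
})

test_that("pooling concatenates reads before binning", {
  ref <- reference_set(c(x = strrep("A", 1000)))
  w <- window_gc(ref, 50, 50)
  w$gc_count <- rep(c(10L, 25L), each = 10L)
  w$gc_percent <- 100 * w$gc_count / 50
  h <- gc_histogram(w)
  mk <- function(n20, n50) {
    make_aln("x", c(sample(0:450, n20, TRUE), sample(500:950, n50, TRUE)), 50L)
  }
  set.seed(8)
  s1 <- mk(20, 100)   # bin 20%: 20/10 windows vs anchor 100/10 -> 0.2
  s2 <- mk(100, 100)  # bin 20%: 1.0
  c1 <- bias_curve(assign_reads_to_windows(s1, w), w, h, anchor = 50)
  expect_equal(c1$relative_value[c1$bin_percent == 20], 0.2)
  pooled_self <- pool_curves(list(s1, s1), w, h, anchor = 50)
  expect_equal(pooled_self$relative_value, c1$relative_value)
  pooled <- pool_curves(list(s1, s2), w, h, anchor = 50)
  # count-level arithmetic: (20+100)/(100+100) relative to anchor = 0.6
  expect_equal(pooled$relative_value[pooled$bin_percent == 20], 0.6)
  # pooled curve lies between the inputs bin-wise at equal anchor coverage
  c2 <- bias_curve(assign_reads_to_windows(s2, w), w, h, anchor = 50)
  lo <- pmin(c1$relative_value, c2$relative_value)
  hi <- pmax(c1$relative_value, c2$relative_value)
  expect_true(all(pooled$relative_value >= lo - 1e-12 &
                    pooled$relative_value <= hi + 1e-12))
  expect_error(pool_curves(list(s1, make_aln("y", 0L, 10L)), w, h, 50),
               "different reference")
})

test_that("uniform reads over an ambiguity-free reference give a flat curve", {
  ref <- generate_component("u", 60000, 0.5, gc_block_sd = 0.06,
                            rng_seed = 202)
  w <- window_gc(ref, 50, 50)
  h <- gc_histogram(w)
  set.seed(203)
  n <- 120000
  starts <- sample(0:(60000 - 101), n, replace = TRUE)
  aln <- make_aln("u", starts, 101L)
  cv <- bias_curve(assign_reads_to_windows(aln, w), w, h)
  m <- merge(as.data.frame(cv), as.data.frame(h),
             by.x = "bin_percent", by.y = "bin_percent")
  expected <- n * m$count / sum(h$count)
  big <- expected >= 200
  expect_gt(sum(big), 5)
  expect_true(all(abs(cv$relative_value[match(m$bin_percent[big],
                                              cv$bin_percent)] - 1) <=
                    3 / sqrt(expected[big])))
})
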