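#' Write a data frame as TSV with '#' metadata header lines
#'
#' All tabular outputs of the package share this layout: optional
#' `# key: value` provenance lines (tool version, seed, parameters), then a
#' header line, then tab-separated rows.
#'
#' @param d Data frame.
#' @param path Output path.
#' @param meta Optional named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_with_meta <- function(d, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gcbias %s",
                     as.character(utils::packageVersion("gcbias"))), con)
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = " "),
                              character(1))), con)
  }
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a bias curve as TSV
#' @param curve A `bias_curve`.
#' @param path File path.
#' @param meta Optional metadata list for the header.
#' @return `write_bias_curve`: `path` invisibly; `read_bias_curve`: a
#'   `bias_curve`.
#' @export
write_bias_curve <- function(curve, path, meta = NULL) {
  meta <- c(list(anchor = paste(attr(curve, "anchor"), collapse = ",")), meta)
  write_tsv_with_meta(as.data.frame(curve), path, meta)
}

#' @rdname write_bias_curve
#' @export
read_bias_curve <- function(path) {
  d <- read_tsv_plain(path)
  need <- c("bin_percent", "observed_reads", "expected_windows",
            "relative_value", "masked")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("not a bias-curve TSV (missing ",
                         paste(miss, collapse = ", "), "): ", path)
  anchor <- c(48, 50, 52)
  hdr <- grep("^# anchor:", readLines(path, n = 20), value = TRUE)
  if (length(hdr)) {
    anchor <- as.numeric(strsplit(sub("^# anchor:\\s*", "", hdr[1]), ",")[[1]])
  }
  if (!"mask_reason" %in% names(d)) d$mask_reason <- NA_character_
  attr(d, "anchor") <- anchor
  attr(d, "n_reads") <- sum(d$observed_reads)
  class(d) <- c("bias_curve", "data.frame")
  d
}

#' Read a locus panel from BED (with optional TSV sidecar)
#'
#' BED is read as 0-based half-open (BED3 or BED6; the name column becomes
#' the locus id). A sidecar TSV with columns `id`, `gc_percent` and
#' optionally `class`/`role` supplies panel annotations; without one,
#' `gc_percent` is computed from the reference when given.
#'
#' @param bed_path BED file path.
#' @param sidecar_path Optional annotation TSV path.
#' @param ref Optional [reference_set] used to compute `gc_percent` when no
#'   sidecar provides it.
#' @return Data frame `id`, `contig`, `start`, `end`, plus annotations.
#' @export
read_panel <- function(bed_path, sidecar_path = NULL, ref = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (length(gr) == 0L) stop("empty BED file: ", bed_path)
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  out$id <- if (!is.null(nm) && !anyNA(nm)) {
    as.character(nm)
  } else {
    sprintf("locus%03d", seq_len(nrow(out)))
  }
  out <- out[, c("id", "contig", "start", "end")]
  if (!is.null(sidecar_path)) {
    sc <- read_tsv_plain(sidecar_path)
    if (!"id" %in% names(sc)) stop("panel sidecar needs an 'id' column")
    out <- merge(out, sc, by = "id", sort = FALSE)
  }
  if (!"gc_percent" %in% names(out)) {
    if (is.null(ref)) {
      stop("no gc_percent in sidecar and no reference supplied")
    }
    out$gc_percent <- vapply(seq_len(nrow(out)), function(i) {
      v <- Biostrings::subseq(ref$seq[[out$contig[i]]],
                              start = out$start[i] + 1L, end = out$end[i])
      100 * as.numeric(Biostrings::letterFrequency(v, "GC")) /
        (out$end[i] - out$start[i])
    }, numeric(1))
  }
  out
}

#' Read a qPCR run from measurement and standards TSVs
#'
#' Measurements: columns `locus_id`, `sample_id`, `replicate`, `cq`,
#' `is_ntc` (empty `cq` = no amplification). Standards: columns `quantity`,
#' `cq`.
#'
#' @param measurements_path,standards_path TSV paths.
#' @return A `qpcr_run` list as produced by [emulate_qpcr].
#' @export
read_qpcr_run <- function(measurements_path, standards_path) {
  meas <- read_tsv_plain(measurements_path)
  need <- c("locus_id", "sample_id", "replicate", "cq", "is_ntc")
  miss <- setdiff(need, names(meas))
  if (length(miss)) stop("measurement TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  meas$is_ntc <- as.logical(meas$is_ntc)
  std <- read_tsv_plain(standards_path)
  if (!all(c("quantity", "cq") %in% names(std))) {
    stop("standards TSV needs columns 'quantity' and 'cq'")
  }
  structure(list(measurements = meas, standards = std), class = "qpcr_run")
}

#' Write a qPCR run to a pair of TSV files
#' @param run A `qpcr_run`.
#' @param measurements_path,standards_path Output paths.
#' @param meta Optional metadata for the headers.
#' @return Invisibly, the two paths.
#' @export
write_qpcr_run <- function(run, measurements_path, standards_path,
                           meta = NULL) {
  write_tsv_with_meta(run$measurements, measurements_path, meta)
  write_tsv_with_meta(run$standards, standards_path, meta)
  invisible(c(measurements_path, standards_path))
}
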