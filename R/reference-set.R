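#' Reference sequence sets
#'
#' A `reference_set` bundles a [Biostrings::DNAStringSet] with a per-base
#' ambiguity mask (TRUE wherever the base is not one of A, C, G, T). All
#' windowing, coverage and simulation functions in the package take one of
#' these as the reference. Coordinates are 0-based, half-open throughout the
#' package; conversions to and from 1-based formats (SAM, FASTA substring
#' arithmetic) happen at the boundary.
#'
#' @param sequences A named character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet]. Lowercase letters are folded to uppercase.
#' @return An object of class `reference_set` with elements `seq`
#'   (DNAStringSet), `mask` (list of per-base logical vectors, TRUE =
#'   ambiguous), and `total_length`.
#' @examples
#' ref <- reference_set(c(a = "ACGT", b = "NNNN"))
#' ref$total_length
#' @export
reference_set <- function(sequences) {
  if (is.character(sequences)) {
    if (length(sequences) == 0L) stop("no sequences supplied")
    nm <- names(sequences)
    if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
    sequences <- toupper(sequences)
    bad <- !grepl("^[ACGTRYSWKMBDHVN]*$", sequences)
    if (any(bad)) {
      stop("non-IUPAC characters in record(s): ",
           paste(nm[bad], collapse = ", "))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
    names(sequences) <- nm
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    stop("'sequences' must be a named character vector or DNAStringSet")
  }
  nm <- names(sequences)
  if (is.null(nm)) stop("sequences must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate contig names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  mask <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    if (length(s) == 0L) return(logical(0))
    acgt <- Biostrings::letterFrequencyInSlidingView(s, 1L, "ACGT")[, 1L]
    acgt == 0L
  })
  names(mask) <- nm
  structure(
    list(seq = sequences, mask = mask,
         total_length = sum(Biostrings::width(sequences))),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$seq), "contig(s),",
      x$total_length, "bases\n")
  w <- Biostrings::width(x$seq)
  n_amb <- vapply(x$mask, sum, integer(1))
  for (i in seq_along(x$seq)) {
    cat(sprintf("  %s: %d bp (%d ambiguous)\n", names(x$seq)[i], w[i], n_amb[i]))
  }
  invisible(x)
}

#' Lengths of the contigs in a reference set
#' @param ref A `reference_set`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(ref) {
  stopifnot(inherits(ref, "reference_set"))
  stats::setNames(Biostrings::width(ref$seq), names(ref$seq))
}

#' Read a FASTA file into a reference set
#'
#' Wraps [Biostrings::readDNAStringSet]; record descriptions are truncated at
#' the first whitespace to give contig names, lowercase is folded to
#' uppercase, and every non-ACGT base is flagged in the ambiguity mask.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return A [reference_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_set(Biostrings::DNAStringSet(toupper(seqs)))
}

#' Write a reference set to FASTA
#' @param ref A `reference_set`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "reference_set"))
  Biostrings::writeXStringSet(ref$seq, path, width = width)
  invisible(path)
}

#' Concatenate reference sets into a composite reference
#'
#' Mirrors the construction of a composite test genome by pooling the
#' reference sequences of several component organisms: every contig of every
#' component is retained (contigs are not physically joined), and the
#' composite total length is the sum of the component lengths.
#'
#' @param components A list of `reference_set` objects.
#' @param prefixes Optional character vector (one per component) used to
#'   disambiguate contig names as `<prefix>_<contig>`. When `NULL`, original
#'   names are kept and any collision is an error.
#' @return A [reference_set] containing all contigs.
#' @export
build_composite <- function(components, prefixes = NULL) {
  if (length(components) < 1L) stop("at least one component required")
  stopifnot(all(vapply(components, inherits, logical(1), "reference_set")))
  if (!is.null(prefixes) && length(prefixes) != length(components)) {
    stop("'prefixes' must have one entry per component")
  }
  seqs <- list()
  for (i in seq_along(components)) {
    s <- components[[i]]$seq
    if (!is.null(prefixes)) names(s) <- paste(prefixes[i], names(s), sep = "_")
    seqs[[i]] <- s
  }
  all_seq <- do.call(c, seqs)
  if (anyDuplicated(names(all_seq))) {
    stop("contig name collision across components (",
         paste(unique(names(all_seq)[duplicated(names(all_seq))]),
               collapse = ", "),
         "); supply 'prefixes'")
  }
  reference_set(all_seq)
}
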