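#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(quantity) over a dilution series
#' (classically five-fold). The amplification efficiency follows from the
#' slope as `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' `-log2(10) = -3.32193` and efficiency 1.
#'
#' @param standards Data frame with columns `quantity` (> 0, in genome
#'   equivalents or any consistent unit) and `cq`.
#' @return A `standard_curve`: list with `slope`, `intercept` (Cq at
#'   quantity 1), `efficiency` (fraction), `r_squared`, `n`.
#' @export
fit_standard_curve <- function(standards) {
  if (!all(c("quantity", "cq") %in% names(standards))) {
    stop("'standards' needs columns 'quantity' and 'cq'")
  }
  q <- standards$quantity
  cq <- standards$cq
  if (any(q <= 0)) stop("standard quantities must be > 0")
  if (length(unique(q)) < 2L) stop("need at least two distinct quantities")
  fit <- stats::lm(cq ~ log10(q))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    warning("standard-curve slope is non-negative; Cq should fall as ",
            "quantity rises")
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         efficiency = 10^(-1 / slope) - 1,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n = length(q)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.4f, intercept %.3f, efficiency %.1f%%, R^2 %.4f (n=%d)\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' Absolute quantity from a Cq value
#'
#' Inverts the fitted log-linear standard curve:
#' `quantity = 10^((Cq - intercept) / slope)`.
#'
#' @param curve A `standard_curve`.
#' @param cq Cq value(s) in cycles.
#' @return Quantity in the standards' unit.
#' @export
quantify <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Background (no-template) filter for qPCR quantities
#'
#' A measurement is kept only if its quantity exceeds `factor` times the
#' no-template-control quantity; values equal to or less than that multiple
#' of background are omitted. The filter is applied per replicate on the
#' quantity scale. An NTC that never amplified is encoded as quantity 0, so
#' every positive measurement is kept.
#'
#' @param sample_quantity Quantity of the measurement(s).
#' @param ntc_quantity Quantity of the matched no-template control.
#' @param factor Background multiple (default 3).
#' @return Logical: TRUE = keep.
#' @export
background_filter <- function(sample_quantity, ntc_quantity, factor = 3) {
  if (any(sample_quantity < 0) || any(ntc_quantity < 0)) {
    stop("quantities must be non-negative")
  }
  sample_quantity > factor * ntc_quantity
}

#' Average surviving replicate quantities
#'
#' Arithmetic mean of the replicates that survived the background filter,
#' with the min/max range retained for error bars.
#'
#' @param quantities Numeric vector of surviving replicate quantities.
#' @return List `mean`, `range_low`, `range_high`, `n`.
#' @export
average_duplicates <- function(quantities) {
  if (length(quantities) == 0L) stop("all replicates omitted")
  list(mean = mean(quantities),
       range_low = min(quantities),
       range_high = max(quantities),
       n = length(quantities))
}

#' Normalize per-locus quantities to mid-GC anchor (or control) loci
#'
#' Each locus quantity is divided by the mean quantity of the anchor loci.
#' By default the anchors are the two panel loci whose GC content is nearest
#' 50% (all tied loci enter the mean if several tie); alternatively, loci
#' with `role == "control"` in the panel are used, the convention for panels
#' on genomes where mid-GC loci are not natural references.
#'
#' @param quantities Named numeric vector of mean quantities per locus id
#'   (NA for omitted loci).
#' @param panel Data frame with columns `id`, `gc_percent` and optionally
#'   `role` (`"test"`, `"anchor"`, `"control"`).
#' @return Data frame `locus_id`, `gc_percent`, `mean_quantity`,
#'   `relative_value`, `is_anchor`.
#' @export
normalize_panel <- function(quantities, panel) {
  if (!all(c("id", "gc_percent") %in% names(panel))) {
    stop("'panel' needs columns 'id' and 'gc_percent'")
  }
  m <- match(panel$id, names(quantities))
  q <- as.numeric(quantities)[m]
  anchor_ids <- character(0)
  if ("role" %in% names(panel) && any(panel$role == "control", na.rm = TRUE)) {
    anchor_ids <- panel$id[which(panel$role == "control")]
  } else {
    d <- abs(panel$gc_percent - 50)
    dmin <- sort(unique(d))
    sel <- which(d == dmin[1])
    if (length(sel) < 2L && length(dmin) > 1L) {
      sel <- c(sel, which(d == dmin[2]))
    }
    anchor_ids <- panel$id[sel]
  }
  aq <- q[panel$id %in% anchor_ids]
  if (length(aq) == 0L || all(is.na(aq))) {
    stop("normalization undefined: all anchor loci omitted")
  }
  denom <- mean(aq, na.rm = TRUE)
  if (denom <= 0) stop("normalization undefined: anchor mean not positive")
  data.frame(locus_id = panel$id,
             gc_percent = panel$gc_percent,
             mean_quantity = q,
             relative_value = q / denom,
             is_anchor = panel$id %in% anchor_ids,
             stringsAsFactors = FALSE)
}

#' Run the full qPCR quantification pipeline on a measurement table
#'
#' Fixed processing order: fit the standard curve, convert every replicate Cq
#' to a quantity, filter each replicate against `factor` times its locus's
#' no-template-control quantity, average the surviving replicates, then
#' normalize to the anchor loci. Loci whose replicates are all filtered out
#' are flagged `omitted` with a reason and carry NA values.
#'
#' @param run A `qpcr_run` (list with `measurements`: columns `locus_id`,
#'   `sample_id`, `replicate`, `cq`, `is_ntc`; and `standards`: columns
#'   `quantity`, `cq`), e.g. from [emulate_qpcr] or [read_qpcr_run].
#' @param panel Panel data frame (`id`, `gc_percent`, optional `role`).
#' @param sample Sample id to process (default: the only / first sample).
#' @param factor Background multiple for [background_filter].
#' @return A `relative_abundance` data frame with columns `locus_id`,
#'   `gc_percent`, `n_replicates`, `mean_quantity`, `range_low`,
#'   `range_high`, `relative_value`, `is_anchor`, `omitted`, `omit_reason`;
#'   attribute `standard_curve`.
#' @export
process_qpcr_run <- function(run, panel, sample = NULL, factor = 3) {
  meas <- run$measurements
  curve <- fit_standard_curve(run$standards)
  if (is.null(sample)) sample <- meas$sample_id[!meas$is_ntc][1]
  meas <- meas[meas$sample_id == sample | meas$is_ntc, , drop = FALSE]
  if (nrow(meas) == 0L) stop("no measurements for sample '", sample, "'")

  qty <- ifelse(is.na(meas$cq), 0, quantify(curve, meas$cq))
  res <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    id <- panel$id[i]
    ntc_q <- qty[meas$locus_id == id & meas$is_ntc]
    ntc_q <- if (length(ntc_q)) mean(ntc_q) else 0
    rep_q <- qty[meas$locus_id == id & !meas$is_ntc]
    n_total <- length(rep_q)
    keep <- rep_q[background_filter(rep_q, ntc_q, factor)]
    if (n_total == 0L) {
      res[[i]] <- list(n = 0L, mean = NA_real_, lo = NA_real_, hi = NA_real_,
                       omitted = TRUE, reason = "not measured")
    } else if (length(keep) == 0L) {
      res[[i]] <- list(n = 0L, mean = NA_real_, lo = NA_real_, hi = NA_real_,
                       omitted = TRUE,
                       reason = sprintf("all %d replicate(s) <= %gx background",
                                        n_total, factor))
    } else {
      av <- average_duplicates(keep)
      res[[i]] <- list(n = av$n, mean = av$mean, lo = av$range_low,
                       hi = av$range_high, omitted = FALSE,
                       reason = if (av$n < n_total) "single replicate" else
                         NA_character_)
    }
  }
  means <- stats::setNames(vapply(res, `[[`, numeric(1), "mean"), panel$id)
  norm <- normalize_panel(means, panel)
  out <- data.frame(
    locus_id = panel$id,
    gc_percent = panel$gc_percent,
    n_replicates = vapply(res, `[[`, integer(1), "n"),
    mean_quantity = norm$mean_quantity,
    range_low = vapply(res, `[[`, numeric(1), "lo"),
    range_high = vapply(res, `[[`, numeric(1), "hi"),
    relative_value = norm$relative_value,
    is_anchor = norm$is_anchor,
    omitted = vapply(res, `[[`, logical(1), "omitted"),
    omit_reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  attr(out, "standard_curve") <- curve
  attr(out, "sample") <- sample
  class(out) <- c("relative_abundance", "data.frame")
  out
}

#' Plateau of a GC-bias profile
#'
#' The plateau is the maximal-length contiguous run of points, in percent-GC
#' order, containing at most `max_below` points with value strictly below
#' `floor` (default: at most one point below 0.7). Among equally long runs,
#' the one containing the point nearest 50% GC wins; remaining ties go to
#' the lower-GC run. Implemented as a linear two-pointer sweep.
#'
#' @param x A `relative_abundance` table, a `bias_curve`, or any data frame
#'   with a GC column (`gc_percent` or `bin_percent`) and `relative_value`.
#' @param floor Relative-abundance floor (default 0.7).
#' @param max_below Maximum number of below-floor points inside the run.
#' @param use_masked Include masked / omitted points (default FALSE).
#' @return List `gc_low`, `gc_high` (percent GC of the run's first and last
#'   points), `n_points`, `n_below`.
#' @export
plateau <- function(x, floor = 0.7, max_below = 1L, use_masked = FALSE) {
  gc_col <- intersect(c("gc_percent", "bin_percent"), names(x))[1]
  if (is.na(gc_col) || !"relative_value" %in% names(x)) {
    stop("input needs a GC column and 'relative_value'")
  }
  drop <- rep(FALSE, nrow(x))
  if (!use_masked) {
    if ("omitted" %in% names(x)) drop <- drop | x$omitted
    if ("masked" %in% names(x)) drop <- drop | x$masked
  }
  keep <- !drop & !is.na(x$relative_value)
  g <- x[[gc_col]][keep]
  v <- x$relative_value[keep]
  if (length(g) == 0L) stop("no usable points")
  o <- order(g)
  g <- g[o]; v <- v[o]
  below <- v < floor
  n <- length(g)
  # two-pointer sweep over all windows with <= max_below below-floor points
  best_len <- 0L
  cand <- list()
  lo <- 1L; n_bel <- 0L
  for (hi in seq_len(n)) {
    n_bel <- n_bel + below[hi]
    while (n_bel > max_below) {
      n_bel <- n_bel - below[lo]
      lo <- lo + 1L
    }
    len <- hi - lo + 1L
    if (len > best_len) {
      best_len <- len
      cand <- list(c(lo, hi, n_bel))
    } else if (len == best_len) {
      cand <- c(cand, list(c(lo, hi, n_bel)))
    }
  }
  if (best_len == 0L) {
    # every point below floor and no below-floor points allowed
    return(list(gc_low = NA_real_, gc_high = NA_real_, n_points = 0L,
                n_below = 0L))
  }
  # tie-break: run containing the point nearest 50% GC, then lowest GC
  pick <- cand[[1]]
  if (length(cand) > 1L) {
    score <- vapply(cand, function(cc) {
      min(abs(g[cc[1]:cc[2]] - 50))
    }, numeric(1))
    pick <- cand[[which.min(score)]]
  }
  list(gc_low = g[pick[1]], gc_high = g[pick[2]],
       n_points = pick[2] - pick[1] + 1L, n_below = as.integer(pick[3]))
}

#' Align relative-abundance tables from several samples
#'
#' Produces a wide per-locus comparison across samples (one column per
#' sample beside the locus metadata) with per-sample plateau annotations as
#' an attribute.
#'
#' @param tables Named list of `relative_abundance` tables over a shared
#'   panel.
#' @param floor,max_below Plateau parameters for the annotations.
#' @return Data frame `locus_id`, `gc_percent`, then one relative-value
#'   column per sample; attribute `plateaus` (named list).
#' @export
compare_samples <- function(tables, floor = 0.7, max_below = 1L) {
  if (length(tables) < 2L) stop("need at least two samples")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("'tables' must be a named list")
  }
  ids <- lapply(tables, function(t) t$locus_id)
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L) stop("samples share no panel loci")
  base <- tables[[1]][match(shared, tables[[1]]$locus_id), ]
  out <- data.frame(locus_id = shared, gc_percent = base$gc_percent,
                    stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    out[[nm]] <- t$relative_value[match(shared, t$locus_id)]
  }
  attr(out, "plateaus") <- lapply(tables, plateau, floor = floor,
                                  max_below = max_below)
  out
}
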