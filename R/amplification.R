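#' Per-cycle amplification-efficiency profile
#'
#' Parametric model of the probability that a library molecule is duplicated
#' in one PCR cycle as a function of its percent GC: a maximal efficiency
#' `p_max` multiplied by two logistic shoulders,
#' `p(g) = p_max * sigma((g - low_mid)/low_scale) *
#' sigma((high_mid - g)/high_scale)`, with `sigma` the standard logistic.
#' The AT-side shoulder suppresses amplification of very AT-rich fragments,
#' the GC-side shoulder that of GC-rich fragments; each shoulder can be
#' disabled by setting its scale to `NA` (the factor is then 1 everywhere).
#' This is the simplest shape with independently tunable shoulders; protocol
#' presets (see [protocol_preset]) are calibrated emulations of observed
#' protocol behavior, not mechanistic models of ramp rate, denaturation time
#' or additives.
#'
#' @param p_max Maximal per-cycle duplication probability, in `[0, 1]`.
#' @param low_mid,low_scale AT-side shoulder midpoint and width (percent GC).
#' @param high_mid,high_scale GC-side shoulder midpoint and width.
#' @param name Optional profile name.
#' @return An `efficiency_profile` object.
#' @export
efficiency_profile <- function(p_max, low_mid = NA, low_scale = NA,
                               high_mid = NA, high_scale = NA,
                               name = "custom") {
  if (p_max < 0 || p_max > 1) stop("p_max must be in [0, 1]")
  if (!is.na(low_scale) && low_scale <= 0) stop("low_scale must be > 0 or NA")
  if (!is.na(high_scale) && high_scale <= 0) stop("high_scale must be > 0 or NA")
  structure(list(p_max = p_max, low_mid = low_mid, low_scale = low_scale,
                 high_mid = high_mid, high_scale = high_scale,
                 preset_name = name),
            class = "efficiency_profile")
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat(sprintf("efficiency_profile '%s': p_max %.3f", x$preset_name, x$p_max))
  if (!is.na(x$low_scale)) {
    cat(sprintf(", AT shoulder (mid %.1f, scale %.2f)", x$low_mid, x$low_scale))
  }
  if (!is.na(x$high_scale)) {
    cat(sprintf(", GC shoulder (mid %.1f, scale %.2f)", x$high_mid, x$high_scale))
  }
  cat("\n")
  invisible(x)
}

# Named presets emulating the qualitative behavior of published library-PCR
# protocols: a fast-ramping standard Phusion HF protocol (severe GC-side
# shoulder, plateau ending in the mid-50s %GC), the same chemistry on slower
# ramps (shoulder pushed right), Phusion with long denaturation plus 2M
# betaine (GC side largely rescued at an AT-side cost), AccuPrime Taq HiFi
# with extension at 65C (broad plateau on both sides) or 60C (AT side
# relaxed further, slight GC-side cost), and a PCR-free profile with no GC
# dependence at all. Parameter values are calibrated fixtures, not
# measurements.
.presets <- list(
  "phusion-fast-ramp" = list(p_max = 0.95, low_mid = 5.3, low_scale = 2.23,
                             high_mid = 67, high_scale = 4.0),
  "phusion-slow-ramp" = list(p_max = 0.95, low_mid = 5.3, low_scale = 2.23,
                             high_mid = 90, high_scale = 5.0),
  "phusion-long-denat-betaine" = list(p_max = 0.95, low_mid = 7.6,
                                      low_scale = 6.0, high_mid = 104.5,
                                      high_scale = 5.5),
  "accuprime-65" = list(p_max = 0.95, low_mid = 8.2, low_scale = 1.35,
                        high_mid = 106, high_scale = 8.3),
  "accuprime-60" = list(p_max = 0.95, low_mid = 6.0, low_scale = 1.1,
                        high_mid = 98, high_scale = 8.0),
  "pcr-free" = list(p_max = 0.95, low_mid = NA, low_scale = NA,
                    high_mid = NA, high_scale = NA)
)

#' Named protocol presets
#'
#' @param name One of [preset_names()].
#' @return The corresponding [efficiency_profile].
#' @export
protocol_preset <- function(name) {
  if (!name %in% names(.presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  }
  p <- .presets[[name]]
  efficiency_profile(p$p_max, p$low_mid, p$low_scale, p$high_mid,
                     p$high_scale, name = name)
}

#' @rdname protocol_preset
#' @export
preset_names <- function() names(.presets)

#' Per-cycle duplication probability at a given GC content
#'
#' @param g Percent GC, in `[0, 100]`.
#' @param profile An [efficiency_profile].
#' @return Probability in `[0, p_max]`.
#' @export
efficiency <- function(g, profile) {
  stopifnot(inherits(profile, "efficiency_profile"))
  if (any(g < 0 | g > 100)) stop("percent GC must be in [0, 100]")
  p <- rep(profile$p_max, length(g))
  if (!is.na(profile$low_scale)) {
    p <- p * stats::plogis((g - profile$low_mid) / profile$low_scale)
  }
  if (!is.na(profile$high_scale)) {
    p <- p * stats::plogis((profile$high_mid - g) / profile$high_scale)
  }
  p
}

#' Expected fold amplification after n cycles
#'
#' Mean of the per-cycle duplication branching process: each copy duplicates
#' with probability `p` per cycle, so the expected copy number multiplies by
#' `(1 + p)` each cycle.
#'
#' @param p Duplication probability per cycle, in `[0, 1]`.
#' @param n_cycles Number of cycles (>= 0).
#' @return `(1 + p)^n_cycles`.
#' @export
expected_amplification <- function(p, n_cycles) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(n_cycles < 0)) stop("n_cycles must be >= 0")
  (1 + p)^n_cycles
}

#' Model-predicted GC-bias curve
#'
#' The closed-form curve the efficiency profile implies after `n_cycles`
#' cycles, relative to the anchor GC:
#' `value(g) = ((1 + p(g)) / (1 + p(anchor_gc)))^n_cycles`, so the anchor bin
#' is exactly 1.
#'
#' @param profile An [efficiency_profile].
#' @param n_cycles Number of PCR cycles.
#' @param anchor_gc Anchor GC percent (default 50).
#' @param bins Percent-GC bins to evaluate (default every 2%).
#' @return A `predicted_curve` data frame with `bin_percent` and
#'   `relative_value`; attributes `n_cycles`, `anchor_gc`.
#' @export
predicted_bias_curve <- function(profile, n_cycles, anchor_gc = 50,
                                 bins = seq(0, 100, by = 2)) {
  p <- efficiency(bins, profile)
  p0 <- efficiency(anchor_gc, profile)
  out <- data.frame(bin_percent = bins,
                    relative_value = ((1 + p) / (1 + p0))^n_cycles)
  attr(out, "n_cycles") <- n_cycles
  attr(out, "anchor_gc") <- anchor_gc
  class(out) <- c("predicted_curve", "data.frame")
  out
}

#' Invert a bias curve to per-cycle relative efficiency
#'
#' Given an observed (or predicted) anchored bias curve and the number of
#' PCR cycles, the per-cycle amplification factor of bin `g` relative to the
#' anchor is `r(g) = value(g)^(1/n_cycles)`. Bins with non-positive values
#' cannot be inverted and are flagged.
#'
#' @param observed A `bias_curve` or `predicted_curve` (needs `bin_percent`
#'   and `relative_value`).
#' @param n_cycles Number of cycles used to produce the curve (>= 1).
#' @return Data frame `bin_percent`, `relative_efficiency`,
#'   `non_invertible`.
#' @export
fit_relative_efficiency <- function(observed, n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  v <- observed$relative_value
  bad <- is.na(v) | v <= 0
  r <- rep(NA_real_, length(v))
  r[!bad] <- v[!bad]^(1 / n_cycles)
  data.frame(bin_percent = observed$bin_percent,
             relative_efficiency = r,
             non_invertible = bad)
}

#' Stochastic per-cycle PCR amplification of a fragment pool
#'
#' Galton-Watson branching by copy-level binomial draws: in each cycle,
#' every fragment with `c` current copies and duplication probability
#' `p(gc)` gains `Binomial(c, p(gc))` new copies. Exact for the mean
#' `(1 + p)^n` and deterministic given the seed.
#'
#' @param copy_counts Integer vector of starting copy numbers (>= 0).
#' @param profile An [efficiency_profile].
#' @param fragment_gc Percent GC of each fragment (same length).
#' @param n_cycles Number of cycles.
#' @param rng_seed Integer seed (mandatory).
#' @return Integer-valued vector of final copy numbers.
#' @export
simulate_pcr <- function(copy_counts, profile, fragment_gc, n_cycles,
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (length(copy_counts) != length(fragment_gc)) {
    stop("copy_counts and fragment_gc must have the same length")
  }
  if (any(copy_counts < 0)) stop("copy counts must be >= 0")
  p <- efficiency(fragment_gc, profile)
  counts <- as.numeric(copy_counts)
  set.seed(rng_seed)
  for (cycle in seq_len(n_cycles)) {
    counts <- counts + stats::rbinom(length(counts), counts, p)
  }
  counts
}
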