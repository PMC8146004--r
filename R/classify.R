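#' Automatic amplitude threshold for one channel
#'
#' Finds the best two-cluster split of a channel's droplet amplitudes by
#' exact one-dimensional two-means (every split point of the sorted
#' amplitudes is scored by within-cluster sum of squares). If the split
#' reduces the total sum of squares by at least `bimodality_factor`, the
#' channel is declared bimodal and the cutoff is the midpoint between the
#' two cluster means. Otherwise the distribution is treated as a single
#' (negative) cloud and the fallback cutoff is the trimmed mean plus
#' `fallback_k` trimmed standard deviations, which places a clean NTC
#' entirely below threshold.
#'
#' Instrument software performs this step on real data; this
#' implementation is a transparent, inspectable stand-in whose diagnostic
#' output should be reviewed for wells with poor cloud separation (the
#' situation where a manual cutoff is warranted).
#'
#' @param amplitudes Numeric vector of one channel's droplet amplitudes
#'   (at least 100 droplets).
#' @param bimodality_factor Minimum ratio of total to within-cluster sum
#'   of squares required to accept the two-cluster split (default 4).
#' @param fallback_k Multiplier on the trimmed SD for the unimodal
#'   fallback cutoff (default 7).
#' @param trim Fraction trimmed from each tail when estimating the
#'   negative-cloud location and spread in the fallback (default 0.1).
#' @return A list with `cutoff`, `bimodal` (logical separability
#'   diagnostic), `ss_ratio` (total/within sum-of-squares ratio of the
#'   best split), and `cluster_means` (length 2 when bimodal).
#' @export
#' @examples
#' set.seed(1)
#' amps <- c(rnorm(900, 1000, 150), rnorm(100, 8000, 400))
#' auto_threshold(amps)
auto_threshold <- function(amplitudes, bimodality_factor = 4,
                           fallback_k = 7, trim = 0.1) {
  if (!is.numeric(amplitudes) || anyNA(amplitudes) ||
      any(!is.finite(amplitudes))) {
    stop("amplitudes must be finite numeric values", call. = FALSE)
  }
  n <- length(amplitudes)
  if (n < 100L) {
    stop("need at least 100 droplets to set a threshold (got ", n, ")",
         call. = FALSE)
  }
  x <- sort(amplitudes)
  # exact 1-D two-means: within-cluster SS for every split of the sorted
  # values, via prefix sums
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- seq_len(n - 1L)
  ss_left <- cs2[i] - cs[i]^2 / i
  n_right <- n - i
  sum_right <- cs[n] - cs[i]
  ss_right <- (cs2[n] - cs2[i]) - sum_right^2 / n_right
  within <- ss_left + ss_right
  best <- which.min(within)
  total_ss <- cs2[n] - cs[n]^2 / n
  ss_ratio <- if (within[best] > 0) total_ss / within[best] else
    (if (total_ss > 0) Inf else 1)
  if (is.finite(ss_ratio) || total_ss > 0) {
    bimodal <- ss_ratio >= bimodality_factor
  } else {
    bimodal <- FALSE  # constant amplitudes
  }
  if (bimodal) {
    mean_lo <- cs[best] / best
    mean_hi <- (cs[n] - cs[best]) / (n - best)
    cutoff <- (mean_lo + mean_hi) / 2
    cluster_means <- c(mean_lo, mean_hi)
  } else {
    lo <- floor(n * trim) + 1L
    hi <- n - floor(n * trim)
    core <- x[lo:hi]
    core_sd <- stats::sd(core)
    if (!is.finite(core_sd)) core_sd <- 0
    cutoff <- mean(core) + fallback_k * core_sd
    cluster_means <- mean(core)
  }
  list(cutoff = cutoff, bimodal = bimodal, ss_ratio = ss_ratio,
       cluster_means = cluster_means)
}

#' Per-well channel cutoffs
#'
#' @param ch1_cutoff,ch2_cutoff Fluorescence cutoffs; a droplet is
#'   positive on a channel when its amplitude is strictly greater than the
#'   cutoff (ties classify negative, the conservative direction for fetal
#'   calls).
#' @param ch1_method,ch2_method `"auto"` or `"manual"`; recorded so
#'   reports can state cutoff provenance.
#' @return A list of class `channel_cutoffs`.
#' @export
channel_cutoffs <- function(ch1_cutoff, ch2_cutoff,
                            ch1_method = "manual", ch2_method = "manual") {
  for (v in list(ch1_cutoff, ch2_cutoff)) {
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0)) {
      stop("cutoffs must be single finite positive numbers", call. = FALSE)
    }
  }
  ch1_method <- match.arg(ch1_method, c("auto", "manual"))
  ch2_method <- match.arg(ch2_method, c("auto", "manual"))
  structure(list(ch1_cutoff = ch1_cutoff, ch2_cutoff = ch2_cutoff,
                 ch1_method = ch1_method, ch2_method = ch2_method),
            class = "channel_cutoffs")
}

#' Set cutoffs for both channels of a droplet table
#'
#' Runs [auto_threshold()] on each channel, unless a manual cutoff is
#' supplied for that channel — a manual value always overrides the
#' automatic one (mirroring instrument practice when the software cannot
#' place the line, as happens for poorly separated assays).
#'
#' @param table A `droplet_table`.
#' @param ch1_manual,ch2_manual Optional manual cutoff for the channel.
#' @param ... Passed to [auto_threshold()].
#' @return A [channel_cutoffs] object with per-channel provenance, plus a
#'   `diagnostics` attribute holding the auto-threshold output.
#' @export
auto_cutoffs <- function(table, ch1_manual = NULL, ch2_manual = NULL, ...) {
  diag <- list()
  if (is.null(ch1_manual)) {
    diag$ch1 <- auto_threshold(table$ch1_amplitude, ...)
    c1 <- diag$ch1$cutoff
    m1 <- "auto"
  } else {
    c1 <- ch1_manual
    m1 <- "manual"
  }
  if (is.null(ch2_manual)) {
    diag$ch2 <- auto_threshold(table$ch2_amplitude, ...)
    c2 <- diag$ch2$cutoff
    m2 <- "auto"
  } else {
    c2 <- ch2_manual
    m2 <- "manual"
  }
  out <- channel_cutoffs(c1, c2, m1, m2)
  attr(out, "diagnostics") <- diag
  out
}

#' Construct (and validate) per-well classified droplet counts
#'
#' The per-well tally unit of the pipeline: total droplets, per-channel
#' positives (a double-positive droplet counts in both channels' tallies,
#' the instrument-export convention), double positives, and
#' double-negative droplets. The four joint classes partition the well,
#' enforced as `n_ch1_pos + n_ch2_pos - n_double_pos + n_neg = n_total`.
#'
#' @param n_total Total droplets.
#' @param n_ch1_pos Droplets positive in channel 1 (FAM), regardless of
#'   channel 2.
#' @param n_ch2_pos Droplets positive in channel 2 (HEX), regardless of
#'   channel 1.
#' @param n_double_pos Droplets positive in both channels.
#' @param n_neg Droplets negative in both channels; derived from the
#'   conservation identity when omitted.
#' @param well_id Well identifier.
#' @param cutoffs Optional [channel_cutoffs] used to produce the tallies.
#' @return An object of class `classified_counts`.
#' @export
classified_counts <- function(n_total, n_ch1_pos, n_ch2_pos,
                              n_double_pos = 0L, n_neg = NULL,
                              well_id = NA_character_, cutoffs = NULL) {
  vals <- c(n_total, n_ch1_pos, n_ch2_pos, n_double_pos)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("droplet counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(n_neg)) {
    n_neg <- n_total - n_ch1_pos - n_ch2_pos + n_double_pos
  }
  if (n_neg < 0 ||
      n_ch1_pos + n_ch2_pos - n_double_pos + n_neg != n_total) {
    stop("well '", well_id, "': counts violate conservation ",
         "(n_ch1_pos + n_ch2_pos - n_double_pos + n_neg must equal n_total)",
         call. = FALSE)
  }
  if (n_double_pos > min(n_ch1_pos, n_ch2_pos)) {
    stop("well '", well_id,
         "': n_double_pos exceeds a channel's positive count", call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total),
         n_ch1_pos = as.integer(n_ch1_pos),
         n_ch2_pos = as.integer(n_ch2_pos),
         n_double_pos = as.integer(n_double_pos),
         n_neg = as.integer(n_neg),
         well_id = well_id,
         cutoffs = cutoffs),
    class = "classified_counts"
  )
}

#' @export
print.classified_counts <- function(x, ...) {
  cat("<classified_counts> well ", x$well_id, ": ", x$n_total,
      " droplets; FAM+ ", x$n_ch1_pos, ", HEX+ ", x$n_ch2_pos,
      ", double+ ", x$n_double_pos, ", neg ", x$n_neg, "\n", sep = "")
  invisible(x)
}

#' Classify a droplet table into per-well counts
#'
#' A droplet is positive on a channel when its amplitude is strictly
#' greater than that channel's cutoff. The result is deterministic and
#' invariant to droplet order.
#'
#' @param table A `droplet_table` (or data frame with `ch1_amplitude` and
#'   `ch2_amplitude` columns).
#' @param cutoffs A [channel_cutoffs] object.
#' @return A [classified_counts] object carrying the cutoffs used.
#' @export
#' @examples
#' tab <- data.frame(ch1_amplitude = c(500, 9000, 950),
#'                   ch2_amplitude = c(900, 800, 8500))
#' classify_droplets(tab, channel_cutoffs(4500, 4500))
classify_droplets <- function(table, cutoffs) {
  if (!inherits(cutoffs, "channel_cutoffs")) {
    stop("'cutoffs' must come from channel_cutoffs() or auto_cutoffs()",
         call. = FALSE)
  }
  if (is.null(table$ch1_amplitude) || is.null(table$ch2_amplitude)) {
    stop("droplet table must have ch1_amplitude and ch2_amplitude columns",
         call. = FALSE)
  }
  if (nrow(table) == 0L) {
    stop("droplet table is empty", call. = FALSE)
  }
  pos1 <- table$ch1_amplitude > cutoffs$ch1_cutoff
  pos2 <- table$ch2_amplitude > cutoffs$ch2_cutoff
  classified_counts(
    n_total = nrow(table),
    n_ch1_pos = sum(pos1),
    n_ch2_pos = sum(pos2),
    n_double_pos = sum(pos1 & pos2),
    n_neg = sum(!pos1 & !pos2),
    well_id = attr(table, "well_id") %||% NA_character_,
    cutoffs = cutoffs
  )
}
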