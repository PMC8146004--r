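#' Decision thresholds for fetal genotype calling
#'
#' Droplet-count limits governing the call: the non-template control may
#' show at most `ntc_max_false_pos` positive droplets per channel (the
#' empirical false-positive ceiling of a clean NTC); a fetus-specific
#' signal is called present from `min_fetal_pos` droplets; results with
#' fetus-specific counts within `repeat_halfwidth` of that limit fall in
#' the repeat zone and should be re-analysed before reporting; and a
#' fetal-negative call additionally requires at least `min_msp`
#' maternal-channel positives so that absence of signal is evidence of
#' absence rather than of a failed well.
#'
#' @param ntc_max_false_pos Maximum tolerated NTC positives per channel
#'   (default 4).
#' @param min_fetal_pos Minimum fetus-specific positive droplets for a
#'   positive call (default 5).
#' @param repeat_halfwidth Half-width of the repeat zone around
#'   `min_fetal_pos` (default 2, i.e. zone \[3, 7\]).
#' @param min_msp Minimum maternal-channel positives for any conclusive
#'   call (default 200, just below the smallest maternal-channel count
#'   observed across the study wells).
#' @return A list of class `decision_thresholds`.
#' @export
decision_thresholds <- function(ntc_max_false_pos = 4L, min_fetal_pos = 5L,
                                repeat_halfwidth = 2L, min_msp = 200L) {
  vals <- c(ntc_max_false_pos, min_fetal_pos, repeat_halfwidth, min_msp)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("thresholds must be non-negative integers", call. = FALSE)
  }
  if (!(ntc_max_false_pos < min_fetal_pos)) {
    stop("ntc_max_false_pos (", ntc_max_false_pos,
         ") must be below min_fetal_pos (", min_fetal_pos, ")",
         call. = FALSE)
  }
  structure(
    list(ntc_max_false_pos = as.integer(ntc_max_false_pos),
         min_fetal_pos = as.integer(min_fetal_pos),
         repeat_halfwidth = as.integer(repeat_halfwidth),
         min_msp = as.integer(min_msp)),
    class = "decision_thresholds"
  )
}

#' Non-template control quality check
#'
#' Passes when the NTC well shows at most `ntc_max_false_pos` positive
#' droplets in *each* channel independently (the per-channel convention
#' matching per-channel NTC tallies).
#'
#' @param ntc_counts [classified_counts] from a no-template well.
#' @param thresholds A [decision_thresholds] object.
#' @return List with `pass` (logical), per-channel positives, the limit
#'   applied and `fail_channels` (character vector, possibly empty).
#' @export
#' @examples
#' ntc <- classified_counts(15000, 1, 0, 0)
#' ntc_qc(ntc, decision_thresholds())$pass
ntc_qc <- function(ntc_counts, thresholds = decision_thresholds()) {
  stopifnot(inherits(ntc_counts, "classified_counts"),
            inherits(thresholds, "decision_thresholds"))
  limit <- thresholds$ntc_max_false_pos
  fail <- c(if (ntc_counts$n_ch1_pos > limit) "ch1",
            if (ntc_counts$n_ch2_pos > limit) "ch2")
  list(pass = length(fail) == 0L,
       ch1_pos = ntc_counts$n_ch1_pos,
       ch2_pos = ntc_counts$n_ch2_pos,
       limit = limit,
       fail_channels = fail %||% character())
}

#' Call the fetal genotype for one well
#'
#' Applies the droplet-count decision rules to a sample well and its
#' paired non-template control:
#'
#' 1. If the NTC fails [ntc_qc()], the run is invalid: `QC_FAIL`, no
#'    genotype call.
#' 2. The fetus-specific positive count (FSP) is read from the channel
#'    returned by [fetus_specific_channel()]; the other channel gives the
#'    maternal-specific positives (MSP; for the RHD assay, the total-DNA
#'    control count).
#' 3. A saturated channel (every droplet positive) makes quantification
#'    impossible: `INCONCLUSIVE` with a `saturation` flag.
#' 4. If MSP is below `min_msp`, too little cell-free DNA was recovered
#'    to trust a negative result: `INCONCLUSIVE` with `low_msp`.
#' 5. FSP at or above `min_fetal_pos`: the fetus carries the paternal
#'    allele; the call is heterozygous (detected allele / maternal
#'    allele) and the fetal fraction is computed with its confidence
#'    interval.
#' 6. FSP at or below `ntc_max_false_pos`: the paternal allele is not
#'    detected; the fetal genotype is reported equal to the maternal
#'    homozygous genotype and no fetal fraction is computed. (Counts
#'    strictly between the two limits can only arise with non-default
#'    thresholds and are `INCONCLUSIVE` — no silent call from an
#'    undefined region.)
#' 7. Independently, an FSP inside the repeat zone
#'    `[min_fetal_pos - repeat_halfwidth, min_fetal_pos + repeat_halfwidth]`
#'    downgrades a conclusive status to `REPEAT_RECOMMENDED`.
#'
#' @param sample [classified_counts] for the sample well.
#' @param ntc [classified_counts] for the paired NTC well.
#' @param ctx [maternal_context] (assay + homozygous maternal genotype).
#' @param thresholds A [decision_thresholds] object.
#' @param ff_method Fetal-fraction method passed to [fetal_fraction()].
#' @return An object of class `fetal_call_result` with the genotype call,
#'   status (`CONCLUSIVE`, `REPEAT_RECOMMENDED`, `INCONCLUSIVE`,
#'   `QC_FAIL`), FSP/MSP, fetal fraction (positive calls only), QC flags
#'   and the thresholds used.
#' @export
#' @examples
#' ctx <- maternal_context("RHD_ex7", "RHD-/RHD-")
#' sample <- classified_counts(15349, 47, 1540, 0, well_id = "S1")
#' ntc <- classified_counts(15646, 1, 0, 0, well_id = "NTC")
#' call_fetal_genotype(sample, ntc, ctx)
call_fetal_genotype <- function(sample, ntc, ctx,
                                thresholds = decision_thresholds(),
                                ff_method = "raw-count") {
  stopifnot(inherits(sample, "classified_counts"),
            inherits(ntc, "classified_counts"),
            inherits(thresholds, "decision_thresholds"))
  if (!inherits(ctx, "maternal_context")) {
    stop("'ctx' must be a maternal_context (homozygous mother)",
         call. = FALSE)
  }
  fs <- fetus_specific_channel(ctx)
  if (fs$channel == "FAM") {
    fsp <- sample$n_ch1_pos
    msp <- sample$n_ch2_pos
  } else {
    fsp <- sample$n_ch2_pos
    msp <- sample$n_ch1_pos
  }
  result <- function(call, status, flags, ff = NULL) {
    res <- structure(
      list(well_id = sample$well_id,
           assay = ctx$assay$name,
           maternal_genotype = paste(ctx$maternal_genotype, collapse = "/"),
           fetal_genotype_call = call,
           status = status,
           fsp = fsp, msp = msp,
           fetus_specific_channel = fs$channel,
           fetus_specific_allele = fs$allele,
           fetal_fraction = ff,
           qc_flags = flags,
           thresholds = thresholds,
           cutoffs = sample$cutoffs),
      class = "fetal_call_result"
    )
    # a called genotype must be Mendelian-consistent with the mother
    if (!is.na(call)) {
      alleles <- strsplit(call, "/", fixed = TRUE)[[1L]]
      stopifnot(any(alleles %in% ctx$maternal_genotype) ||
                  ctx$assay$reference_channel_is_total_dna)
    }
    res
  }

  qc <- ntc_qc(ntc, thresholds)
  if (!qc$pass) {
    return(result(NA_character_, "QC_FAIL",
                  paste0("ntc_fail_", qc$fail_channels)))
  }
  if (fsp >= sample$n_total || msp >= sample$n_total) {
    return(result(NA_character_, "INCONCLUSIVE", "saturation"))
  }
  if (msp < thresholds$min_msp) {
    return(result(NA_character_, "INCONCLUSIVE", "low_msp"))
  }

  zone_lo <- thresholds$min_fetal_pos - thresholds$repeat_halfwidth
  zone_hi <- thresholds$min_fetal_pos + thresholds$repeat_halfwidth
  in_repeat_zone <- fsp >= zone_lo && fsp <= zone_hi
  flags <- if (in_repeat_zone) "repeat_zone" else character()
  status <- if (in_repeat_zone) "REPEAT_RECOMMENDED" else "CONCLUSIVE"

  if (fsp >= thresholds$min_fetal_pos) {
    # paternal allele detected: heterozygous fetus
    maternal_allele <- if (ctx$assay$reference_channel_is_total_dna) {
      ctx$maternal_genotype[1L]
    } else {
      fs$maternal_allele
    }
    call <- paste(fs$allele, maternal_allele, sep = "/")
    ff <- fetal_fraction(fsp, msp, method = ff_method,
                         n_total = sample$n_total)
    return(result(call, status, flags, ff))
  }
  if (fsp <= thresholds$ntc_max_false_pos) {
    # paternal allele not detected: fetus matches the homozygous mother
    call <- paste(ctx$maternal_genotype, collapse = "/")
    return(result(call, status, flags))
  }
  # count falls in a user-configured gap between the two limits
  result(NA_character_, "INCONCLUSIVE", c(flags, "undefined_zone"))
}

#' @export
print.fetal_call_result <- function(x, ...) {
  cat("<fetal_call_result> well ", x$well_id, " [", x$assay, "]\n",
      "  mother ", x$maternal_genotype, "; FSP ", x$fsp, " (",
      x$fetus_specific_channel, "/", x$fetus_specific_allele,
      "), MSP ", x$msp, "\n",
      "  call: ", if (is.na(x$fetal_genotype_call)) "none"
      else x$fetal_genotype_call,
      "   status: ", x$status, sep = "")
  if (length(x$qc_flags) > 0L) {
    cat("   flags: ", paste(x$qc_flags, collapse = ","), sep = "")
  }
  cat("\n")
  if (!is.null(x$fetal_fraction)) {
    cat("  fetal fraction: ", x$fetal_fraction$percent_label, "\n", sep = "")
  }
  invisible(x)
}
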