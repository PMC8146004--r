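#' Poisson occupancy estimate from digital PCR counts
#'
#' Standard digital-PCR quantification: with `n_pos` of `n_total`
#' droplets positive, the mean number of target molecules per droplet is
#' `lambda = -ln(1 - n_pos / n_total)`, the Poisson inversion of the
#' fraction of empty droplets.
#'
#' @param n_pos Positive droplets (0 <= n_pos < n_total).
#' @param n_total Total droplets.
#' @return Estimated occupancy `lambda` (molecules per droplet).
#' @export
#' @examples
#' lambda_estimate(1000, 10000)  # -log(0.9)
lambda_estimate <- function(n_pos, n_total) {
  if (!(is.numeric(n_total) && length(n_total) == 1L && n_total > 0)) {
    stop("n_total must be a single positive count", call. = FALSE)
  }
  if (!(is.numeric(n_pos) && length(n_pos) == 1L && n_pos >= 0)) {
    stop("n_pos must be a single non-negative count", call. = FALSE)
  }
  if (n_pos >= n_total) {
    stop("all ", n_total, " droplets positive: occupancy is unbounded ",
         "(saturation); dilute and re-run", call. = FALSE)
  }
  -log(1 - n_pos / n_total)
}

#' Confidence interval for the Poisson occupancy
#'
#' Delta-method interval on `lambda = -ln(1 - p)` with binomial sampling
#' variance on the positive fraction `p`:
#' `SD(lambda) = sqrt(p / (n (1 - p)))`. With zero positives the upper
#' bound uses the rule of three (`lambda_hi = -ln(1 - 3/n)`).
#'
#' @param n_pos,n_total Droplet counts as in [lambda_estimate()].
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lambda = , lower = , upper = )`.
#' @export
lambda_ci <- function(n_pos, n_total, conf = 0.95) {
  lam <- lambda_estimate(n_pos, n_total)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (n_pos == 0) {
    return(c(lambda = 0, lower = 0, upper = -log(1 - 3 / n_total)))
  }
  p <- n_pos / n_total
  sd_lam <- sqrt(p / (n_total * (1 - p)))
  c(lambda = lam,
    lower = max(0, lam - z * sd_lam),
    upper = lam + z * sd_lam)
}

#' Absolute concentration from droplet occupancy
#'
#' @param lambda Mean molecules per droplet.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85,
#'   the usual instrument convention; configurable).
#' @return Concentration in copies per microlitre of reaction.
#' @export
#' @examples
#' copies_per_microliter(1, droplet_volume_nl = 1)  # 1000 copies/uL
copies_per_microliter <- function(lambda, droplet_volume_nl = 0.85) {
  if (!(is.numeric(droplet_volume_nl) && droplet_volume_nl > 0)) {
    stop("droplet volume must be positive", call. = FALSE)
  }
  if (!(is.numeric(lambda) && all(lambda >= 0))) {
    stop("lambda must be non-negative", call. = FALSE)
  }
  lambda / (droplet_volume_nl * 1e-3)
}

#' Format a fetal fraction for reporting
#'
#' Fractions at or above 10% are reported as whole percent, smaller ones
#' with one decimal (`0.2627` -> `"26%"`, `0.066` -> `"6.6%"`).
#'
#' @param fraction Dimensionless fetal fraction.
#' @return A list with `percent` (the rounded numeric percent) and
#'   `label` (the formatted string).
#' @export
format_ff_percent <- function(fraction) {
  pct <- 100 * fraction
  pct_rounded <- if (pct >= 10) round(pct) else round(pct, 1)
  list(percent = pct_rounded,
       label = paste0(format(pct_rounded, trim = TRUE), "%"))
}

#' Cell-free fetal DNA fraction from droplet counts
#'
#' The fetal fraction is computed from fetus-specific positive droplets
#' (FSP; the channel of the allele the homozygous mother lacks) and
#' maternal-specific positive droplets (MSP):
#'
#' `FF = FSP / ((MSP - FSP) / 2)`
#'
#' Each fetal genome contributes one copy of the paternal allele
#' (heterozygous fetus) while every genome, maternal or fetal,
#' contributes two copies of the maternal allele, so `(MSP - FSP) / 2`
#' estimates maternal genome-equivalents and the ratio is fetal over
#' maternal genome-equivalents. The default `raw-count` method treats
#' each positive droplet as exactly one molecule, justified at the low
#' occupancies typical of cell-free DNA wells; `poisson-corrected`
#' replaces each count by the Poisson molecule-number estimate
#' `n_total * lambda(count)` before applying the same formula, and is
#' preferable when a channel's occupancy is not small.
#'
#' For the RHD assay, MSP is the beta-globin total-DNA control count and
#' the same formula is applied by convention (so published figures are
#' reproduced); the `total-reference` method instead uses
#' `2 * FSP / MSP`, reflecting that the control channel counts maternal
#' plus fetal genomes. It is never the default.
#'
#' @param fsp Fetus-specific positive droplets.
#' @param msp Maternal-specific positive droplets (must exceed `fsp`).
#' @param method `"raw-count"` (default), `"poisson-corrected"` or
#'   `"total-reference"`.
#' @param n_total Total droplets; required for `poisson-corrected` and
#'   for the confidence interval.
#' @param conf Confidence level for the interval (when `n_total` given).
#' @return An object of class `fetal_fraction_result` with fields `fsp`,
#'   `msp`, `fraction`, `percent` / `percent_label` (reporting
#'   convention: whole percent at >= 10%, one decimal below), `method`
#'   and `ci` (or `NULL`).
#' @export
#' @examples
#' fetal_fraction(44, 379)   # 26%
#' fetal_fraction(54, 517)   # 23%
fetal_fraction <- function(fsp, msp,
                           method = c("raw-count", "poisson-corrected",
                                      "total-reference"),
                           n_total = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (!(is.numeric(fsp) && is.numeric(msp) && fsp >= 0 && msp >= 0)) {
    stop("fsp and msp must be non-negative counts", call. = FALSE)
  }
  if (msp <= fsp) {
    stop("fetal fraction undefined: MSP (", msp,
         ") must exceed FSP (", fsp, ")", call. = FALSE)
  }
  if (method == "poisson-corrected") {
    if (is.null(n_total)) {
      stop("poisson-corrected method requires n_total", call. = FALSE)
    }
    m_fsp <- n_total * lambda_estimate(fsp, n_total)
    m_msp <- n_total * lambda_estimate(msp, n_total)
    fraction <- m_fsp / ((m_msp - m_fsp) / 2)
  } else if (method == "total-reference") {
    fraction <- 2 * fsp / msp
  } else {
    fraction <- fsp / ((msp - fsp) / 2)
  }
  fmt <- format_ff_percent(fraction)
  ci <- if (!is.null(n_total)) fetal_fraction_ci(fsp, msp, n_total, conf)
  structure(
    list(fsp = fsp, msp = msp, fraction = fraction,
         percent = fmt$percent, percent_label = fmt$label,
         method = method, ci = ci, n_total = n_total),
    class = "fetal_fraction_result"
  )
}

#' @export
print.fetal_fraction_result <- function(x, ...) {
  cat("<fetal_fraction_result> FSP ", x$fsp, " / MSP ", x$msp,
      " -> FF = ", signif(x$fraction, 4), " (", x$percent_label, ", ",
      x$method, ")\n", sep = "")
  if (!is.null(x$ci)) {
    cat("  95% CI [", signif(x$ci[["lower"]], 4), ", ",
        signif(x$ci[["upper"]], 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Confidence interval for the fetal fraction
#'
#' Propagates Poisson sampling uncertainty on the two droplet counts to
#' the ratio `FF = 2 FSP / (MSP - FSP)` by the delta method on the log
#' scale: `Var(log FF) = (1/FSP + 1/(MSP-FSP))^2 FSP + MSP/(MSP-FSP)^2`,
#' giving a multiplicative interval that always contains the point
#' estimate. With `FSP = 0` the interval is `[0, upper]` with the upper
#' bound from the rule-of-three Poisson bound on FSP.
#'
#' @param fsp,msp Droplet counts as in [fetal_fraction()].
#' @param n_total Total droplets (retained for interface symmetry with
#'   the occupancy-based estimators; the Poisson count approximation does
#'   not use it).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
fetal_fraction_ci <- function(fsp, msp, n_total = NULL, conf = 0.95) {
  if (msp <= fsp || fsp < 0) {
    stop("fetal fraction undefined: require 0 <= FSP < MSP", call. = FALSE)
  }
  if (fsp == 0) {
    upper <- 2 * 3 / (msp - 3)
    return(c(lower = 0, upper = max(upper, 0)))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  point <- 2 * fsp / (msp - fsp)
  var_log <- (1 / fsp + 1 / (msp - fsp))^2 * fsp + msp / (msp - fsp)^2
  half <- z * sqrt(var_log)
  c(lower = point * exp(-half), upper = point * exp(half))
}
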