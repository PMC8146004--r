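#' Amplitude cloud model for one fluorescence channel
#'
#' Droplet amplitudes are drawn from a negative cloud (empty or
#' non-amplified droplets) or a positive cloud, both Gaussian in arbitrary
#' fluorescence units, with an optional uniform "rain" band between the
#' cloud means for a fraction of positive droplets. Defaults give cleanly
#' separable clouds with visible rain, mimicking typical one-dimensional
#' ddPCR plots.
#'
#' @param neg_mean,neg_sd Negative-cloud mean and standard deviation.
#' @param pos_mean,pos_sd Positive-cloud mean and standard deviation.
#' @return A list of class `amplitude_model`.
#' @export
amplitude_model <- function(neg_mean = 1000, neg_sd = 150,
                            pos_mean = 8000, pos_sd = 400) {
  if (!(pos_mean > neg_mean)) {
    stop("positive-cloud mean must exceed negative-cloud mean", call. = FALSE)
  }
  if (neg_sd < 0 || pos_sd < 0) {
    stop("cloud standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd),
            class = "amplitude_model")
}

#' Simulation parameters for one duplex ddPCR well
#'
#' Describes the molecular and instrument model used by [simulate_well()]:
#' maternal and fetal cell-free DNA molecules are partitioned into
#' droplets by independent Poisson counts per channel, each surviving
#' molecule renders its droplet positive, and amplitudes are drawn from
#' per-channel cloud models.
#'
#' The per-channel occupancy is
#' `lambda_c = copies_m(c) * lambda_g + copies_f(c) * f * lambda_g`,
#' where `lambda_g` is `maternal_genomes_per_droplet`, `f` is
#' `fetal_fraction_true`, and `copies_m`/`copies_f` count how many copies
#' of the channel's target allele one maternal/fetal genome carries
#' (homozygote 2, heterozygote 1; a total-DNA control locus contributes 2
#' from every genome, maternal or fetal).
#'
#' Note that `f` is the ratio of fetal to *maternal* genome-equivalents
#' (not fetal to total), matching the droplet-count fetal-fraction formula
#' used downstream.
#'
#' @param ctx A [maternal_context] (assay + homozygous maternal genotype).
#' @param fetal_genotype Fetal genotype (any form accepted by
#'   [parse_genotype()]); must share an allele with the mother.
#' @param n_droplets Number of droplets in the well.
#' @param maternal_genomes_per_droplet Mean maternal genome-equivalents
#'   per droplet (dimensionless occupancy `lambda_g`).
#' @param fetal_fraction_true Ratio of fetal to maternal
#'   genome-equivalents.
#' @param amplitude_ch1,amplitude_ch2 Per-channel [amplitude_model]s.
#' @param rain_prob Probability that a positive droplet's amplitude falls
#'   uniformly between the cloud means instead of in the positive cloud.
#' @param false_positive_rate Per-droplet, per-channel probability that a
#'   droplet with no surviving target molecule still reads positive.
#' @param detection_dropout Per-molecule probability of non-amplification.
#' @param seed Integer seed; every simulation with the same parameters and
#'   seed is bit-identical. `NULL` uses the session RNG stream.
#' @return A list of class `simulation_params`.
#' @export
#' @examples
#' ctx <- maternal_context("RHCE_rs676785", "cc")
#' p <- simulation_params(ctx, "Cc", fetal_fraction_true = 0.08, seed = 1)
#' expected_counts(p)
simulation_params <- function(ctx, fetal_genotype,
                              n_droplets = 14000,
                              maternal_genomes_per_droplet = 0.025,
                              fetal_fraction_true = 0.1,
                              amplitude_ch1 = amplitude_model(),
                              amplitude_ch2 = amplitude_model(),
                              rain_prob = 0.01,
                              false_positive_rate = 2e-5,
                              detection_dropout = 0,
                              seed = NULL) {
  if (!inherits(ctx, "maternal_context")) {
    stop("'ctx' must be a maternal_context", call. = FALSE)
  }
  fetal <- parse_genotype(fetal_genotype)
  if (!any(fetal %in% ctx$maternal_genotype)) {
    stop("fetal genotype ", paste(fetal, collapse = "/"),
         " shares no allele with the mother (",
         paste(ctx$maternal_genotype, collapse = "/"),
         "); incompatible with Mendelian inheritance", call. = FALSE)
  }
  assay <- ctx$assay
  valid <- c(assay$fam_allele,
             if (!assay$reference_channel_is_total_dna) assay$hex_allele,
             if (!is.na(assay$null_allele)) assay$null_allele)
  bad <- setdiff(fetal, valid)
  if (length(bad) > 0L) {
    stop("fetal allele(s) ", paste(bad, collapse = ", "),
         " are not alleles of assay '", assay$name, "'", call. = FALSE)
  }
  if (!(is.numeric(n_droplets) && length(n_droplets) == 1L && n_droplets >= 1)) {
    stop("n_droplets must be a single count >= 1", call. = FALSE)
  }
  if (!(maternal_genomes_per_droplet > 0)) {
    stop("maternal_genomes_per_droplet must be > 0", call. = FALSE)
  }
  if (fetal_fraction_true < 0) {
    stop("fetal_fraction_true must be >= 0", call. = FALSE)
  }
  for (nm in c("rain_prob", "false_positive_rate", "detection_dropout")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && v >= 0 && v <= 1)) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(inherits(amplitude_ch1, "amplitude_model"),
            inherits(amplitude_ch2, "amplitude_model"))
  structure(
    list(
      ctx = ctx,
      fetal_genotype = fetal,
      n_droplets = as.integer(round(n_droplets)),
      maternal_genomes_per_droplet = maternal_genomes_per_droplet,
      fetal_fraction_true = fetal_fraction_true,
      amplitude_ch1 = amplitude_ch1,
      amplitude_ch2 = amplitude_ch2,
      rain_prob = rain_prob,
      false_positive_rate = false_positive_rate,
      detection_dropout = detection_dropout,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "simulation_params"
  )
}

# Allele copies of `allele` carried by one genome of `genotype`; a
# total-DNA control locus contributes 2 copies from any genome.
allele_copies <- function(allele, genotype, is_total_dna_control) {
  if (is_total_dna_control) 2L else sum(genotype == allele)
}

#' Per-channel Poisson occupancies implied by simulation parameters
#'
#' @param params A [simulation_params] object.
#' @return Named numeric vector `c(ch1 = ..., ch2 = ...)` of mean target
#'   molecules per droplet.
#' @export
channel_lambdas <- function(params) {
  assay <- params$ctx$assay
  lam_g <- params$maternal_genomes_per_droplet
  f <- params$fetal_fraction_true
  mat <- params$ctx$maternal_genotype
  fet <- params$fetal_genotype
  lam <- function(allele, control) {
    allele_copies(allele, mat, control) * lam_g +
      allele_copies(allele, fet, control) * f * lam_g
  }
  c(ch1 = lam(assay$fam_allele, FALSE),
    ch2 = lam(assay$hex_allele, assay$reference_channel_is_total_dna))
}

#' Expected positive-droplet counts per channel (analytic)
#'
#' Closed-form expectation used as the oracle for [simulate_well()]: with
#' per-droplet occupancy `lambda`, dropout `d` and false-positive rate
#' `fp`, the probability a droplet reads positive is
#' `(1 - exp(-lambda * (1 - d))) + exp(-lambda * (1 - d)) * fp`, and the
#' expected count is `n_droplets` times that.
#'
#' @param params A [simulation_params] object.
#' @return A list with `ch1` and `ch2` expected positive counts, the
#'   per-channel positive probabilities `p_ch1`/`p_ch2`, and the channel
#'   occupancies `lambda`.
#' @export
expected_counts <- function(params) {
  lam <- channel_lambdas(params)
  p_pos <- function(lambda) {
    p_empty <- exp(-lambda * (1 - params$detection_dropout))
    (1 - p_empty) + p_empty * params$false_positive_rate
  }
  p1 <- p_pos(lam[["ch1"]])
  p2 <- p_pos(lam[["ch2"]])
  list(ch1 = params$n_droplets * p1,
       ch2 = params$n_droplets * p2,
       p_ch1 = p1, p_ch2 = p2,
       lambda = lam)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream; a NULL seed uses the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

draw_amplitudes <- function(positive, model, rain_prob) {
  n <- length(positive)
  amps <- numeric(n)
  n_neg <- sum(!positive)
  if (n_neg > 0L) {
    amps[!positive] <- stats::rnorm(n_neg, model$neg_mean, model$neg_sd)
  }
  n_pos <- sum(positive)
  if (n_pos > 0L) {
    rain <- stats::runif(n_pos) < rain_prob
    a <- numeric(n_pos)
    a[!rain] <- stats::rnorm(sum(!rain), model$pos_mean, model$pos_sd)
    a[rain] <- stats::runif(sum(rain), model$neg_mean, model$pos_mean)
    amps[positive] <- a
  }
  pmax(amps, 0)
}

new_droplet_table <- function(df, well_id) {
  attr(df, "well_id") <- well_id
  class(df) <- c("droplet_table", "data.frame")
  df
}

#' Simulate one duplex ddPCR well
#'
#' Draws per-droplet molecule counts for each channel from independent
#' Poisson distributions at the occupancies implied by the parameters
#' (see [channel_lambdas()]), thins them by the detection dropout, marks a
#' droplet latently positive when at least one molecule survives (or, for
#' molecule-free droplets, with the false-positive probability), and draws
#' a fluorescence amplitude from the matching cloud or the rain band.
#' Because molecule counts are Poisson, droplets with several molecules —
#' and double-positive droplets — arise naturally; the one-molecule-per-
#' droplet approximation used in raw-count quantification can therefore be
#' stress-tested against this simulator.
#'
#' @param params A [simulation_params] object.
#' @param well_id Identifier stored on the output table.
#' @param include_truth Keep the latent per-droplet molecule counts and
#'   positivity indicators as extra columns (default `TRUE`).
#' @return A `droplet_table` data frame with columns `ch1_amplitude` and
#'   `ch2_amplitude` (plus, when `include_truth`, `ch1_molecules`,
#'   `ch2_molecules`, `ch1_latent_pos`, `ch2_latent_pos`).
#' @export
#' @examples
#' ctx <- maternal_context("KEL_rs8176058", "KEL2/KEL2")
#' p <- simulation_params(ctx, "KEL1/KEL2", n_droplets = 2000, seed = 42)
#' tab <- simulate_well(p)
#' colSums(tab[, c("ch1_latent_pos", "ch2_latent_pos")])
simulate_well <- function(params, well_id = "sim_well",
                          include_truth = TRUE) {
  if (!inherits(params, "simulation_params")) {
    stop("'params' must come from simulation_params()", call. = FALSE)
  }
  lam <- channel_lambdas(params)
  n <- params$n_droplets
  with_local_seed(params$seed, {
    sim_channel <- function(lambda, model) {
      k <- stats::rpois(n, lambda)
      survivors <- k
      if (params$detection_dropout > 0) {
        survivors <- stats::rbinom(n, k, 1 - params$detection_dropout)
      }
      latent <- survivors >= 1L
      fp <- !latent & (stats::runif(n) < params$false_positive_rate)
      positive <- latent | fp
      list(molecules = k, latent = positive,
           amplitude = draw_amplitudes(positive, model, params$rain_prob))
    }
    ch1 <- sim_channel(lam[["ch1"]], params$amplitude_ch1)
    ch2 <- sim_channel(lam[["ch2"]], params$amplitude_ch2)
    df <- data.frame(ch1_amplitude = ch1$amplitude,
                     ch2_amplitude = ch2$amplitude)
    if (include_truth) {
      df$ch1_molecules <- ch1$molecules
      df$ch2_molecules <- ch2$molecules
      df$ch1_latent_pos <- ch1$latent
      df$ch2_latent_pos <- ch2$latent
    }
    new_droplet_table(df, well_id)
  })
}

#' Simulate a non-template control (NTC) well
#'
#' No target molecules are present; positives arise only from the
#' false-positive mechanism. A clean NTC is the basis for the
#' false-positive droplet limit applied by the caller's quality control.
#'
#' @param n_droplets Number of droplets.
#' @param false_positive_rate Per-droplet, per-channel false-positive
#'   probability.
#' @param amplitude_ch1,amplitude_ch2 Per-channel [amplitude_model]s.
#' @param rain_prob Rain probability for (false-)positive droplets.
#' @param seed Integer seed, or `NULL`.
#' @param well_id Identifier stored on the output.
#' @return A `droplet_table` with truth columns.
#' @export
simulate_ntc <- function(n_droplets = 15646, false_positive_rate = 2e-5,
                         amplitude_ch1 = amplitude_model(),
                         amplitude_ch2 = amplitude_model(),
                         rain_prob = 0.01, seed = NULL, well_id = "NTC") {
  if (!(is.numeric(n_droplets) && length(n_droplets) == 1L && n_droplets >= 1)) {
    stop("n_droplets must be a single count >= 1", call. = FALSE)
  }
  if (!(false_positive_rate >= 0 && false_positive_rate <= 1)) {
    stop("false_positive_rate must be a probability in [0, 1]", call. = FALSE)
  }
  n <- as.integer(round(n_droplets))
  with_local_seed(seed, {
    mk <- function(model) {
      positive <- stats::runif(n) < false_positive_rate
      list(latent = positive,
           amplitude = draw_amplitudes(positive, model, rain_prob))
    }
    ch1 <- mk(amplitude_ch1)
    ch2 <- mk(amplitude_ch2)
    df <- data.frame(ch1_amplitude = ch1$amplitude,
                     ch2_amplitude = ch2$amplitude,
                     ch1_molecules = 0L, ch2_molecules = 0L,
                     ch1_latent_pos = ch1$latent, ch2_latent_pos = ch2$latent)
    new_droplet_table(df, well_id)
  })
}
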