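#' Published well scenarios for the simulator
#'
#' One row per maternal/fetal genotype group of the study cohort, with
#' the group-mean droplet statistics used to calibrate simulated wells:
#' total droplets per well, the mean maternal-channel (or total-DNA
#' control) positive count, and the group-mean fetal fraction where one
#' was observable. The `cc` maternal group prints per-sample counts for
#' its two heterozygous fetuses; all other groups print group means, so
#' scenarios are calibrated to means.
#'
#' @return A data frame with columns `scenario`, `assay`, `maternal`,
#'   `fetal`, `n_droplets`, `msp_target` (mean maternal-channel positive
#'   droplets), `nominal_ff` (group-mean fetal fraction used when the
#'   caller does not supply one) and `fetus_carries_paternal` (whether
#'   the fetus carries the allele the mother lacks).
#' @export
published_scenarios <- function() {
  data.frame(
    scenario = c("RHDpos_on_RHDneg", "RHDneg_on_RHDneg",
                 "Ee_on_ee", "ee_on_ee",
                 "Cc_on_CC", "CC_on_CC",
                 "Cc_on_cc", "cc_on_cc",
                 "KEL1_on_KEL2", "KEL2_on_KEL2"),
    assay = c("RHD_ex7", "RHD_ex7",
              "RHCE_rs609320", "RHCE_rs609320",
              "RHCE_rs676785", "RHCE_rs676785",
              "RHCE_rs676785", "RHCE_rs676785",
              "KEL_rs8176058", "KEL_rs8176058"),
    maternal = c("RHD-/RHD-", "RHD-/RHD-", "ee", "ee",
                 "CC", "CC", "cc", "cc",
                 "KEL2/KEL2", "KEL2/KEL2"),
    fetal = c("RHD/RHD-", "RHD-/RHD-", "Ee", "ee",
              "Cc", "CC", "Cc", "cc",
              "KEL1/KEL2", "KEL2/KEL2"),
    n_droplets = c(15349L, 15698L, 13955L, 12527L,
                   14399L, 13608L, 14000L, 14000L,
                   15019L, 14953L),
    msp_target = c(1540, 1457, 1450, 792, 672, 938, 448, 695, 760, 625),
    nominal_ff = c(0.09, 0.09, 0.07, 0.07, 0.08, 0.08,
                   0.245, 0.245, 0.07, 0.07),
    fetus_carries_paternal = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                               TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build calibrated simulation parameters for a named scenario
#'
#' Back-solves the maternal genome occupancy so that the expected
#' maternal-channel positive count matches the scenario's published group
#' mean at the fetal fraction in use: with maternal-channel positive
#' probability `p = msp_target / n_droplets`, channel occupancy
#' `lambda = -log(1 - p)`, and `lambda_g = lambda / (c_m + f * c_f)`
#' where `c_m`/`c_f` are maternal/fetal allele copies on that channel.
#'
#' @param scenario A scenario name from [published_scenarios()].
#' @param fetal_fraction Fetal fraction to simulate; defaults to the
#'   scenario's `nominal_ff`.
#' @param fetal Override the fetal genotype (e.g. to simulate a negative
#'   fetus under a positive scenario's molecular load).
#' @param seed Integer seed for [simulation_params()].
#' @param ... Further arguments passed to [simulation_params()] (e.g.
#'   `false_positive_rate`, amplitude models).
#' @return A [simulation_params] object.
#' @export
#' @examples
#' p <- scenario_params("Cc_on_cc", seed = 7)
#' expected_counts(p)$ch1  # close to the published maternal-channel mean
scenario_params <- function(scenario, fetal_fraction = NULL, fetal = NULL,
                            seed = NULL, ...) {
  scen <- published_scenarios()
  row <- scen[scen$scenario == scenario, ]
  if (nrow(row) != 1L) {
    stop("unknown scenario '", scenario, "'; see published_scenarios()",
         call. = FALSE)
  }
  ctx <- maternal_context(row$assay, row$maternal)
  f <- fetal_fraction %||% row$nominal_ff
  fetal_gt <- parse_genotype(fetal %||% row$fetal)
  fs <- fetus_specific_channel(ctx)
  control <- fs$reference_is_total_dna
  c_m <- allele_copies(fs$maternal_allele, ctx$maternal_genotype, control)
  c_f <- allele_copies(fs$maternal_allele, fetal_gt, control)
  p <- row$msp_target / row$n_droplets
  lambda_chan <- -log(1 - p)
  lambda_g <- lambda_chan / (c_m + f * c_f)
  simulation_params(
    ctx = ctx, fetal_genotype = fetal_gt,
    n_droplets = row$n_droplets,
    maternal_genomes_per_droplet = lambda_g,
    fetal_fraction_true = f,
    seed = seed, ...
  )
}
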