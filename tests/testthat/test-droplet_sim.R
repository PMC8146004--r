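ctx_cc <- maternal_context("RHCE_rs676785", "cc")

test_that("simulation is reproducible for a fixed seed and explicit about its stream", {
  p <- simulation_params(ctx_cc, "Cc", n_droplets = 2000, seed = 11)
  a <- simulate_well(p)
  b <- simulate_well(p)
  expect_identical(a, b)
  p2 <- simulation_params(ctx_cc, "Cc", n_droplets = 2000, seed = 12)
  expect_false(identical(simulate_well(p2), a))
  # the caller's RNG stream is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_well(p))
  expect_identical(runif(1), before)
})

test_that("a fetus matching the homozygous mother yields no fetus-specific molecules", {
  p <- simulation_params(ctx_cc, "cc", n_droplets = 5000,
                         fetal_fraction_true = 0,
                         false_positive_rate = 0, seed = 4)
  tab <- simulate_well(p)
  # HEX detects C, which neither genome carries
  expect_equal(sum(tab$ch2_latent_pos), 0)
  expect_equal(sum(tab$ch2_molecules), 0)
  expect_gt(sum(tab$ch1_latent_pos), 0)
})

test_that("expected_counts matches the closed-form positive probability", {
  # a channel with no target and no false positives expects zero
  p0 <- simulation_params(ctx_cc, "cc", n_droplets = 10000,
                          fetal_fraction_true = 0, false_positive_rate = 0)
  expect_equal(expected_counts(p0)$ch2, 0)

  # an empty channel with fp = 1.5e-4 in 15,000 droplets expects 2.25
  pf <- simulation_params(ctx_cc, "cc", n_droplets = 15000,
                          fetal_fraction_true = 0,
                          false_positive_rate = 1.5e-4)
  expect_equal(expected_counts(pf)$ch2, 15000 * 1.5e-4)

  # occupancy 0.05: n * (1 - exp(-0.05)) = 487.706 of 10,000
  p5 <- simulation_params(ctx_cc, "cc", n_droplets = 10000,
                          maternal_genomes_per_droplet = 0.025,
                          fetal_fraction_true = 0, false_positive_rate = 0)
  expect_equal(channel_lambdas(p5)[["ch1"]], 0.05)
  expect_equal(expected_counts(p5)$ch1, 10000 * (1 - exp(-0.05)),
               tolerance = 1e-12)
  expect_equal(expected_counts(p5)$ch1, 487.7058, tolerance = 1e-4)

  # dropout thins the effective occupancy
  pd <- simulation_params(ctx_cc, "cc", n_droplets = 10000,
                          maternal_genomes_per_droplet = 0.025,
                          fetal_fraction_true = 0, false_positive_rate = 0,
                          detection_dropout = 0.5)
  expect_equal(expected_counts(pd)$ch1, 10000 * (1 - exp(-0.025)))
})

test_that("simulated channel counts track the analytic expectation across replicates", {
  # maternal-channel positives near 700 of 14,000, heterozygous fetus
  p <- simulation_params(ctx_cc, "Cc", n_droplets = 14000,
                         maternal_genomes_per_droplet = 0.0256,
                         fetal_fraction_true = 0.08, seed = NULL)
  ec <- expected_counts(p)
  lo1 <- qbinom(0.005, p$n_droplets, ec$p_ch1)
  hi1 <- qbinom(0.995, p$n_droplets, ec$p_ch1)
  lo2 <- qbinom(0.005, p$n_droplets, ec$p_ch2)
  hi2 <- qbinom(0.995, p$n_droplets, ec$p_ch2)
  set.seed(2024)
  in1 <- 0L; in2 <- 0L
  for (i in 1:50) {
    tab <- simulate_well(p)
    n1 <- sum(tab$ch1_latent_pos)
    n2 <- sum(tab$ch2_latent_pos)
    in1 <- in1 + (n1 >= lo1 && n1 <= hi1)
    in2 <- in2 + (n2 >= lo2 && n2 <= hi2)
  }
  # 99% intervals: expect ~49.5/50 inside; allow a small margin
  expect_gte(in1, 47)
  expect_gte(in2, 47)
})

test_that("every droplet falls in exactly one latent joint class", {
  p <- simulation_params(ctx_cc, "Cc", n_droplets = 8000,
                         fetal_fraction_true = 0.1, seed = 31)
  tab <- simulate_well(p)
  pp <- tab$ch1_latent_pos & tab$ch2_latent_pos
  pn <- tab$ch1_latent_pos & !tab$ch2_latent_pos
  np <- !tab$ch1_latent_pos & tab$ch2_latent_pos
  nn <- !tab$ch1_latent_pos & !tab$ch2_latent_pos
  expect_equal(sum(pp) + sum(pn) + sum(np) + sum(nn), nrow(tab))
  expect_true(all(pp + pn + np + nn == 1L))
  expect_true(all(is.finite(tab$ch1_amplitude)) &&
                all(tab$ch1_amplitude >= 0))
})

test_that("expected fetus-specific positives increase strictly with fetal fraction", {
  fs <- seq(0.02, 0.26, by = 0.04)
  exp_fsp <- vapply(fs, function(f) {
    p <- simulation_params(ctx_cc, "Cc", fetal_fraction_true = f)
    expected_counts(p)$ch2
  }, numeric(1))
  expect_true(all(diff(exp_fsp) > 0))
})

test_that("NTC wells contain only false-positive noise", {
  clean <- simulate_ntc(n_droplets = 15000, false_positive_rate = 0,
                        seed = 5)
  expect_equal(sum(clean$ch1_latent_pos) + sum(clean$ch2_latent_pos), 0)
  expect_identical(clean, simulate_ntc(n_droplets = 15000,
                                       false_positive_rate = 0, seed = 5))

  # at fp = 1.5e-5 in 15,646 droplets, positives should essentially
  # always land in 0..4 (Poisson mean 0.23 per channel)
  maxima <- vapply(1:30, function(s) {
    tab <- simulate_ntc(15646, 1.5e-5, seed = 1000 + s)
    max(sum(tab$ch1_latent_pos), sum(tab$ch2_latent_pos))
  }, numeric(1))
  expect_true(all(maxima <= 4))
})

test_that("parameter validation rejects impossible inputs", {
  expect_error(simulation_params(ctx_cc, "CC"),
               "shares no allele")
  expect_error(simulation_params(ctx_cc, "Cc", n_droplets = 0),
               "n_droplets")
  expect_error(simulation_params(ctx_cc, "Cc", rain_prob = 1.5),
               "probability")
  expect_error(simulation_params(ctx_cc, "Cc",
                                 maternal_genomes_per_droplet = 0),
               "maternal_genomes_per_droplet")
  expect_error(simulate_ntc(n_droplets = 0), "n_droplets")
  expect_error(amplitude_model(pos_mean = 500, neg_mean = 1000),
               "must exceed")
})

test_that("scenario calibration reproduces the published maternal-channel means", {
  scen <- published_scenarios()
  for (i in seq_len(nrow(scen))) {
    p <- scenario_params(scen$scenario[i])
    ec <- expected_counts(p)
    fs <- fetus_specific_channel(p$ctx)
    msp_expected <- if (fs$maternal_channel == "FAM") ec$ch1 else ec$ch2
    expect_equal(msp_expected, scen$msp_target[i], tolerance = 0.02,
                 label = scen$scenario[i])
  }
})
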