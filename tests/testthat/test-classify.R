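test_that("auto threshold agrees with the exhaustive two-means oracle on separable clouds", {
  set.seed(7)
  amps <- c(rnorm(900, 1000, 150), rnorm(100, 8000, 400))
  res <- auto_threshold(amps)
  oracle <- oracle_two_means(amps)
  expect_true(res$bimodal)
  expect_equal(res$cutoff, (oracle$mean_lo + oracle$mean_hi) / 2)
  expect_equal(res$ss_ratio, oracle$total_ss / oracle$within_ss)
  expect_gt(res$cutoff, 4000)
  expect_lt(res$cutoff, 5000)
})

test_that("a single negative cloud falls back to a cutoff above all droplets", {
  set.seed(8)
  amps <- rnorm(5000, 1000, 150)
  res <- auto_threshold(amps)
  expect_false(res$bimodal)
  expect_gt(res$cutoff, max(amps))
})

test_that("degenerate constant amplitudes classify as all-negative", {
  amps <- rep(1000, 500)
  res <- auto_threshold(amps)
  expect_false(res$bimodal)
  expect_equal(res$cutoff, 1000)
  tab <- data.frame(ch1_amplitude = amps, ch2_amplitude = amps)
  counts <- classify_droplets(tab, channel_cutoffs(res$cutoff, res$cutoff))
  expect_equal(counts$n_neg, 500L)
  expect_equal(counts$n_ch1_pos, 0L)
})

test_that("thresholding refuses tiny wells", {
  expect_error(auto_threshold(rnorm(50, 1000, 100)), "at least 100")
})

test_that("classification reproduces a hand-enumerated six-droplet well", {
  tab <- data.frame(
    ch1_amplitude = c(500, 9000, 950, 8800, 400, 700),
    ch2_amplitude = c(900, 800, 8500, 9100, 300, 600)
  )
  counts <- classify_droplets(tab, channel_cutoffs(4500, 4500))
  expect_equal(counts$n_total, 6L)
  expect_equal(counts$n_ch1_pos, 2L)
  expect_equal(counts$n_ch2_pos, 2L)
  expect_equal(counts$n_double_pos, 1L)
  expect_equal(counts$n_neg, 3L)
})

test_that("vectorized classification matches a per-droplet loop exactly on random wells", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 1000
    ch1 <- runif(n, 0, 10000)
    ch2 <- runif(n, 0, 10000)
    cut1 <- runif(1, 1000, 9000)
    cut2 <- runif(1, 1000, 9000)
    tab <- data.frame(ch1_amplitude = ch1, ch2_amplitude = ch2)
    counts <- classify_droplets(tab, channel_cutoffs(cut1, cut2))
    oracle <- oracle_classify_loop(ch1, ch2, cut1, cut2)
    expect_identical(counts$n_ch1_pos, oracle$n_ch1_pos)
    expect_identical(counts$n_ch2_pos, oracle$n_ch2_pos)
    expect_identical(counts$n_double_pos, oracle$n_double_pos)
    expect_identical(counts$n_neg, oracle$n_neg)
    # conservation holds on every random well
    expect_equal(counts$n_ch1_pos + counts$n_ch2_pos -
                   counts$n_double_pos + counts$n_neg, counts$n_total)
  }
})

test_that("classification is order-invariant and monotone in the cutoff", {
  set.seed(9)
  tab <- make_test_table(800, 100, 60, 40)
  cuts <- channel_cutoffs(4500, 4500)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- classify_droplets(tab, cuts)
  b <- classify_droplets(shuffled, cuts)
  expect_equal(a$n_ch1_pos, b$n_ch1_pos)
  expect_equal(a$n_double_pos, b$n_double_pos)
  expect_equal(a$n_neg, b$n_neg)

  pos_at <- vapply(c(500, 2000, 4500, 7000, 9500), function(cut) {
    classify_droplets(tab, channel_cutoffs(cut, 4500))$n_ch1_pos
  }, integer(1))
  expect_true(all(diff(pos_at) <= 0))
})

test_that("ties at the cutoff classify negative (conservative direction)", {
  tab <- data.frame(ch1_amplitude = c(4500, 4500.0001),
                    ch2_amplitude = c(100, 100))
  counts <- classify_droplets(tab, channel_cutoffs(4500, 4500))
  expect_equal(counts$n_ch1_pos, 1L)
})

test_that("count containers enforce their invariants", {
  expect_error(classified_counts(100, 10, 10, 0, n_neg = 50),
               "conservation")
  expect_error(classified_counts(100, 5, 10, 8), "exceeds")
  expect_error(classified_counts(100, -1, 0, 0), "non-negative")
  expect_error(classify_droplets(data.frame(ch1_amplitude = numeric(),
                                            ch2_amplitude = numeric()),
                                 channel_cutoffs(1, 1)),
               "empty")
  # n_neg derived from conservation when omitted
  cc <- classified_counts(100, 10, 10, 5)
  expect_equal(cc$n_neg, 85L)
})

test_that("manual cutoffs override the automatic threshold with recorded provenance", {
  set.seed(10)
  tab <- make_test_table(900, 80, 20)
  auto <- auto_cutoffs(tab)
  expect_equal(auto$ch1_method, "auto")
  mixed <- auto_cutoffs(tab, ch2_manual = 3000)
  expect_equal(mixed$ch2_method, "manual")
  expect_equal(mixed$ch2_cutoff, 3000)
  expect_equal(mixed$ch1_cutoff, auto$ch1_cutoff)
})
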