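# economical synthetic sessions used across these tests
small_session <- function(seed, gain = 0, n = 60, prob0 = 0, ...) {
  synthesize_dff_dataset(n_neurons = n, seed = seed, block_mins = c(3, 6, 3),
                         drift_prob0 = prob0, drift_coupling_gain = gain, ...)
}

test_that("the synthetic generator is reproducible and structured as a session", {
  ds1 <- small_session(7)
  ds2 <- small_session(7)
  expect_identical(ds1$dff, ds2$dff)
  expect_identical(ds1$stim_table, ds2$stim_table)
  expect_false(identical(ds1$dff, small_session(8)$dff))
  # gratings only inside the first and last blocks
  expect_true(all(ds1$stim_table$start_frame <= max(ds1$blocks$first) |
                    ds1$stim_table$start_frame >= min(ds1$blocks$last)))
  expect_lt(max(ds1$blocks$first), min(ds1$blocks$last))
  gt <- attr(ds1, "ground_truth")
  expect_length(gt$coupling, 60)
  expect_true(all(gt$pref_first %in% seq(0, 315, by = 45)))
})

test_that("session QC excludes small and unstable recordings", {
  tiny <- small_session(1, n = 49)
  qc <- qc_experiment(tiny)
  expect_false(qc$include)
  expect_equal(qc$reason, "too few neurons")

  # strong shared signal: split-half couplings agree
  good <- small_session(2)
  expect_true(qc_experiment(good, seed = 3)$include)

  # independent noise only: couplings are noise, halves disagree
  lone <- small_session(3, coupling_mean = 0, coupling_sd = 0, amp_mean = 0,
                        noise_sd = 0.5)
  qc2 <- qc_experiment(lone, seed = 3)
  expect_false(qc2$include)
  expect_lt(qc2$r2, 0.8)
})

test_that("population coupling from dF/F recovers planted coupling weights", {
  ds <- small_session(11)
  gt <- attr(ds, "ground_truth")
  pc <- pc_from_dff(ds)
  expect_gt(cor(pc, gt$coupling, method = "spearman", use = "complete.obs"), 0.8)
  # a neuron's own coupling is invariant to affine rescaling of its trace
  ds2 <- ds
  ds2$dff[1, ] <- 3 * ds$dff[1, ] - 2
  expect_equal(pc_from_dff(ds2)[1], pc[1], tolerance = 1e-10)
  # two-neuron hand example equals the plain Pearson correlation
  d2 <- calcium_dataset(ds$dff[1:2, ], ds$frame_rate, ds$stim_table, ds$blocks)
  expect_equal(pc_from_dff(d2)[1], cor(ds$dff[1, ], ds$dff[2, ]),
               tolerance = 1e-12)
})

test_that("preferred gratings are recovered and ties break toward smaller angles", {
  ds <- synthesize_dff_dataset(n_neurons = 60, seed = 5,
                               drift_prob0 = 0, drift_coupling_gain = 0)
  gt <- attr(ds, "ground_truth")
  p1 <- preferred_grating(ds, block = "first", attribute = "direction")
  p2 <- preferred_grating(ds, block = "last", attribute = "direction")
  # high-SNR neurons (planted amplitude above median) recovered >= 95%
  snr <- gt$amplitude > median(gt$amplitude)
  expect_gte(mean(p1[snr] == gt$pref_first[snr]), 0.95)
  expect_gte(mean(p2[snr] == gt$pref_last[snr]), 0.95)

  # constructed exact tie: two gratings, identical responses
  dff <- matrix(0, 2, 100)
  tab <- data.frame(type = "drifting", orientation_deg = c(0, 90, 0, 90),
                    direction_deg = c(0, 90, 0, 90), sf = 0.04, tf = 2,
                    phase = 0, start_frame = c(1, 11, 81, 91),
                    end_frame = c(10, 20, 90, 100))
  dff[, c(1:20, 81:100)] <- 1   # equal response to both gratings
  d <- calcium_dataset(dff, 10, tab, list(first = 1:40, last = 61:100))
  expect_equal(preferred_grating(d, 1, "first", "direction"), 0)
  expect_error(preferred_grating(
    calcium_dataset(dff, 10, tab[1:2, ], list(first = 1:40, last = 61:100)),
    1, "last"), "no grating")
})

test_that("preference change is the literal absolute difference with a circular option", {
  expect_equal(delta_pref(60, 60), 0)
  expect_equal(delta_pref(30, 90), 60)
  expect_equal(delta_pref(0, 150), 150)
  expect_equal(delta_pref(0, 150, circular = TRUE), 30)
  expect_equal(delta_pref(0, 270, circular = TRUE, period = 360), 90)
})

test_that("response reliability separates repeatable from noise-driven neurons", {
  ds <- small_session(6, amp_mean = 2, noise_sd = 0.05, coupling_mean = 0,
                      coupling_sd = 0)
  rel_hi <- response_reliability(ds, attribute = "direction")
  dsn <- small_session(6, amp_mean = 0, noise_sd = 0.5)
  rel_lo <- response_reliability(dsn, attribute = "direction")
  expect_gt(mean(rel_hi, na.rm = TRUE), 0.6)
  expect_lt(abs(mean(rel_lo, na.rm = TRUE)), 0.1)
})

test_that("the median-reliability filter includes half the neurons", {
  ds <- small_session(9)
  res <- analyze_calcium(ds, attribute = "direction")
  expect_s3_class(res, "drift_result")
  expect_equal(sum(res$included), nrow(res) %/% 2)
  # 75% and 100% inclusion variants
  res75 <- analyze_calcium(ds, attribute = "direction",
                           reliability_quantile = 0.75)
  expect_equal(sum(res75$included), floor(nrow(res) * 0.75))
  res100 <- analyze_calcium(ds, attribute = "direction",
                            reliability_quantile = 1)
  expect_equal(sum(res100$included), nrow(res))
  expect_true(all(res$delta_pref == abs(res$pref_first - res$pref_last)))
})

test_that("drift statistics recover a planted coupling-drift link and not a null", {
  link <- lapply(1:14, function(s)
    analyze_calcium(small_session(100 + s, gain = 3), "direction", seed = s))
  st <- drift_statistics(link)
  expect_gt(st$spearman_r, 0)
  expect_lt(st$spearman_p, 0.01)
  expect_gt(st$mean_ratio, 1)

  null <- lapply(1:8, function(s)
    analyze_calcium(small_session(200 + s, gain = 0), "direction", seed = s))
  st0 <- drift_statistics(null)
  expect_lt(abs(st0$mean_ratio - 1), 0.15)

  # degenerate inputs: all preferences conserved -> sessions skipped
  frozen <- analyze_calcium(small_session(301, gain = 0, amp_mean = 3,
                                          noise_sd = 0.05,
                                          prob0 = -30), "direction")
  expect_true(all(frozen$delta_pref[frozen$included] == 0))
  expect_error(drift_statistics(list(NULL)), "no included sessions")
  st_skip <- drift_statistics(list(frozen, link[[1]]))
  expect_equal(st_skip$n_sessions_skipped, 1L)
})

test_that("calcium datasets round-trip through plain-text serialization", {
  ds <- small_session(4, n = 50)
  dir <- file.path(tempdir(), "ca-roundtrip")
  write_calcium_dataset(ds, dir)
  ds2 <- read_calcium_dataset(dir)
  expect_equal(ds2$dff, ds$dff)
  expect_equal(ds2$frame_rate, ds$frame_rate)
  expect_equal(ds2$stim_table$orientation_deg, ds$stim_table$orientation_deg)
  expect_equal(range(ds2$blocks$first), range(ds$blocks$first))
})
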