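test_that("population coupling is the leave-self-out Pearson correlation", {
  # identical fluctuating traces: PC = 1 for every neuron
  x <- matrix(rep(sin(1:200), 5), 5, byrow = TRUE)
  expect_equal(as.vector(population_coupling(x)), rep(1, 5), tolerance = 1e-12)

  # scalar oracle on a 3-neuron, 4-timepoint example
  a <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                5, 5, 6, 4), 3, 4, byrow = TRUE)
  pc <- population_coupling(a)
  for (i in 1:3)
    expect_equal(pc[i], reference_pearson(a[i, ], colMeans(a[-i, , drop = FALSE])),
                 tolerance = 1e-12)

  # an independent neuron among co-fluctuating ones has |PC| < 3/sqrt(T)
  set.seed(4)
  T <- 4000
  shared <- rnorm(T)
  m <- rbind(t(replicate(9, shared + 0.2 * rnorm(T))), rnorm(T))
  pc2 <- population_coupling(m)
  expect_lt(abs(pc2[10]), 3 / sqrt(T))
  expect_true(all(pc2[1:9] > 0.8))

  # zero-variance trace flagged, not zeroed
  z <- rbind(shared[1:50], rep(2, 50), shared[1:50] * 2)
  pcz <- population_coupling(z)
  expect_true(is.na(pcz[2]))
  expect_equal(attr(pcz, "n_undefined"), 1L)

  # a neuron's own coupling is invariant to affine rescaling of its trace
  # (the leave-self-out reference of the others is unchanged)
  y <- matrix(rnorm(400), 4)
  y2 <- y
  y2[3, ] <- 0.5 * y[3, ] + 4
  pcy <- population_coupling(y)
  pcy2 <- population_coupling(y2)
  expect_equal(pcy2[3], pcy[3], tolerance = 1e-12)
})

test_that("connection specificity is the specific/non-specific input ratio", {
  prefs <- rep(1:2, each = 3)
  W <- matrix(0.021, 6, 6); diag(W) <- 0
  expect_equal(as.vector(connection_specificity(W, prefs)), rep(1, 6))
  W2 <- W
  for (i in 1:6) {
    W2[i, prefs == prefs[i]] <- 0.042
    W2[i, prefs != prefs[i]] <- 0.021
  }
  diag(W2) <- 0
  expect_equal(as.vector(connection_specificity(W2, prefs)), rep(2, 6))
  # zero non-specific mean flagged
  W3 <- W2; W3[1, prefs != 1] <- 0
  expect_true(is.na(connection_specificity(W3, prefs)[1]))
  # scalar-loop oracle on a random matrix
  set.seed(11)
  Wr <- matrix(runif(100), 10, 10); diag(Wr) <- 0
  pr <- rep(1:2, 5)
  expect_equal(as.vector(connection_specificity(Wr, pr)),
               reference_specificity(Wr, pr), tolerance = 1e-14)
})

test_that("specificity fluctuations use the population-std convention over the window", {
  rec <- rbind(rep(2, 302), rep(c(1, 3), length.out = 302))
  times <- 200:501
  fl <- specificity_fluctuations(rec, times, t_end = 501)
  expect_equal(fl[1], 0)
  expect_equal(fl[2], 1)          # |a - b| / 2 = 1 for alternating 1, 3
  expect_error(specificity_fluctuations(rec[, 1:2, drop = FALSE], c(200, 201),
                                        t_start = 300, t_end = 500), "snapshots")
  # window restriction: values outside [t_start, t_end] ignored
  rec2 <- cbind(matrix(100, 2, 10), rec)
  expect_equal(specificity_fluctuations(rec2, c(1:10, times), t_end = 501), fl)
})

test_that("selectivity is the same-orientation minus different-orientation mean input", {
  ori <- rep(1:2, each = 3)
  W <- matrix(0.01, 6, 6); diag(W) <- 0
  expect_equal(as.vector(rf_selectivity(W, ori)), rep(0, 6))
  W2 <- W
  for (i in 1:6) W2[i, ori == ori[i]] <- 0.03
  diag(W2) <- 0
  expect_equal(as.vector(rf_selectivity(W2, ori)), rep(0.02, 6))
  set.seed(12)
  Wr <- matrix(runif(100), 10, 10); diag(Wr) <- 0
  orr <- rep(1:5, 2)
  expect_equal(as.vector(rf_selectivity(Wr, orr)),
               reference_selectivity(Wr, orr), tolerance = 1e-14)
  # a neuron with no same-orientation partner is flagged
  expect_true(is.na(rf_selectivity(Wr, c(1, rep(2, 9)))[1]))
})

test_that("feedforward and associated selectivity ratios match a scalar oracle", {
  prefs <- rep(1:2, each = 3)
  W <- matrix(0.01, 6, 6); diag(W) <- 0
  sel <- association_selectivity(W, prefs, assoc = 2)
  expect_equal(unname(sel$ff), rep(0, 6))
  expect_equal(unname(sel$assoc), rep(0, 6))
  set.seed(13)
  Wr <- matrix(runif(64, 0, 0.04), 8, 8); diag(Wr) <- 0
  pr <- rep(1:4, 2)
  s2 <- association_selectivity(Wr, pr, assoc = 3)
  for (i in 1:8) {
    same <- setdiff(which(pr == pr[i]), i)
    diff <- which(pr != pr[i])
    expect_equal(s2$ff[i], mean(Wr[i, same]) / mean(Wr[i, diff]) - 1,
                 tolerance = 1e-14)
    agrp <- setdiff(which(pr == 3), i)
    rest <- setdiff(seq_len(8), c(agrp, i))
    expect_equal(s2$assoc[i], mean(Wr[i, agrp]) / mean(Wr[i, rest]) - 1,
                 tolerance = 1e-14)
  }
})

test_that("the variance comparison detects unequal spread and not equal spread", {
  set.seed(14)
  a <- rnorm(500); b <- rnorm(500)
  same <- compare_distributions(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  # power: sd 1 vs sd 3 at n = 500 rejects comfortably
  wide <- compare_distributions(a, rnorm(500, sd = 3))
  expect_lt(wide$p.value, 0.01)
  expect_lt(wide$var_a, wide$var_b)
  null <- compare_distributions(a, b)
  expect_gt(null$p.value, 1e-4)
})

test_that("rank correlation handles perfect order, ties and missing pairs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(rank_correlation(x, x)$r, 1)
  expect_equal(rank_correlation(x, -x)$r, -1)
  # tie case against brute-force average ranks
  xt <- c(1, 2, 2, 3); yt <- c(1, 3, 2, 4)
  expect_equal(rank_correlation(xt, yt)$r, reference_spearman(xt, yt),
               tolerance = 1e-12)
  # NA pairs removed
  xn <- c(x, NA); yn <- c(-x, 5)
  expect_equal(rank_correlation(xn, yn)$r, -1)
  expect_equal(rank_correlation(xn, yn)$n, 6)
  # constant input flagged
  expect_true(is.na(rank_correlation(rep(1, 5), 1:5)$r))
  expect_error(rank_correlation(c(1, NA, NA, NA), c(1, 2, 3, 4)), "pairs")
})

test_that("trace specificity channel converts to ratio and difference series", {
  cfg <- network_config(sigma_ou = 0)
  net <- make_test_net(6, 2, cfg, alpha = 2e-4)
  prog <- make_schedule(2, 4000, 500, seed = 1)
  tr <- run_network(net, prog, plastic = TRUE, seed = 1, group_record_ms = 1000)
  ts <- trace_specificity(tr)
  expect_equal(dim(ts$specificity), c(6, 4))
  expect_equal(ts$times, 1:4)
  # consistency with the endpoint weight matrix at the last sample
  W <- tr$weights[1:6, 1:6]
  expect_equal(ts$selectivity[, 4], as.vector(rf_selectivity(W, net$prefs)),
               tolerance = 1e-12)
  expect_equal(ts$specificity[, 4], as.vector(connection_specificity(W, net$prefs)),
               tolerance = 1e-12)
})
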