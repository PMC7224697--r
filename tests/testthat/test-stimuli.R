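test_that("discrete-stimulus input is a Kronecker delta plus noise", {
  prefs <- rep(1:4, each = 3)
  H <- fc_input(prefs, stim = 2, h_stim = 8)
  expect_equal(H, as.numeric(prefs == 2) * 8)
  expect_equal(fc_input(prefs, 2, 8, noise = 0.5), H + 0.5)
  # noise-only epoch: H equals the noise vector exactly
  nz <- rnorm(12)
  expect_equal(fc_input(prefs, 2, 0, nz), nz)
  expect_error(fc_input(prefs, 9, 8), "unknown stimulus")
  # superposition: linear in (h_stim, noise)
  a <- fc_input(prefs, 1, 3, nz); b <- fc_input(prefs, 1, 5, 2 * nz)
  expect_equal(a + fc_input(prefs, 1, 2, nz), b)
})

test_that("association input adds a global drive only when the associated stimulus is shown", {
  prefs <- c(1, 1, 2, 2)
  H <- association_input(prefs, stim = 1, assoc = 1, h_assoc = 10, h_stim = 8)
  expect_equal(H, c(18, 18, 10, 10))
  expect_equal(association_input(prefs, 2, assoc = 1, h_assoc = 10, h_stim = 8),
               fc_input(prefs, 2, 8))
  expect_equal(association_input(prefs, 1, assoc = 1, h_assoc = 0, h_stim = 8),
               fc_input(prefs, 1, 8))
  expect_equal(association_input(prefs, 1, assoc = NA, h_assoc = 10, h_stim = 8),
               fc_input(prefs, 1, 8))
})

test_that("Gabor receptive fields evaluate the rotated Gaussian-carrier form", {
  grid <- gabor_grid(9, 1)   # odd size: lattice contains the origin
  # at the origin the raw value is A cos(phi)
  p <- gabor_params(A = 2, theta = 0.3, phi = 0.7)
  rf <- gabor_rf(p, grid, normalize = FALSE)
  expect_equal(rf[5, 5], 2 * cos(0.7))
  expect_equal(gabor_rf(gabor_params(phi = pi / 2), grid, normalize = FALSE)[5, 5], 0)

  # scalar-loop oracle at every lattice point
  p2 <- gabor_params(A = 1.5, sigma_x = 0.4, sigma_y = 0.6, theta = 1.1,
                     f = 2, phi = 0.25)
  rf2 <- gabor_rf(p2, grid, normalize = FALSE)
  for (i in c(1, 3, 7)) for (j in c(2, 5, 9)) {
    x <- grid$x[i, j]; y <- grid$y[i, j]
    xp <- x * cos(1.1) - y * sin(1.1)
    yp <- x * sin(1.1) + y * cos(1.1)
    expect_equal(rf2[i, j],
                 1.5 * exp(-xp^2 / (2 * 0.4^2) - yp^2 / (2 * 0.6^2)) *
                   cos(2 * pi * 2 * xp + 0.25),
                 tolerance = 1e-12)
  }

  # rotating by pi/2 permutes the axes (coordinate-rotation oracle):
  # RF_{pi/2}(x, y) = RF_0(-y, x)
  p0 <- gabor_params(theta = 0, phi = 0.4)
  p90 <- gabor_params(theta = pi / 2, phi = 0.4)
  rf0 <- gabor_rf(p0, grid, normalize = FALSE)
  rf90 <- gabor_rf(p90, grid, normalize = FALSE)
  n <- 9
  for (i in 1:n) for (j in 1:n) {
    # grid: x varies with row, y with column; (x,y) -> (-y, x) maps
    # entry [i, j] (x = u[i], y = u[j]) to x' = -u[j] = u[n+1-j], y' = u[i]
    expect_equal(rf90[i, j], rf0[n + 1 - j, i], tolerance = 1e-12)
  }

  # normalized patches have unit Frobenius norm
  expect_equal(sqrt(sum(gabor_rf(p2, grid)^2)), 1)
})

test_that("receptive-field ensembles use the fixed frequency, width and orientation set", {
  ens <- sample_rf_ensemble(250, seed = 5)
  expect_length(ens, 250)
  expect_true(all(vapply(ens, `[[`, 0, "f") == 2))
  expect_true(all(vapply(ens, `[[`, 0, "sigma_x") == 0.5))
  expect_true(all(vapply(ens, `[[`, 0, "sigma_y") == 0.5))
  th <- vapply(ens, `[[`, 0, "theta")
  expect_true(all(round(th / (pi / 4), 10) %% 1 == 0))
  expect_equal(sort(unique(round(th / (pi / 4)))), 1:8)
  ph <- vapply(ens, `[[`, 0, "phi")
  expect_true(all(ph >= 0 & ph < 2 * pi))
  # determinism
  ens2 <- sample_rf_ensemble(250, seed = 5)
  expect_identical(ens, ens2)
  expect_false(identical(ens, sample_rf_ensemble(250, seed = 6)))
})

test_that("image projection is the pixel-wise dot product", {
  grid <- gabor_grid(16)
  rf <- gabor_rf(gabor_params(theta = pi / 4, phi = 1), grid)
  expect_equal(image_input(rf, rf), sum(rf^2))
  expect_equal(image_input(matrix(0, 16, 16), rf, noise = 0.3), 0.3)
  # a quarter-period phase shift gives a near-orthogonal patch
  rf_q <- gabor_rf(gabor_params(theta = pi / 4, phi = 1 + pi / 2), grid)
  expect_lt(abs(image_input(rf_q, rf)), 0.05 * sum(rf^2))
  expect_error(image_input(matrix(0, 4, 4), rf), "shape")
})

test_that("oriented bars drive matched receptive fields most strongly", {
  grid <- gabor_grid(16)
  # orientation, not direction
  expect_equal(make_bar_image(pi / 4, grid), make_bar_image(pi / 4 + pi, grid))
  # norm roughly orientation-independent
  norms <- vapply(rf_orientations(), function(th)
    sqrt(sum(make_bar_image(th, grid)^2)), 0)
  expect_lt(diff(range(norms)) / mean(norms), 0.11)
  # expected |drive| over phase: same orientation beats orthogonal
  set.seed(3)
  phis <- runif(200, 0, 2 * pi)
  for (th in c(pi / 4, pi / 2)) {
    bar <- make_bar_image(th, grid)
    same <- mean(abs(vapply(phis, function(p)
      image_input(bar, gabor_rf(gabor_params(theta = th, phi = p), grid)), 0)))
    orth <- mean(abs(vapply(phis, function(p)
      image_input(bar, gabor_rf(gabor_params(theta = th + pi / 2, phi = p),
                                grid)), 0)))
    expect_gt(same, orth)
  }
})

test_that("stimulus schedules are uniform, epoch-aligned and reproducible", {
  prog <- make_schedule(4, 500000, 500, seed = 10)
  expect_length(prog$schedule, 1000)
  expect_true(all(prog$schedule %in% 1:4))
  # empirical frequencies consistent with uniform (chi-square)
  expect_gt(chisq.test(table(factor(prog$schedule, 1:4)))$p.value, 0.001)
  expect_identical(prog$schedule, make_schedule(4, 500000, 500, seed = 10)$schedule)
  expect_error(make_schedule(4, 1234, 500), "not TRUE")

  # association track: re-drawn every switch period, off before onset
  pa <- make_schedule(4, 100000, 500, seed = 2, assoc_switch_ms = 25000,
                      assoc_onset_ms = 50000)
  expect_true(all(pa$assoc[1:100] == 0))          # first 50 s off
  on <- pa$assoc[101:200]
  expect_true(all(on %in% 1:4))
  expect_equal(length(unique(on[1:50])), 1)       # constant within 25 s
  expect_true(all(table(rep(seq_len(4), 50)[1]) >= 0))
})

test_that("drive matrices assemble per-stimulus columns", {
  prefs <- rep(1:2, each = 2)
  D <- fc_drive_matrix(prefs, 2, h_stim = 8)
  expect_equal(D, cbind(c(8, 8, 0, 0), c(0, 0, 8, 8)))
  ens <- sample_rf_ensemble(5, seed = 1)
  grid <- gabor_grid(16)
  D2 <- rf_drive_matrix(ens, grid)
  expect_equal(dim(D2), c(5, 8))
  expect_equal(D2[3, 2],
               image_input(make_bar_image(rf_orientations()[2], grid),
                           gabor_rf(ens[[3]], grid)))
})
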