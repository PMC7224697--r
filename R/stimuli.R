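#' Discrete-stimulus feedforward input
#'
#' External input to the excitatory population for a discrete stimulus:
#' \code{H_i = h_stim} for neurons whose preferred stimulus matches the one
#' shown (Kronecker delta) plus each neuron's noise sample. Inhibitory
#' neurons receive no feedforward drive.
#'
#' @param prefs integer preferred-stimulus label per excitatory neuron
#'   (1-based).
#' @param stim stimulus identifier shown (1-based).
#' @param h_stim preferred-stimulus drive amplitude.
#' @param noise per-neuron noise samples (default 0).
#' @return Input vector, one entry per excitatory neuron.
#' @examples
#' fc_input(c(1, 1, 2, 2), stim = 1, h_stim = 8)
#' @export
fc_input <- function(prefs, stim, h_stim = 8, noise = 0) {
  stopifnot(length(stim) == 1L)
  if (!(stim %in% prefs) && (stim < 1 || stim > max(prefs)))
    stop("unknown stimulus id: ", stim)
  as.numeric(prefs == stim) * h_stim + rep_len(noise, length(prefs))
}

#' Feedforward input with a stimulus association
#'
#' As \code{\link{fc_input}}, plus an association term: whenever the shown
#' stimulus equals the associated stimulus, an extra drive \code{h_assoc} is
#' delivered to \emph{all} excitatory neurons (modelling a reward or top-down
#' signal during perceptual learning).
#'
#' @inheritParams fc_input
#' @param assoc associated stimulus identifier, or \code{NA} for none.
#' @param h_assoc association drive amplitude.
#' @return Input vector, one entry per excitatory neuron.
#' @export
association_input <- function(prefs, stim, assoc = NA, h_assoc = 10,
                              h_stim = 8, noise = 0) {
  H <- fc_input(prefs, stim, h_stim, noise)
  if (!is.na(assoc) && stim == assoc) H <- H + h_assoc
  H
}

#' Gabor receptive-field parameters
#'
#' @param A amplitude.
#' @param sigma_x,sigma_y Gaussian envelope widths (patch units).
#' @param theta orientation, rad.
#' @param f spatial frequency, cycles per patch unit.
#' @param phi phase, rad.
#' @return A list of class \code{"gabor_params"}.
#' @export
gabor_params <- function(A = 1, sigma_x = 0.5, sigma_y = 0.5,
                         theta = 0, f = 2, phi = 0) {
  stopifnot(sigma_x > 0, sigma_y > 0)
  structure(list(A = A, sigma_x = sigma_x, sigma_y = sigma_y,
                 theta = theta, f = f, phi = phi), class = "gabor_params")
}

#' Square coordinate lattice for receptive fields
#'
#' @param n points per side.
#' @param lim half-width; the lattice spans \code{[-lim, lim]} per axis.
#' @return List with matrices \code{x} and \code{y} of coordinates.
#' @export
gabor_grid <- function(n = 16, lim = 1) {
  u <- seq(-lim, lim, length.out = n)
  list(x = matrix(u, n, n), y = matrix(u, n, n, byrow = TRUE))
}

#' Evaluate a 2-D Gabor receptive field on a lattice
#'
#' Rotated coordinates \code{x' = x cos(theta) - y sin(theta)},
#' \code{y' = x sin(theta) + y cos(theta)}; Gaussian envelope; cosine
#' carrier \code{cos(2 pi f x' + phi)}.
#'
#' @param params a \code{\link{gabor_params}}.
#' @param grid a \code{\link{gabor_grid}} (centered on 0).
#' @param normalize if \code{TRUE}, scale the patch to unit Frobenius norm so
#'   image drive is comparable across neurons (the default; the raw-amplitude
#'   patch is returned when \code{FALSE}).
#' @return Matrix patch of RF values.
#' @export
gabor_rf <- function(params, grid = gabor_grid(), normalize = TRUE) {
  xp <- grid$x * cos(params$theta) - grid$y * sin(params$theta)
  yp <- grid$x * sin(params$theta) + grid$y * cos(params$theta)
  rf <- params$A *
    exp(-xp^2 / (2 * params$sigma_x^2) - yp^2 / (2 * params$sigma_y^2)) *
    cos(2 * pi * params$f * xp + params$phi)
  if (normalize) {
    nrm <- sqrt(sum(rf^2))
    if (nrm > 0) rf <- rf / nrm
  }
  rf
}

#' Orientation set used for receptive fields and bar stimuli
#'
#' Eight equally spaced orientations with spacing pi/4:
#' \code{pi/4, pi/2, ..., 2 pi}.
#' @return Numeric vector of length 8, rad.
#' @export
rf_orientations <- function() (1:8) * pi / 4

#' Sample a receptive-field ensemble
#'
#' Draws \code{n} Gabor parameter sets with fixed \code{f = 2},
#' \code{sigma_x = sigma_y = 0.5}, phase uniform on \code{[0, 2 pi)}, and
#' orientation uniform over the eight-element set
#' \code{\link{rf_orientations}}. Deterministic under \code{seed}.
#'
#' @param n number of neurons.
#' @param seed integer seed.
#' @return List of \code{\link{gabor_params}}; orientations retrievable via
#'   \code{vapply(ens, `[[`, 1, "theta")}.
#' @export
sample_rf_ensemble <- function(n, seed = 1L) {
  stopifnot(n > 0)
  oris <- rf_orientations()
  withr_seed(seed, {
    theta <- sample(oris, n, replace = TRUE)
    phi <- stats::runif(n, 0, 2 * pi)
  })
  lapply(seq_len(n), function(i)
    gabor_params(theta = theta[i], phi = phi[i]))
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval(expr, parent.frame())
}

#' Project an image onto a receptive field
#'
#' Feedforward drive of one neuron for one image: the pixel-wise dot product
#' of image and receptive field, plus a noise sample.
#'
#' @param image matrix of pixel values on the RF lattice.
#' @param rf receptive-field patch (same shape).
#' @param noise scalar noise sample.
#' @return Scalar input.
#' @export
image_input <- function(image, rf, noise = 0) {
  if (!all(dim(image) == dim(rf))) stop("image/RF shape mismatch")
  sum(image * rf) + noise
}

#' Oriented-bar image
#'
#' A rectangular bar of width \code{width} (patch units) through the center
#' of the lattice, aligned with the stripe direction of a Gabor receptive
#' field of the same \code{theta} (so a bar at \code{theta} maximally
#' drives same-\code{theta} receptive fields). Pixel values are scaled so
#' the image norm is identical across orientations (the axis-aligned bar's
#' norm is the reference), removing the lattice-discretisation dependence of
#' stimulus energy on angle. A bar at \code{theta} equals the bar at
#' \code{theta + pi} (orientation, not direction).
#'
#' @param theta orientation, rad.
#' @param grid a \code{\link{gabor_grid}}.
#' @param width bar width, patch units.
#' @return Matrix image.
#' @export
make_bar_image <- function(theta, grid = gabor_grid(), width = 0.25) {
  # distance along the Gabor carrier axis x' = x cos(theta) - y sin(theta);
  # the bar occupies |x'| <= width/2, i.e. it runs along the stripes
  band <- function(th) {
    d <- grid$x * cos(th) - grid$y * sin(th)
    (abs(d) <= width / 2) * 1
  }
  img <- band(theta)
  ref <- sqrt(sum(band(0)^2))
  nrm <- sqrt(sum(img^2))
  if (nrm > 0) img <- img * (ref / nrm)
  img
}

#' Grating image (alternative stimulus generator)
#'
#' Full-field sinusoidal grating at the given orientation, frequency and
#' phase on the RF lattice.
#'
#' @inheritParams make_bar_image
#' @param f spatial frequency, cycles per patch unit.
#' @param phi phase, rad.
#' @return Matrix image.
#' @export
make_grating_image <- function(theta, grid = gabor_grid(), f = 2, phi = 0) {
  xp <- grid$x * cos(theta) - grid$y * sin(theta)
  cos(2 * pi * f * xp + phi)
}

#' Random stimulus schedule
#'
#' Draws an i.i.d. uniform stimulus identity for each fixed-length epoch
#' (default 500 ms), optionally with an associated-stimulus track whose
#' identity is re-drawn every \code{assoc_switch_ms} (continual perceptual
#' learning). The association can be delayed by \code{assoc_onset_ms}
#' (baseline period with no association drive).
#'
#' @param n_stimuli number of distinct stimuli.
#' @param total_ms total schedule duration; multiple of \code{epoch_ms}.
#' @param epoch_ms epoch length, ms.
#' @param seed integer seed.
#' @param assoc_switch_ms optional association switch period, ms.
#' @param assoc_onset_ms time before which the association is off, ms.
#' @param h_assoc association drive amplitude.
#' @return An object of class \code{"stimulus_program"}: list with
#'   \code{schedule} (stimulus id per epoch, 1-based), \code{epoch_ms},
#'   \code{assoc} (associated id per epoch or \code{NA}... encoded 0 for
#'   none), and \code{h_assoc}.
#' @export
make_schedule <- function(n_stimuli, total_ms, epoch_ms = 500, seed = 1L,
                          assoc_switch_ms = NULL, assoc_onset_ms = 0,
                          h_assoc = 10) {
  stopifnot(n_stimuli >= 1, total_ms > 0,
            abs(total_ms / epoch_ms - round(total_ms / epoch_ms)) < 1e-9)
  n_epochs <- as.integer(round(total_ms / epoch_ms))
  withr_seed(seed, {
    sched <- sample.int(n_stimuli, n_epochs, replace = TRUE)
    assoc <- rep(0L, n_epochs)
    if (!is.null(assoc_switch_ms)) {
      epochs_per_switch <- max(1L, as.integer(round(assoc_switch_ms / epoch_ms)))
      starts <- seq(1L, n_epochs, by = epochs_per_switch)
      ids <- sample.int(n_stimuli, length(starts), replace = TRUE)
      assoc <- rep(ids, each = epochs_per_switch)[seq_len(n_epochs)]
      off <- (seq_len(n_epochs) - 1) * epoch_ms < assoc_onset_ms
      assoc[off] <- 0L
    }
  })
  structure(list(schedule = sched, epoch_ms = epoch_ms,
                 assoc = assoc, h_assoc = h_assoc,
                 n_stimuli = n_stimuli, seed = as.integer(seed)),
            class = "stimulus_program")
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat(sprintf("Stimulus program: %d epochs x %g ms, %d stimuli%s\n",
              length(x$schedule), x$epoch_ms, x$n_stimuli,
              if (any(x$assoc > 0)) " (with association track)" else ""))
  invisible(x)
}

#' Feedforward drive matrix for a discrete-stimulus network
#'
#' One column per stimulus; column s holds each neuron's drive when stimulus
#' s is shown (\code{h_stim} times the group indicator).
#'
#' @inheritParams fc_input
#' @param n_stimuli number of stimuli.
#' @return \code{length(prefs) x n_stimuli} matrix.
#' @export
fc_drive_matrix <- function(prefs, n_stimuli, h_stim = 8) {
  matrix(vapply(seq_len(n_stimuli), function(s) as.numeric(prefs == s) * h_stim,
                numeric(length(prefs))),
         nrow = length(prefs))
}

#' Feedforward drive matrix for a receptive-field network
#'
#' Column s holds each neuron's dot product of its receptive field with the
#' oriented-bar image at orientation s.
#'
#' @param ensemble list of \code{\link{gabor_params}}.
#' @param grid a \code{\link{gabor_grid}}.
#' @param orientations bar orientations (default the RF orientation set).
#' @param image_fun image generator, \code{function(theta, grid)}.
#' @return \code{length(ensemble) x length(orientations)} matrix.
#' @export
rf_drive_matrix <- function(ensemble, grid = gabor_grid(),
                            orientations = rf_orientations(),
                            image_fun = make_bar_image) {
  rfs <- lapply(ensemble, gabor_rf, grid = grid)
  imgs <- lapply(orientations, image_fun, grid = grid)
  out <- vapply(imgs, function(im)
    vapply(rfs, function(rf) sum(im * rf), 0), numeric(length(rfs)))
  matrix(out, nrow = length(rfs))
}
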