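#' Learning-rate assignments
#'
#' Builds the per-neuron Hebbian learning-rate vector for a population of
#' \code{n_exc} neurons split into \code{n_groups} equal stimulus groups.
#' Modes:
#' \describe{
#'   \item{\code{"fast_slow"}}{half of each group slow (\code{alpha_s}), half
#'     fast (\code{5 alpha_s}).}
#'   \item{\code{"log_spaced"}}{each group carries one neuron of each of
#'     \code{group size} learning rates, logarithmically spaced on
#'     \code{[0.5, 75] * alpha_s}.}
#'   \item{\code{"log_uniform"}}{independent log-uniform draw per neuron on
#'     \code{[0.5, 75] * alpha_s} (the "diverse" assignment).}
#'   \item{\code{"uniform"}}{every neuron at the geometric mean of the
#'     diverse range (\code{sqrt(0.5 * 75) * alpha_s}), so uniform and
#'     diverse networks match in median plasticity.}
#'   \item{\code{"slow"} / \code{"fast"}}{every neuron at \code{alpha_s} /
#'     \code{5 alpha_s}.}
#' }
#'
#' @param n_exc number of excitatory neurons.
#' @param mode assignment mode.
#' @param n_groups number of stimulus groups (for the structured modes).
#' @param alpha_s base learning rate, Hz.
#' @param seed seed for the random draw modes.
#' @return Numeric vector of learning rates, Hz.
#' @export
alpha_assignment <- function(n_exc, mode = c("fast_slow", "log_spaced",
                                             "log_uniform", "uniform",
                                             "slow", "fast"),
                             n_groups = 4, alpha_s = 2e-6, seed = 1L) {
  mode <- match.arg(mode)
  per <- n_exc / n_groups
  switch(mode,
    fast_slow = {
      stopifnot(per == round(per), per %% 2 == 0)
      rep(rep(c(alpha_s, 5 * alpha_s), each = per / 2), n_groups)
    },
    log_spaced = {
      stopifnot(per == round(per))
      rep(exp(seq(log(0.5 * alpha_s), log(75 * alpha_s), length.out = per)),
          n_groups)
    },
    log_uniform = withr_seed(seed,
      exp(stats::runif(n_exc, log(0.5 * alpha_s), log(75 * alpha_s)))),
    uniform = rep(sqrt(0.5 * 75) * alpha_s, n_exc),
    slow = rep(alpha_s, n_exc),
    fast = rep(5 * alpha_s, n_exc)
  )
}

#' Fully connected discrete-stimulus network
#'
#' The small network model: \code{n_exc} excitatory neurons (default 48) in
#' \code{n_stimuli} equal preference groups (default 4, so 12 neurons per
#' stimulus), one global inhibitory neuron, dense connectivity, and
#' feedforward drive \code{h_stim} to the preferred group.
#'
#' @param n_exc excitatory population size; multiple of \code{n_stimuli}.
#' @param n_stimuli number of input stimuli.
#' @param alpha per-neuron learning rates, or a mode string passed to
#'   \code{\link{alpha_assignment}}.
#' @param cfg a \code{\link{network_config}}.
#' @param seed seed for random alpha modes.
#' @return A \code{\link{rate_network}} with \code{prefs} set to the
#'   stimulus-group labels.
#' @export
fc_network <- function(n_exc = 48, n_stimuli = 4, alpha = "fast_slow",
                       cfg = network_config(), seed = 1L) {
  stopifnot(n_exc %% n_stimuli == 0)
  prefs <- rep(seq_len(n_stimuli), each = n_exc / n_stimuli)
  if (is.character(alpha))
    alpha <- alpha_assignment(n_exc, alpha, n_groups = n_stimuli,
                              alpha_s = cfg$alpha_s, seed = seed)
  drive <- fc_drive_matrix(prefs, n_stimuli, cfg$h_stim)
  rate_network(n_exc, alpha, drive, prefs = prefs, cfg = cfg)
}

#' Gabor receptive-field network
#'
#' The cortical network model: \code{n_exc} excitatory neurons (default 250)
#' with randomly sampled Gabor receptive fields, one global inhibitory
#' neuron, and feedforward drive given by the dot product of oriented-bar
#' images with each neuron's receptive field. \code{prefs} holds the RF
#' orientation group (1..8).
#'
#' @param n_exc excitatory population size.
#' @param alpha per-neuron learning rates or an \code{\link{alpha_assignment}}
#'   mode (default the diverse log-uniform draw).
#' @param cfg a \code{\link{network_config}}; the cortical regime uses
#'   \code{sigma_ou = 5}.
#' @param grid RF lattice.
#' @param seed seed for RF sampling and random alpha modes.
#' @param image_fun stimulus image generator (bars by default).
#' @param drive_gain overall gain applied to the image--RF drive (the Gabor
#'   amplitude A of every receptive field; drive is linear in A).
#' @param w_init_ee initial E-to-E weight; the default (\code{NULL}) starts
#'   uniform connectivity at the synaptic-scaling target,
#'   \code{w_total_ee / (n_exc - 1)}, so the network begins rate-stable
#'   (the small fully connected model keeps its own \code{0.5 * wmax}
#'   initialisation).
#' @return A \code{\link{rate_network}} with attribute \code{"ensemble"}
#'   (the Gabor parameter list) and \code{"orientations"}.
#' @export
rf_network <- function(n_exc = 250, alpha = "log_uniform",
                       cfg = network_config(sigma_ou = 5, tau_m = 200),
                       grid = gabor_grid(), seed = 1L,
                       image_fun = make_bar_image, w_init_ee = NULL,
                       drive_gain = 1) {
  cfg$w_init_ee <- if (is.null(w_init_ee)) cfg$w_total_ee / (n_exc - 1)
                   else w_init_ee
  ens <- sample_rf_ensemble(n_exc, seed = derive_seed(seed, "rf-ensemble"))
  theta <- vapply(ens, `[[`, 0, "theta")
  oris <- rf_orientations()
  prefs <- match(round(theta, 10), round(oris, 10))
  if (is.character(alpha))
    alpha <- alpha_assignment(n_exc, alpha, alpha_s = cfg$alpha_s,
                              seed = derive_seed(seed, "alpha"))
  drive <- drive_gain * rf_drive_matrix(ens, grid, oris, image_fun)
  net <- rate_network(n_exc, alpha, drive, prefs = prefs, cfg = cfg)
  attr(net, "ensemble") <- ens
  attr(net, "orientations") <- theta
  net
}
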