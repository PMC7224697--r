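#' Rate-neuron transfer function
#'
#' Saturating transfer function mapping a neuron's state variable onto a
#' firing rate: zero for negative drive, and
#' \code{(rmax - r0) * tanh(x / (rmax - r0))} otherwise, giving rates in
#' \code{[0, rmax - r0)}. An optional baseline-shifted variant
#' (\code{baseline_shift = TRUE}) adds \code{r0} for positive drive, giving
#' rates in \code{[r0, rmax)}; the unshifted form is the default.
#'
#' @param x drive value(s); must be finite.
#' @param r0 baseline rate, Hz.
#' @param rmax maximum rate, Hz; \code{rmax > r0 >= 0}.
#' @param baseline_shift logical; use the shifted variant.
#' @return Firing rate(s), Hz.
#' @examples
#' transfer_rate(-1)            # 0
#' transfer_rate(19)            # 19 * tanh(1)
#' @export
transfer_rate <- function(x, r0 = 1, rmax = 20, baseline_shift = FALSE) {
  if (any(!is.finite(x))) stop("non-finite drive value")
  stopifnot(rmax > r0, r0 >= 0)
  span <- rmax - r0
  r <- ifelse(x < 0, 0, span * tanh(pmax(x, 0) / span))
  if (baseline_shift) r <- ifelse(x < 0, 0, r + r0)
  r
}

#' Advance an Ornstein-Uhlenbeck noise process
#'
#' Exact discretization of a zero-mean OU process with correlation time
#' \code{tau} and stationary standard deviation \code{sigma}:
#' \code{v <- v * exp(-dt/tau) + sigma * sqrt(1 - exp(-2 dt/tau)) * N(0,1)}.
#' Because the update is exact, the stationary statistics are independent of
#' the step size. Vectorized over \code{value}.
#'
#' @param value current sample(s).
#' @param dt time step, ms; positive.
#' @param tau correlation time, ms.
#' @param sigma stationary standard deviation.
#' @return Updated sample(s).
#' @examples
#' set.seed(1)
#' ou_step(0, dt = 1, tau = 10, sigma = 1)
#' @export
ou_step <- function(value, dt, tau = 10, sigma = 1) {
  stopifnot(dt > 0, tau > 0, sigma >= 0)
  decay <- exp(-dt / tau)
  value * decay + sigma * sqrt(1 - decay^2) * stats::rnorm(length(value))
}

#' One Euler step of the recurrent rate dynamics
#'
#' Advances the network state by one step of
#' \code{dy/dt = (-y + W g(y) + H) / tau_m}, leaving the weights untouched.
#' This is the R reference integrator used for verification; long simulations
#' go through \code{\link{run_network}}'s compiled path.
#'
#' @param y state vector (one entry per neuron, excitatory first).
#' @param W signed weight matrix, row = postsynaptic.
#' @param H external-input vector, same length as \code{y}.
#' @param cfg a \code{\link{network_config}} (uses \code{dt}, \code{tau_m},
#'   \code{r0}, \code{rmax}).
#' @return Updated state vector.
#' @export
integrate_step <- function(y, W, H, cfg = network_config()) {
  if (length(H) != length(y) || nrow(W) != length(y) || ncol(W) != length(y))
    stop("dimension mismatch between state, weights and input")
  r <- transfer_rate(y, cfg$r0, cfg$rmax, cfg$baseline_shift)
  y + (cfg$dt / cfg$tau_m) * (-y + as.vector(W %*% r) + H)
}

#' Construct a recurrent rate network
#'
#' Builds the network state: \code{n_exc} excitatory neurons plus
#' \code{n_inh} inhibitory neurons (default one global interneuron), with
#' dense connectivity (no autapses, no I-to-I), uniform initial weights, a
#' per-neuron Hebbian learning rate vector, and per-excitatory-neuron
#' stimulus drive. Stimulus drive is supplied as a matrix \code{drive} with
#' one column per stimulus: column s is added to the excitatory input
#' whenever stimulus s is shown (for discrete-stimulus networks this is
#' \code{h_stim} times a group-indicator; for receptive-field networks it is
#' the image--RF dot products).
#'
#' @param n_exc number of excitatory neurons.
#' @param alpha per-neuron Hebbian learning rate vector (recycled to
#'   \code{n_exc}).
#' @param drive \code{n_exc x n_stimuli} feedforward drive matrix.
#' @param prefs integer vector of preferred-stimulus labels (1-based) used by
#'   specificity metrics; for receptive-field networks pass the orientation
#'   group index.
#' @param cfg a \code{\link{network_config}}.
#' @param n_inh number of inhibitory neurons.
#' @return An object of class \code{"rate_network"}.
#' @export
rate_network <- function(n_exc, alpha, drive, prefs = NULL,
                         cfg = network_config(), n_inh = 1) {
  stopifnot(n_exc >= 2, n_inh >= 1, nrow(drive) == n_exc)
  alpha <- rep_len(alpha, n_exc)
  n <- n_exc + n_inh
  w_ei <- if (is.na(cfg$w_init_ei)) 7.2 / n_exc else cfg$w_init_ei
  W <- matrix(0, n, n)
  W[seq_len(n_exc), seq_len(n_exc)] <- cfg$w_init_ee          # E -> E
  W[n_exc + seq_len(n_inh), seq_len(n_exc)] <- w_ei           # E -> I (static)
  W[seq_len(n_exc), n_exc + seq_len(n_inh)] <- -cfg$w_init_ie # I -> E (signed)
  diag(W) <- 0
  structure(list(
    n_exc = n_exc, n_inh = n_inh,
    alpha = alpha, drive = drive,
    prefs = if (is.null(prefs)) rep(1L, n_exc) else as.integer(prefs),
    W = W, y = rep(0, n), cfg = cfg
  ), class = "rate_network")
}

#' @export
print.rate_network <- function(x, ...) {
  cat(sprintf("Recurrent rate network: %d E + %d I neurons, %d stimuli\n",
              x$n_exc, x$n_inh, ncol(x$drive)))
  cat(sprintf("  alpha range [%.3g, %.3g] Hz; w_init_EE %.4g; sigma_OU %.3g\n",
              min(x$alpha), max(x$alpha), x$cfg$w_init_ee, x$cfg$sigma_ou))
  invisible(x)
}

#' Simulate a network over a stimulus program
#'
#' Advances the recurrent dynamics over a timed stimulus schedule with
#' per-neuron Ornstein-Uhlenbeck input noise, optionally applying the
#' plasticity rules (Hebbian + synaptic scaling on E-to-E, homeostatic rule
#' on I-to-E, then weight clipping) at every timestep. Rates \code{g(y)} are
#' recorded every \code{rate_record_ms}; full weight snapshots every
#' \code{record_every_ms}; and, when \code{groups} is given, the per-neuron
#' mean specific (same-group) and non-specific (other-group) E-to-E input
#' weights are recorded every \code{group_record_ms} -- the substrate for
#' specificity and selectivity time courses.
#'
#' Identical (network, program, seed) inputs produce bit-identical traces.
#'
#' @param net a \code{\link{rate_network}}.
#' @param program a \code{\link{stimulus_program}}.
#' @param plastic logical; apply the plasticity rules.
#' @param seed integer seed for the noise stream.
#' @param record_every_ms weight-snapshot interval, ms (\code{Inf} for final
#'   weights only).
#' @param rate_record_ms rate-sampling interval, ms.
#' @param groups optional integer group label per excitatory neuron for the
#'   specific/non-specific weight channel (defaults to \code{net$prefs} when
#'   \code{group_record_ms} is finite).
#' @param group_record_ms sampling interval of the group-weight channel, ms
#'   (\code{Inf} disables it).
#' @return A \code{"simulation_trace"}: list with \code{rates}
#'   (neurons x samples matrix of \code{g(y)}), \code{times} (ms),
#'   \code{weights} (final weight matrix), \code{snapshots} (3-D array) and
#'   \code{snapshot_times}, \code{spec_mean}/\code{nonspec_mean} matrices and
#'   \code{group_times} (s), the final \code{state}, and the config echo.
#' @export
run_network <- function(net, program, plastic = TRUE, seed = 1L,
                        record_every_ms = Inf, rate_record_ms = 10,
                        groups = NULL, group_record_ms = Inf) {
  stopifnot(inherits(net, "rate_network"), inherits(program, "stimulus_program"))
  cfg <- net$cfg
  epoch_steps <- as.integer(round(program$epoch_ms / cfg$dt))
  stopifnot(epoch_steps >= 1)
  n_steps <- epoch_steps * length(program$schedule)
  if (is.null(groups)) groups <- net$prefs
  rec_w  <- if (is.finite(record_every_ms))
    as.integer(round(record_every_ms / cfg$dt)) else 0L
  rec_r  <- as.integer(round(rate_record_ms / cfg$dt))
  rec_g  <- if (is.finite(group_record_ms))
    as.integer(round(group_record_ms / cfg$dt)) else 0L
  assoc <- program$assoc
  if (is.null(assoc)) assoc <- rep(0L, length(program$schedule))
  out <- cpp_run_network(
    y = net$y, W = net$W, n_exc = net$n_exc,
    drive = net$drive,
    schedule = as.integer(program$schedule) - 1L,
    assoc = as.integer(assoc) - 1L,
    h_assoc = program$h_assoc,
    epoch_steps = epoch_steps,
    dt = cfg$dt, tau_m = cfg$tau_m,
    r0 = cfg$r0, rmax = cfg$rmax, baseline_shift = cfg$baseline_shift,
    tau_ou = cfg$tau_ou, sigma_ou = cfg$sigma_ou,
    plastic = isTRUE(plastic),
    plast_linear = identical(cfg$plasticity_activity, "linear"),
    alpha = net$alpha, zeta = cfg$zeta, eta = cfg$eta,
    w_total_ee = cfg$w_total_ee, y0 = cfg$y0,
    wmax = cfg$wmax, wmax_inh = cfg$wmax_inh,
    rec_rate_every = rec_r, rec_w_every = rec_w,
    groups = as.integer(groups) - 1L, rec_group_every = rec_g,
    seed = as.integer(seed)
  )
  trace <- list(
    rates = out$rates, times = as.vector(out$rate_times),
    weights = out$W, snapshots = out$snapshots,
    snapshot_times = as.vector(out$snapshot_times),
    spec_mean = out$spec_mean, nonspec_mean = out$nonspec_mean,
    group_times = as.vector(out$group_times) / 1000,
    state = list(y = as.vector(out$y), ou = as.vector(out$ou)),
    n_exc = net$n_exc, n_inh = net$n_inh,
    plastic = isTRUE(plastic), seed = as.integer(seed),
    config = unclass(cfg), duration_ms = n_steps * cfg$dt
  )
  class(trace) <- "simulation_trace"
  trace
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("Simulation trace: %.1f s, %d E + %d I neurons, %s weights\n",
              x$duration_ms / 1000, x$n_exc, x$n_inh,
              if (x$plastic) "plastic" else "frozen"))
  cat(sprintf("  %d rate samples at %.3g ms spacing; %d weight snapshots\n",
              ncol(x$rates), if (ncol(x$rates) > 1) diff(x$times[1:2]) else NA,
              length(x$snapshot_times)))
  invisible(x)
}

#' Continue a simulation from the end state of a trace
#'
#' Returns a copy of \code{net} whose weights and state are taken from the
#' end of \code{trace}, e.g. to measure population coupling on frozen weights
#' after a plasticity phase.
#'
#' @param net the original \code{\link{rate_network}}.
#' @param trace a \code{simulation_trace} produced from it.
#' @return A \code{rate_network}.
#' @export
network_from_trace <- function(net, trace) {
  stopifnot(inherits(net, "rate_network"), inherits(trace, "simulation_trace"))
  net$W <- trace$weights
  net$y <- trace$state$y
  net
}

#' Serialize a simulation trace as plain text
#'
#' Writes the rate matrix and final weights as CSV plus a JSON sidecar
#' carrying times, config and seed; \code{read_trace} restores the object.
#'
#' @param trace a \code{simulation_trace}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "simulation_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(trace$rates, file.path(dir, "rates.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(trace$weights, file.path(dir, "weights.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- trace[c("times", "snapshot_times", "group_times", "n_exc", "n_inh",
                  "plastic", "seed", "config", "duration_ms")]
  jsonlite::write_json(side, file.path(dir, "trace.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trace
#' @param dir directory written by \code{write_trace}.
#' @export
read_trace <- function(dir) {
  side <- jsonlite::fromJSON(file.path(dir, "trace.json"))
  trace <- list(
    rates = as.matrix(utils::read.table(file.path(dir, "rates.csv"), sep = ",")),
    weights = as.matrix(utils::read.table(file.path(dir, "weights.csv"), sep = ",")),
    times = side$times, snapshot_times = side$snapshot_times,
    group_times = side$group_times,
    n_exc = side$n_exc, n_inh = side$n_inh, plastic = side$plastic,
    seed = side$seed, config = side$config, duration_ms = side$duration_ms
  )
  dimnames(trace$rates) <- NULL
  dimnames(trace$weights) <- NULL
  class(trace) <- "simulation_trace"
  trace
}
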