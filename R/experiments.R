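#' Fully connected network experiment
#'
#' Develops the small fully connected network (48 E + 1 I, 4 stimulus
#' groups) through 500 s of plasticity under a random stimulus schedule,
#' then measures population coupling during a frozen-weight replay.
#' With \code{alpha = "fast_slow"} each group holds 6 slow and 6 fast
#' neurons; with \code{alpha = "log_spaced"}, one neuron per group at each
#' of 12 log-spaced learning rates on \code{[0.5, 75] * alpha_s}.
#'
#' @param alpha learning-rate mode or vector (see
#'   \code{\link{alpha_assignment}}).
#' @param seed master seed.
#' @param duration_s plasticity duration, s.
#' @param pc_duration_s frozen-weight population-coupling window, s.
#' @param n_exc,n_stimuli network size.
#' @param cfg a \code{\link{network_config}}.
#' @return List of class \code{"fc_experiment"}: per-neuron \code{alpha},
#'   endpoint \code{specificity}, \code{fluctuation} (std of specificity over
#'   200--500 s at 1 s sampling), \code{pc}, masks \code{slow}/\code{fast},
#'   the final weights, mean excitatory rate, and the config echo.
#' @export
run_fc_experiment <- function(alpha = c("fast_slow", "log_spaced"),
                              seed = 1L, duration_s = 500,
                              pc_duration_s = 250,
                              n_exc = 48, n_stimuli = 4,
                              cfg = network_config()) {
  if (is.character(alpha)) alpha <- match.arg(alpha)
  net <- fc_network(n_exc, n_stimuli, alpha, cfg, seed = derive_seed(seed, "net"))
  program <- make_schedule(n_stimuli, duration_s * 1000, 500,
                           seed = derive_seed(seed, "schedule"))
  tr <- run_network(net, program, plastic = TRUE,
                    seed = derive_seed(seed, "noise"),
                    rate_record_ms = 100, group_record_ms = 1000)
  spec <- trace_specificity(tr)
  e <- seq_len(n_exc)
  W_ee <- tr$weights[e, e]
  frozen <- network_from_trace(net, tr)
  pc_prog <- make_schedule(n_stimuli, pc_duration_s * 1000, 500,
                           seed = derive_seed(seed, "pc-schedule"))
  pc_tr <- run_network(frozen, pc_prog, plastic = FALSE,
                       seed = derive_seed(seed, "pc-noise"),
                       rate_record_ms = 10)
  pc <- population_coupling(pc_tr$rates[e, , drop = FALSE])
  structure(list(
    alpha = net$alpha,
    prefs = net$prefs,
    specificity = connection_specificity(W_ee, net$prefs),
    fluctuation = specificity_fluctuations(spec$specificity, spec$times,
                                           t_start = min(200, duration_s * 0.4),
                                           t_end = duration_s),
    pc = pc,
    slow = net$alpha <= min(net$alpha) + 1e-20,
    fast = net$alpha >= max(net$alpha) - 1e-20,
    weights = tr$weights, n_exc = n_exc,
    mean_rate = mean(pc_tr$rates[e, ]),
    seed = seed, config = unclass(cfg)
  ), class = "fc_experiment")
}

#' @export
print.fc_experiment <- function(x, ...) {
  cat(sprintf("FC network experiment (%d E neurons): mean specificity %.2f, mean PC %.3f\n",
              x$n_exc, mean(x$specificity, na.rm = TRUE), mean(x$pc, na.rm = TRUE)))
  invisible(x)
}

#' Receptive-field network experiment
#'
#' Develops the Gabor receptive-field network (default 250 E + 1 I) through
#' 500 s of plasticity under random oriented-bar presentations at
#' \code{sigma_ou = 5}, tracks each neuron's stimulus selectivity every
#' second, then measures population coupling during a 250 s frozen-weight
#' replay. Networks are compared between diverse (\code{"log_uniform"}) and
#' \code{"uniform"} learning-rate assignments.
#'
#' @param alpha \code{"log_uniform"} (diverse) or \code{"uniform"}, or a
#'   numeric vector.
#' @param seed master seed.
#' @param n_exc excitatory population size.
#' @param duration_s plasticity duration, s.
#' @param pc_duration_s frozen population-coupling window, s.
#' @param cfg a \code{\link{network_config}}; default uses the cortical
#'   noise regime \code{sigma_ou = 5}.
#' @param drive_gain feedforward drive gain (see \code{\link{rf_network}}).
#' @return List of class \code{"rf_experiment"}: \code{alpha}, \code{pc},
#'   \code{summed_input} (row sums of the E-to-E block), endpoint
#'   \code{selectivity}, \code{sel_variability} (std over the
#'   post-convergence window), orientation groups, and the config echo.
#' @export
run_rf_experiment <- function(alpha = c("log_uniform", "uniform"),
                              seed = 1L, n_exc = 250,
                              duration_s = 500, pc_duration_s = 250,
                              cfg = network_config(sigma_ou = 5, tau_m = 200),
                              drive_gain = 1) {
  if (is.character(alpha)) alpha <- match.arg(alpha)
  net <- rf_network(n_exc, alpha, cfg, seed = derive_seed(seed, "net"),
                    drive_gain = drive_gain)
  program <- make_schedule(length(rf_orientations()), duration_s * 1000, 500,
                           seed = derive_seed(seed, "schedule"))
  tr <- run_network(net, program, plastic = TRUE,
                    seed = derive_seed(seed, "noise"),
                    rate_record_ms = 100, group_record_ms = 1000)
  spec <- trace_specificity(tr)
  e <- seq_len(n_exc)
  W_ee <- tr$weights[e, e]
  frozen <- network_from_trace(net, tr)
  pc_prog <- make_schedule(length(rf_orientations()), pc_duration_s * 1000, 500,
                           seed = derive_seed(seed, "pc-schedule"))
  pc_tr <- run_network(frozen, pc_prog, plastic = FALSE,
                       seed = derive_seed(seed, "pc-noise"),
                       rate_record_ms = 10)
  pc <- population_coupling(pc_tr$rates[e, , drop = FALSE])
  structure(list(
    alpha = net$alpha,
    prefs = net$prefs,
    pc = pc,
    summed_input = rowSums(W_ee),
    selectivity = rf_selectivity(W_ee, net$prefs),
    sel_variability = selectivity_variability(spec$selectivity, spec$times,
                                              t_start = min(200, duration_s * 0.4),
                                              t_end = duration_s),
    weights = tr$weights, n_exc = n_exc,
    mean_rate = mean(pc_tr$rates[e, ]),
    seed = seed, config = unclass(cfg)
  ), class = "rf_experiment")
}

#' @export
print.rf_experiment <- function(x, ...) {
  cat(sprintf("RF network experiment (%d E neurons): PC sd %.3f, mean selectivity %.4g\n",
              x$n_exc, stats::sd(x$pc, na.rm = TRUE),
              mean(x$selectivity, na.rm = TRUE)))
  invisible(x)
}

#' Metric table of a network experiment
#'
#' One row per excitatory neuron with learning rate, population coupling and
#' the experiment's derived metrics -- the tidy export consumed by the CLI.
#'
#' @param x an \code{fc_experiment} or \code{rf_experiment}.
#' @return A data frame.
#' @export
experiment_metrics <- function(x) {
  if (inherits(x, "fc_experiment"))
    data.frame(neuron = seq_along(x$alpha), alpha = x$alpha, pc = x$pc,
               specificity = as.vector(x$specificity),
               fluctuation = x$fluctuation)
  else if (inherits(x, "rf_experiment"))
    data.frame(neuron = seq_along(x$alpha), alpha = x$alpha, pc = x$pc,
               summed_input = x$summed_input,
               selectivity = as.vector(x$selectivity),
               sel_variability = x$sel_variability)
  else stop("not an experiment object")
}

#' Noise-amplitude sweep of the receptive-field network
#'
#' Runs matched diverse- and uniform-learning-rate receptive-field networks
#' across a grid of noise amplitudes \code{sigma_ou} and summarises, per
#' amplitude and network type, the mean stimulus selectivity and the spread
#' (population std) of the population-coupling distribution.
#'
#' @param sigmas noise amplitudes (log-spaced grid).
#' @param seed master seed.
#' @param n_exc,duration_s,pc_duration_s scale of each run.
#' @return Data frame with columns \code{sigma_ou}, \code{type},
#'   \code{mean_selectivity}, \code{pc_sd}, \code{pc_undefined}.
#' @export
run_noise_sweep <- function(sigmas = c(0.5, 1, 2, 5, 10), seed = 1L,
                            n_exc = 250, duration_s = 500,
                            pc_duration_s = 250) {
  stopifnot(all(sigmas >= 0))
  rows <- list()
  for (s in sigmas) {
    for (type in c("log_uniform", "uniform")) {
      res <- run_rf_experiment(type,
                               seed = derive_seed(seed, paste0("sweep-", type, "-", s)),
                               n_exc = n_exc, duration_s = duration_s,
                               pc_duration_s = pc_duration_s,
                               cfg = network_config(sigma_ou = s))
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_ou = s,
        type = if (type == "uniform") "uniform" else "diverse",
        mean_selectivity = mean(res$selectivity, na.rm = TRUE),
        pc_sd = sd_pop(res$pc),
        pc_undefined = sum(is.na(res$pc)))
    }
  }
  do.call(rbind, rows)
}

#' Continual stimulus-association (perceptual learning) experiment
#'
#' Develops the fully connected network for \code{baseline_s} seconds
#' without associations, then simulates continual perceptual learning: an
#' extra drive \code{h_assoc = 10} is delivered to every excitatory neuron
#' whenever the associated stimulus is shown, and the associated identity is
#' re-drawn every 25 s. Tracked are the time courses of feedforward
#' selectivity (specific/non-specific ratio - 1) and associated-stimulus
#' selectivity, for networks composed entirely of slow neurons, entirely of
#' fast neurons, or a 50/50 mix per group.
#'
#' @param network_type \code{"slow"}, \code{"fast"} or \code{"mixed"}.
#' @param seed master seed.
#' @param baseline_s association-free development, s.
#' @param learning_s continual-association period, s.
#' @param assoc_switch_s association switch period, s.
#' @param n_exc,n_stimuli network size.
#' @param cfg a \code{\link{network_config}}.
#' @param snapshot_s weight-snapshot interval for the selectivity time
#'   courses, s.
#' @return List of class \code{"association_experiment"} with the final
#'   feedforward/associated selectivity per neuron, their time courses
#'   (list of per-snapshot summaries), slow/fast masks and config echo.
#' @export
run_association_experiment <- function(network_type = c("slow", "fast", "mixed"),
                                       seed = 1L, baseline_s = 300,
                                       learning_s = 300, assoc_switch_s = 25,
                                       n_exc = 48, n_stimuli = 4,
                                       cfg = network_config(),
                                       snapshot_s = 5) {
  network_type <- match.arg(network_type)
  alpha_mode <- switch(network_type, slow = "slow", fast = "fast",
                       mixed = "fast_slow")
  net <- fc_network(n_exc, n_stimuli, alpha_mode, cfg,
                    seed = derive_seed(seed, "net"))
  total_ms <- (baseline_s + learning_s) * 1000
  program <- make_schedule(n_stimuli, total_ms, 500,
                           seed = derive_seed(seed, "schedule"),
                           assoc_switch_ms = assoc_switch_s * 1000,
                           assoc_onset_ms = baseline_s * 1000,
                           h_assoc = 10)
  tr <- run_network(net, program, plastic = TRUE,
                    seed = derive_seed(seed, "noise"),
                    record_every_ms = snapshot_s * 1000,
                    rate_record_ms = 500)
  e <- seq_len(n_exc)
  # per-snapshot selectivities, associated id taken from the schedule
  n_snap <- length(tr$snapshot_times)
  epoch_of <- pmin(ceiling(tr$snapshot_times / program$epoch_ms),
                   length(program$schedule))
  course <- data.frame(time_s = tr$snapshot_times / 1000,
                       ff_slow = NA_real_, ff_fast = NA_real_,
                       assoc_slow = NA_real_, assoc_fast = NA_real_)
  slow <- net$alpha <= min(net$alpha) + 1e-20
  fast <- net$alpha >= max(net$alpha) - 1e-20
  for (k in seq_len(n_snap)) {
    W_ee <- tr$snapshots[e, e, k]
    aid <- program$assoc[epoch_of[k]]
    if (aid == 0) aid <- program$assoc[min(which(program$assoc > 0))]
    sel <- association_selectivity(W_ee, net$prefs, aid)
    course$ff_slow[k] <- mean(sel$ff[slow], na.rm = TRUE)
    course$ff_fast[k] <- mean(sel$ff[fast], na.rm = TRUE)
    course$assoc_slow[k] <- mean(sel$assoc[slow], na.rm = TRUE)
    course$assoc_fast[k] <- mean(sel$assoc[fast], na.rm = TRUE)
  }
  W_ee <- tr$weights[e, e]
  final_aid <- program$assoc[length(program$assoc)]
  if (final_aid == 0) final_aid <- 1L
  sel <- association_selectivity(W_ee, net$prefs, final_aid)
  # end-of-block summaries: the association is re-drawn every switch period,
  # so learning of the current association is read out just before each
  # switch and averaged over blocks of the learning phase
  block_end <- course$time_s > baseline_s &
    (course$time_s %% assoc_switch_s) == 0
  blocks <- course[block_end, , drop = FALSE]
  structure(list(
    network_type = network_type, alpha = net$alpha,
    ff = sel$ff, assoc = sel$assoc,
    course = course, slow = slow, fast = fast,
    block_assoc_slow = mean(blocks$assoc_slow, na.rm = TRUE),
    block_assoc_fast = mean(blocks$assoc_fast, na.rm = TRUE),
    block_ff_slow = mean(blocks$ff_slow, na.rm = TRUE),
    block_ff_fast = mean(blocks$ff_fast, na.rm = TRUE),
    weights = tr$weights, n_exc = n_exc,
    seed = seed, config = unclass(cfg)
  ), class = "association_experiment")
}

#' @export
print.association_experiment <- function(x, ...) {
  cat(sprintf("Association experiment (%s): final mean ff %.2f, assoc %.2f\n",
              x$network_type, mean(x$ff, na.rm = TRUE),
              mean(x$assoc, na.rm = TRUE)))
  invisible(x)
}

#' Embedded-plastic-neuron coupling sweep
#'
#' A single plastic readout neuron and a small static readout population are
#' embedded in a recurrent network whose weights are fixed. The population
#' carries the two stimuli (half the neurons prefer each); the two static
#' readouts prefer one stimulus each; the plastic readout has no feedforward
#' preference of its own -- its "original preferred stimulus" (blue) is a
#' small initial bias of its input weight from the blue static neuron. The
#' population input to static and plastic readouts is scaled by the coupling
#' factors \code{pc_static} and \code{pc_plastic}, and the
#' static-to-plastic weights are functionally silent (updated each step,
#' never fed back into activity).
#'
#' After a 500 s baseline, an association drive \code{h_assoc = 10} is
#' delivered to the population whenever the "red" stimulus is shown, for
#' 100 s. The association reaches the readouts only through their scaled
#' population input, so the coupling factors gate the learning signal.
#' Learning is quantified as the ratio of the red (associated) weight to the
#' blue (original-preference) weight.
#'
#' @param pc_plastic_grid,pc_static_grid coupling-factor grids (default 11
#'   points on \code{[0, 2]}).
#' @param seed master seed.
#' @param n_pop population neurons (split between the two stimuli).
#' @param baseline_s,learning_s phase durations, s.
#' @param alpha_plastic Hebbian rate of the plastic readout, Hz; sized so
#'   its input weights stay inside \code{[0, wmax]} over the protocol.
#' @param w_total target summed input of the plastic readout.
#' @param w_init initial (blue, red) input weights; the blue excess defines
#'   the original preference.
#' @param cfg a \code{\link{network_config}}.
#' @return List of class \code{"embedded_sweep"} with the learning-ratio
#'   matrix (rows = \code{pc_plastic}, cols = \code{pc_static}) and grids.
#' @export
run_embedded_sweep <- function(pc_plastic_grid = seq(0, 2, length.out = 11),
                               pc_static_grid = seq(0, 2, length.out = 11),
                               seed = 1L, n_pop = 20,
                               baseline_s = 500, learning_s = 100,
                               alpha_plastic = 1e-6,
                               w_total = 0.04,
                               w_init = c(0.021, 0.019),
                               cfg = network_config()) {
  stopifnot(n_pop %% 2 == 0, length(w_init) == 2)
  half <- n_pop / 2
  prefs_pop <- rep(1:2, each = half)
  # fixed, developed-like population connectivity: strong within-group
  W_pop <- matrix(0, n_pop, n_pop)
  for (i in seq_len(n_pop))
    W_pop[i, prefs_pop == prefs_pop[i]] <- cfg$wmax
  diag(W_pop) <- 0
  drive_pop <- fc_drive_matrix(prefs_pop, 2, cfg$h_stim)
  drive_static <- fc_drive_matrix(1:2, 2, cfg$h_stim)  # one static per stimulus
  drive_plastic <- c(0, 0)   # no feedforward preference of its own
  w_pop_row <- rep(cfg$w_init_ee, n_pop)
  total_ms <- (baseline_s + learning_s) * 1000
  n_epochs <- total_ms / 500
  ratio <- matrix(NA_real_, length(pc_plastic_grid), length(pc_static_grid),
                  dimnames = list(pc_plastic = signif(pc_plastic_grid, 3),
                                  pc_static = signif(pc_static_grid, 3)))
  sched_seed <- derive_seed(seed, "embedded-schedule")
  program <- make_schedule(2, total_ms, 500, seed = sched_seed)
  assoc <- rep(0L, n_epochs)
  assoc[(seq_len(n_epochs) - 1) * 500 >= baseline_s * 1000] <- 2L  # red
  for (a in seq_along(pc_plastic_grid)) {
    for (b in seq_along(pc_static_grid)) {
      out <- cpp_run_embedded(
        y_pop = rep(0, n_pop), W_pop = W_pop, drive_pop = drive_pop,
        y_static = c(0, 0), drive_static = drive_static,
        y_plastic = 0, drive_plastic = drive_plastic,
        w_pop_row = w_pop_row,
        pc_static = pc_static_grid[b], pc_plastic = pc_plastic_grid[a],
        w_plastic = w_init,
        alpha = alpha_plastic, zeta = cfg$zeta, w_total = w_total,
        wmax = cfg$wmax,
        schedule = program$schedule - 1L, assoc = assoc - 1L,
        h_assoc = 10, assoc_to_readouts = FALSE,
        epoch_steps = as.integer(500 / cfg$dt),
        dt = cfg$dt, tau_m = cfg$tau_m,
        r0 = cfg$r0, rmax = cfg$rmax, baseline_shift = cfg$baseline_shift,
        tau_ou = cfg$tau_ou, sigma_ou = cfg$sigma_ou,
        rec_every = 0L,
        seed = derive_seed(seed, sprintf("embedded-%d-%d", a, b)))
      w <- out$w_plastic
      ratio[a, b] <- if (w[1] > 0) w[2] / w[1] else Inf
    }
  }
  structure(list(ratio = ratio, pc_plastic = pc_plastic_grid,
                 pc_static = pc_static_grid, alpha_plastic = alpha_plastic,
                 w_total = w_total, w_init = w_init,
                 seed = seed, config = unclass(cfg)),
            class = "embedded_sweep")
}

#' @export
print.embedded_sweep <- function(x, ...) {
  cat(sprintf("Embedded-neuron sweep (%d x %d grid): %.0f%% of cells learned (ratio > 1)\n",
              nrow(x$ratio), ncol(x$ratio), 100 * mean(x$ratio > 1)))
  invisible(x)
}

#' Stimulus-pair decoding experiment
#'
#' Develops three fully connected networks with eight stimulus groups --
#' all-slow, all-fast, and a 50/50 mix of learning rates -- then, for each
#' point of a (feedforward strength x noise amplitude) log grid, presents
#' stimuli to the frozen networks, averages each neuron's rate over 500 ms
#' windows, trains one linear perceptron per stimulus pair (28 pairs from 8
#' stimuli, 50/50 train/test split over windows) and averages test accuracy
#' over pairs. Reported is each network's deviation from the three-network
#' mean accuracy per grid point.
#'
#' @param seed master seed.
#' @param stim_grid feedforward drive amplitudes (log-spaced).
#' @param noise_grid noise amplitudes \code{sigma_ou} (log-spaced).
#' @param n_groups,per_group architecture (8 x 12 by default).
#' @param develop_s plasticity duration for network development, s.
#' @param windows_per_stim sampling windows per stimulus per grid point.
#' @param cfg a \code{\link{network_config}}.
#' @return List of class \code{"decoding_experiment"}: \code{accuracy}
#'   (grid x 3 networks array), \code{relative} (deviation from grid-point
#'   mean), per-network grid means, and the grids.
#' @export
run_decoding_experiment <- function(seed = 1L,
                                    stim_grid = 10^seq(0, 1.5, length.out = 4),
                                    noise_grid = 10^seq(-0.5, 1, length.out = 4),
                                    n_groups = 8, per_group = 12,
                                    develop_s = 500, windows_per_stim = 20,
                                    cfg = network_config()) {
  n_exc <- n_groups * per_group
  types <- c("slow", "fast", "mixed")
  nets <- list()
  for (ty in types) {
    mode <- if (ty == "mixed") "fast_slow" else ty
    net <- fc_network(n_exc, n_groups, mode, cfg,
                      seed = derive_seed(seed, paste0("dec-net-", ty)))
    program <- make_schedule(n_groups, develop_s * 1000, 500,
                             seed = derive_seed(seed, paste0("dec-sched-", ty)))
    tr <- run_network(net, program, plastic = TRUE,
                      seed = derive_seed(seed, paste0("dec-noise-", ty)),
                      rate_record_ms = 1000)
    nets[[ty]] <- network_from_trace(net, tr)
  }
  pairs <- utils::combn(n_groups, 2)
  acc <- array(NA_real_, c(length(stim_grid), length(noise_grid), length(types)),
               dimnames = list(NULL, NULL, types))
  for (si in seq_along(stim_grid)) {
    for (ni in seq_along(noise_grid)) {
      # balanced, shuffled presentation schedule shared by the three networks
      sched <- withr_seed(derive_seed(seed, sprintf("dec-grid-%d-%d", si, ni)),
                          sample(rep(seq_len(n_groups), windows_per_stim)))
      prog <- structure(list(schedule = sched, epoch_ms = 500,
                             assoc = rep(0L, length(sched)), h_assoc = 0,
                             n_stimuli = n_groups, seed = NA_integer_),
                        class = "stimulus_program")
      for (ty in types) {
        net <- nets[[ty]]
        net$cfg$sigma_ou <- noise_grid[ni]
        net$drive <- fc_drive_matrix(net$prefs, n_groups, stim_grid[si])
        tr <- run_network(net, prog, plastic = FALSE,
                          seed = derive_seed(seed, sprintf("dec-run-%s-%d-%d",
                                                           ty, si, ni)),
                          rate_record_ms = 10)
        feats <- window_means(tr$rates[seq_len(n_exc), , drop = FALSE],
                              n_windows = length(sched))
        accs <- vapply(seq_len(ncol(pairs)), function(p) {
          a <- pairs[1, p]; b <- pairs[2, p]
          keep <- sched %in% c(a, b)
          decode_pair(feats[keep, , drop = FALSE],
                      ifelse(sched[keep] == a, 1, -1),
                      seed = derive_seed(seed, sprintf("dec-perc-%s-%d-%d-%d",
                                                       ty, si, ni, p)))
        }, 0)
        acc[si, ni, ty] <- mean(accs)
      }
    }
  }
  rel <- acc - array(rep(apply(acc, c(1, 2), mean), length(types)), dim(acc))
  structure(list(accuracy = acc, relative = rel,
                 mean_relative = apply(rel, 3, mean),
                 mean_accuracy = apply(acc, 3, mean),
                 stim_grid = stim_grid, noise_grid = noise_grid,
                 n_pairs = ncol(pairs), seed = seed, config = unclass(cfg)),
            class = "decoding_experiment")
}

#' @export
print.decoding_experiment <- function(x, ...) {
  cat("Stimulus-pair decoding (", x$n_pairs, " pairs):\n", sep = "")
  print(round(rbind(mean_accuracy = x$mean_accuracy,
                    mean_relative = x$mean_relative), 4))
  invisible(x)
}

# mean rate per neuron within each equal-length window of a rate matrix
window_means <- function(rates, n_windows) {
  per <- ncol(rates) / n_windows
  stopifnot(per == round(per))
  t(vapply(seq_len(n_windows), function(w)
    rowMeans(rates[, ((w - 1) * per + 1):(w * per), drop = FALSE]),
    numeric(nrow(rates))))
}
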