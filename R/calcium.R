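#' Calcium-imaging dataset container
#'
#' Bundles a dF/F matrix (neurons x frames), the acquisition frame rate, a
#' grating-presentation table and the frame ranges of the first and last
#' grating blocks. The stimulus table has one row per presentation with
#' columns \code{type} ("static" or "drifting"), \code{orientation_deg},
#' \code{direction_deg} (NA for static), \code{sf}, \code{tf}, \code{phase},
#' \code{start_frame}, \code{end_frame} (1-based, inclusive).
#'
#' @param dff neurons x frames numeric matrix.
#' @param frame_rate Hz.
#' @param stim_table data frame as described above.
#' @param blocks list with integer vectors \code{first} and \code{last}
#'   (frame ranges of the two grating blocks).
#' @return An object of class \code{"calcium_dataset"}.
#' @export
calcium_dataset <- function(dff, frame_rate, stim_table, blocks) {
  stopifnot(is.matrix(dff), frame_rate > 0, is.data.frame(stim_table),
            all(c("type", "orientation_deg", "direction_deg", "sf", "tf",
                  "phase", "start_frame", "end_frame") %in% names(stim_table)),
            all(stim_table$end_frame <= ncol(dff)),
            all(stim_table$start_frame >= 1),
            max(blocks$first) < min(blocks$last))
  structure(list(dff = dff, frame_rate = frame_rate,
                 stim_table = stim_table, blocks = blocks),
            class = "calcium_dataset")
}

#' @export
print.calcium_dataset <- function(x, ...) {
  cat(sprintf("Calcium dataset: %d neurons x %d frames at %g Hz, %d presentations (%s)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate, nrow(x$stim_table),
              x$stim_table$type[1]))
  invisible(x)
}

#' Synthetic dF/F dataset generator
#'
#' Emulates the structure of a passive-viewing two-photon session: a first
#' grating block, a long middle period without gratings, and a final grating
#' block. Each neuron's trace is
#' \code{coupling_i * shared(t) + tuned_i(t) + noise_i(t)}: a per-neuron
#' coupling weight times a shared low-pass population signal, plus
#' orientation-tuned evoked responses with a von-Mises-shaped tuning curve,
#' plus independent noise. Each neuron's preferred grating may be re-drawn
#' between the first and last block with a probability that can depend on
#' its coupling weight (\code{drift_prob0 + drift_coupling_gain * coupling}
#' on the logistic scale), planting a coupling--drift link (or, with zero
#' gain, a null dataset). All planted ground truth is returned in attribute
#' \code{"ground_truth"}.
#'
#' @param n_neurons number of neurons.
#' @param seed integer seed.
#' @param frame_rate acquisition rate, Hz.
#' @param block_mins durations (minutes) of the first grating block, the
#'   gratings-free middle period, and the last grating block.
#' @param type \code{"drifting"} (8 directions) or \code{"static"} (6
#'   orientations).
#' @param pres_s,gap_s presentation and inter-presentation durations, s.
#' @param coupling_mean,coupling_sd distribution of per-neuron coupling
#'   weights (truncated at 0).
#' @param amp_mean evoked-response peak amplitude scale (dF/F units;
#'   the onset transient decays from this peak over ~0.6 s).
#' @param kappa von-Mises tuning concentration.
#' @param noise_sd independent noise standard deviation (dF/F units).
#' @param shared_tau correlation time of the shared signal, s.
#' @param transient_tau decay time of the evoked onset transient, s.
#' @param drift_prob0 intercept of the drift probability (logit scale).
#' @param drift_coupling_gain coupling coefficient of the drift probability
#'   (logit scale); 0 plants coupling-independent drift.
#' @return A \code{\link{calcium_dataset}} with attribute
#'   \code{"ground_truth"}: coupling, pref_first, pref_last, drifted,
#'   amplitude.
#' @export
synthesize_dff_dataset <- function(n_neurons = 80, seed = 1L,
                                   frame_rate = 10,
                                   block_mins = c(10, 42, 10),
                                   type = c("drifting", "static"),
                                   pres_s = 2, gap_s = 1,
                                   coupling_mean = 0.6, coupling_sd = 0.35,
                                   amp_mean = 2.0, kappa = 2.5,
                                   noise_sd = 0.35, shared_tau = 0.5,
                                   transient_tau = 1,
                                   drift_prob0 = 0, drift_coupling_gain = 0) {
  type <- match.arg(type)
  values <- if (type == "drifting") seq(0, 315, by = 45) else seq(0, 150, by = 30)
  period <- if (type == "drifting") 360 else 180
  nb <- round(block_mins * 60 * frame_rate)
  n_frames <- sum(nb)
  blocks <- list(first = 1:nb[1], last = (nb[1] + nb[2] + 1):n_frames)
  pres_frames <- round(pres_s * frame_rate)
  cyc_frames <- round((pres_s + gap_s) * frame_rate)

  withr_seed(seed, {
    coupling <- pmax(stats::rnorm(n_neurons, coupling_mean, coupling_sd), 0)
    amp <- amp_mean * stats::rlnorm(n_neurons, 0, 0.4)
    pref1 <- sample(values, n_neurons, replace = TRUE)
    p_drift <- stats::plogis(drift_prob0 + drift_coupling_gain * coupling)
    drifted <- stats::runif(n_neurons) < p_drift
    pref2 <- pref1
    for (i in which(drifted))
      pref2[i] <- sample(setdiff(values, pref1[i]), 1)

    # shared low-pass population signal (exact-discretized OU, unit sd)
    decay <- exp(-1 / (shared_tau * frame_rate))
    eps <- stats::rnorm(n_frames) * sqrt(1 - decay^2)
    shared <- stats::filter(eps, decay, method = "recursive")
    shared <- as.numeric(shared)

    # grating presentation tables for the two blocks
    mk_block <- function(frame0, n_block_frames) {
      starts <- seq(1, n_block_frames - cyc_frames + 1, by = cyc_frames)
      data.frame(
        type = type,
        grating = sample(values, length(starts), replace = TRUE),
        start_frame = frame0 + starts,
        end_frame = frame0 + starts + pres_frames - 1)
    }
    tab1 <- mk_block(0, nb[1])
    tab2 <- mk_block(nb[1] + nb[2], nb[3])
    tab <- rbind(tab1, tab2)

    dff <- coupling %o% shared
    # evoked responses: von-Mises-shaped tuning on the orientation circle,
    # with a calcium-like onset transient so repeated presentations share a
    # time course (the substrate of the reliability measure)
    tune <- function(stim, pref)
      exp(kappa * (cos(2 * pi * (stim - pref) / period) - 1))
    kernel <- exp(-(seq_len(pres_frames) - 1) / (transient_tau * frame_rate))
    for (k in seq_len(nrow(tab))) {
      fr <- tab$start_frame[k]:tab$end_frame[k]
      pref <- if (tab$start_frame[k] <= nb[1]) pref1 else pref2
      resp <- amp * tune(tab$grating[k], pref)
      dff[, fr] <- dff[, fr] + resp %o% kernel
    }
    dff <- dff + matrix(stats::rnorm(n_neurons * n_frames, 0, noise_sd),
                        n_neurons, n_frames)
  })

  stim_table <- data.frame(
    type = tab$type,
    orientation_deg = tab$grating %% 180,
    direction_deg = if (type == "drifting") tab$grating else NA_real_,
    sf = 0.04, tf = if (type == "drifting") 2 else 0, phase = 0,
    start_frame = tab$start_frame, end_frame = tab$end_frame)
  ds <- calcium_dataset(dff, frame_rate, stim_table, blocks)
  attr(ds, "ground_truth") <- list(coupling = coupling, pref_first = pref1,
                                   pref_last = pref2, drifted = drifted,
                                   amplitude = amp, p_drift = p_drift)
  ds
}

#' Population coupling from dF/F
#'
#' Applies the population-coupling measure (Pearson correlation of each
#' neuron's trace with the leave-self-out mean of all others) to the dF/F
#' matrix over the entire recording session.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @return Numeric coupling vector (NA where a trace has zero variance).
#' @export
pc_from_dff <- function(ds) {
  stopifnot(inherits(ds, "calcium_dataset"))
  population_coupling(ds$dff)
}

#' Session quality control
#'
#' Excludes a session when fewer than 50 neurons were recorded, or when the
#' population-coupling estimate is unstable: couplings computed against the
#' mean of either random half of the population must agree (r-squared of a
#' linear regression >= 0.8). The half-split is seeded.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @param min_neurons minimum neuron count.
#' @param r2_threshold split-half agreement threshold.
#' @param seed seed of the random split.
#' @return List with \code{include} (logical), \code{reason} (character or
#'   NA), and \code{r2}.
#' @export
qc_experiment <- function(ds, min_neurons = 50, r2_threshold = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "calcium_dataset"))
  n <- nrow(ds$dff)
  if (n < min_neurons)
    return(list(include = FALSE, reason = "too few neurons", r2 = NA_real_))
  half <- withr_seed(seed, sample(rep(c(TRUE, FALSE), length.out = n)))
  pc_against <- function(mask) {
    m <- colSums(ds$dff[mask, , drop = FALSE])
    cnt <- sum(mask)
    vapply(seq_len(n), function(i) {
      ref <- if (mask[i]) (m - ds$dff[i, ]) / (cnt - 1) else m / cnt
      if (stats::sd(ds$dff[i, ]) == 0 || stats::sd(ref) == 0) return(NA_real_)
      stats::cor(ds$dff[i, ], ref)
    }, 0)
  }
  pa <- pc_against(half)
  pb <- pc_against(!half)
  ok <- !is.na(pa) & !is.na(pb)
  r2 <- summary(stats::lm(pb[ok] ~ pa[ok]))$r.squared
  if (r2 < r2_threshold)
    list(include = FALSE, reason = "unstable population coupling", r2 = r2)
  else
    list(include = TRUE, reason = NA_character_, r2 = r2)
}

# presentations of one block; tab rows restricted to the block's frames
block_presentations <- function(ds, block = c("first", "last")) {
  block <- match.arg(block)
  fr <- ds$blocks[[block]]
  tab <- ds$stim_table
  tab[tab$start_frame >= min(fr) & tab$end_frame <= max(fr), , drop = FALSE]
}

# mean dF/F of each neuron over each presentation of a table
presentation_means <- function(dff, tab) {
  matrix(vapply(seq_len(nrow(tab)), function(k)
    rowMeans(dff[, tab$start_frame[k]:tab$end_frame[k], drop = FALSE]),
    numeric(nrow(dff))), nrow = nrow(dff))
}

grating_values <- function(tab, attribute) {
  if (attribute == "direction") {
    if (all(is.na(tab$direction_deg)))
      stop("direction undefined for static gratings")
    tab$direction_deg
  } else tab$orientation_deg
}

#' Preferred grating of a neuron in one block
#'
#' The grating value (orientation or direction, degrees) that evoked the
#' largest mean dF/F response across all its presentations within the block.
#' Exact ties break toward the smaller angle.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @param neuron neuron index, or a vector (vectorized).
#' @param block \code{"first"} or \code{"last"} grating block.
#' @param attribute \code{"orientation"} or \code{"direction"}.
#' @return Preferred value(s), degrees.
#' @export
preferred_grating <- function(ds, neuron = seq_len(nrow(ds$dff)),
                              block = c("first", "last"),
                              attribute = c("orientation", "direction")) {
  block <- match.arg(block); attribute <- match.arg(attribute)
  tab <- block_presentations(ds, block)
  if (!nrow(tab)) stop("block contains no grating presentations")
  vals <- grating_values(tab, attribute)
  resp <- presentation_means(ds$dff[neuron, , drop = FALSE], tab)
  uv <- sort(unique(vals))
  mean_resp <- vapply(uv, function(v)
    rowMeans(resp[, vals == v, drop = FALSE]), numeric(length(neuron)))
  mean_resp <- matrix(mean_resp, nrow = length(neuron))
  uv[apply(mean_resp, 1, which.max)]   # which.max takes first (smaller angle)
}

#' Response reliability
#'
#' Trial-to-trial correlation of a neuron's dF/F segments across all
#' presentations of its preferred grating (preference taken over the whole
#' session): the mean of all pairwise Pearson correlations between
#' presentation segments. Neurons with fewer than two usable presentations
#' are flagged \code{NA}.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @param neuron neuron indices (default all).
#' @param attribute grating attribute defining the preference.
#' @return Numeric reliability score per neuron.
#' @export
response_reliability <- function(ds, neuron = seq_len(nrow(ds$dff)),
                                 attribute = c("orientation", "direction")) {
  attribute <- match.arg(attribute)
  tab <- ds$stim_table
  vals <- grating_values(tab, attribute)
  seg_len <- min(tab$end_frame - tab$start_frame) + 1
  resp <- presentation_means(ds$dff[neuron, , drop = FALSE], tab)
  uv <- sort(unique(vals))
  mean_resp <- vapply(uv, function(v)
    rowMeans(resp[, vals == v, drop = FALSE]), numeric(length(neuron)))
  mean_resp <- matrix(mean_resp, nrow = length(neuron))
  pref <- uv[apply(mean_resp, 1, which.max)]
  vapply(seq_along(neuron), function(ii) {
    rows <- which(vals == pref[ii])
    if (length(rows) < 2) return(NA_real_)
    segs <- vapply(rows, function(k)
      ds$dff[neuron[ii], tab$start_frame[k] + 0:(seg_len - 1)],
      numeric(seg_len))
    cm <- suppressWarnings(stats::cor(segs))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }, 0)
}

#' Absolute change in preferred grating
#'
#' Literal absolute difference between two preferred values in degrees (the
#' printed definition); with \code{circular = TRUE} the wrapped circular
#' distance on the given period is used instead.
#'
#' @param p1,p2 preferred values, degrees.
#' @param circular use circular distance.
#' @param period 180 for orientation, 360 for direction.
#' @return Absolute difference, degrees.
#' @examples
#' delta_pref(30, 90)                  # 60
#' delta_pref(0, 150)                  # 150
#' delta_pref(0, 150, circular = TRUE) # 30
#' @export
delta_pref <- function(p1, p2, circular = FALSE, period = 180) {
  d <- abs(p1 - p2)
  if (circular) d <- pmin(d, period - d)
  d
}

#' Orientation/direction drift analysis of one session
#'
#' The full measurement cascade on one dataset: session QC, population
#' coupling over the whole session, preferred grating in the first and last
#' blocks, the absolute preference change, and the response-reliability
#' filter (neurons at or above the session's reliability quantile are
#' included; default the median, with 75% and 100% inclusion as variants).
#' Stage counts are recorded in attribute \code{"log"}.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @param attribute \code{"orientation"} or \code{"direction"}.
#' @param reliability_quantile fraction of most-reliable neurons to include
#'   (0.5 = above-median, 0.75, or 1 = all).
#' @param circular use circular preference distance.
#' @param seed seed for the QC split.
#' @return A data frame of class \code{"drift_result"} with columns
#'   \code{neuron}, \code{pc}, \code{pref_first}, \code{pref_last},
#'   \code{delta_pref}, \code{reliability}, \code{included}; or \code{NULL}
#'   with a message when the session fails QC (attribute \code{"qc"} carries
#'   the reason).
#' @export
analyze_calcium <- function(ds, attribute = c("orientation", "direction"),
                            reliability_quantile = 0.5, circular = FALSE,
                            seed = 1L) {
  attribute <- match.arg(attribute)
  qc <- qc_experiment(ds, seed = seed)
  if (!qc$include) {
    out <- NULL
    attr(out, "qc") <- qc
    return(out)
  }
  n <- nrow(ds$dff)
  pc <- pc_from_dff(ds)
  p1 <- preferred_grating(ds, block = "first", attribute = attribute)
  p2 <- preferred_grating(ds, block = "last", attribute = attribute)
  rel <- response_reliability(ds, attribute = attribute)
  period <- if (attribute == "direction") 360 else 180
  dp <- delta_pref(p1, p2, circular = circular, period = period)
  # deterministic tie-break: rank by (reliability, neuron index)
  thr_rank <- floor(n * (1 - reliability_quantile))
  ord <- order(rel, seq_len(n), na.last = FALSE)
  included <- logical(n)
  included[ord[seq_len(n) > thr_rank]] <- TRUE
  included[is.na(rel) | is.na(pc)] <- FALSE
  res <- data.frame(neuron = seq_len(n), pc = pc,
                    pref_first = p1, pref_last = p2, delta_pref = dp,
                    reliability = rel, included = included)
  class(res) <- c("drift_result", "data.frame")
  attr(res, "qc") <- qc
  attr(res, "log") <- c(n_neurons = n, n_reliable = sum(included))
  res
}

#' Drift statistics over included neurons
#'
#' For a single session: Spearman rank correlation between population
#' coupling and the preference change among included neurons, and the ratio
#' of the mean coupling of changing neurons (\code{delta_pref > 0}) to that
#' of stable neurons (\code{delta_pref = 0}). For a list of sessions:
#' per-session ratios (sessions with an empty group are skipped with a log
#' entry), the pooled rank correlation, and a one-sample t-test of the
#' ratios against 1.
#'
#' @param results a \code{drift_result} or a list of them (\code{NULL}
#'   entries from excluded sessions are dropped).
#' @return List with \code{spearman_r}, \code{spearman_p}, \code{ratios},
#'   \code{mean_ratio}, \code{t_p} (NA for a single session with < 2
#'   ratios), and \code{n_sessions_used}.
#' @export
drift_statistics <- function(results) {
  if (inherits(results, "drift_result")) results <- list(results)
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no included sessions")
  pooled_pc <- numeric(0); pooled_dp <- numeric(0)
  ratios <- numeric(0); skipped <- 0L
  for (res in results) {
    inc <- res[res$included, , drop = FALSE]
    pooled_pc <- c(pooled_pc, inc$pc)
    pooled_dp <- c(pooled_dp, inc$delta_pref)
    chg <- inc$pc[inc$delta_pref > 0]
    stb <- inc$pc[inc$delta_pref == 0]
    if (length(chg) < 3 || length(stb) < 3) { skipped <- skipped + 1L; next }
    ratios <- c(ratios, mean(chg) / mean(stb))
  }
  rc <- if (length(pooled_pc) >= 3 && stats::sd(pooled_dp) > 0)
    rank_correlation(pooled_pc, pooled_dp)
  else list(r = NA_real_, p.value = NA_real_)
  tt_p <- if (length(ratios) >= 2)
    stats::t.test(ratios, mu = 1)$p.value else NA_real_
  list(spearman_r = rc$r, spearman_p = rc$p.value,
       ratios = ratios, mean_ratio = mean(ratios),
       t_p = tt_p, n_sessions_used = length(ratios),
       n_sessions_skipped = skipped)
}

#' Plain-text serialization of a calcium dataset
#'
#' Writes the dF/F matrix and stimulus table as CSV plus a JSON sidecar with
#' the frame rate and block ranges; \code{read_calcium_dataset} restores the
#' object.
#'
#' @param ds a \code{\link{calcium_dataset}}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_calcium_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "calcium_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ds$dff, file.path(dir, "dff.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(ds$stim_table, file.path(dir, "stim_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_rate = ds$frame_rate,
                            first = range(ds$blocks$first),
                            last = range(ds$blocks$last)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_calcium_dataset
#' @export
read_calcium_dataset <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  dff <- as.matrix(utils::read.table(file.path(dir, "dff.csv"), sep = ","))
  dimnames(dff) <- NULL
  tab <- utils::read.csv(file.path(dir, "stim_table.csv"))
  calcium_dataset(dff, meta$frame_rate, tab,
                  list(first = meta$first[1]:meta$first[2],
                       last = meta$last[1]:meta$last[2]))
}
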