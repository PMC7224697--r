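#' Canonical simulation parameters
#'
#' Returns the full parameter set of the network model as a named list of
#' class \code{"network_config"}. Defaults are the canonical constants of the
#' model: stimulus drive \code{h_stim = 8}, transfer-function baseline
#' \code{r0 = 1} Hz and maximum \code{rmax = 20} Hz, homeostatic target rate
#' \code{y0 = 5} Hz, base Hebbian learning rate \code{alpha_s = 2e-6} Hz,
#' synaptic-scaling rate \code{zeta = 2e-4} Hz, inhibitory learning rate
#' \code{eta = 1e-5} Hz, excitatory weight cap \code{wmax = 0.042}, inhibitory
#' weight-magnitude cap \code{wmax_inh = 50}, summed E-to-E input target
#' \code{w_total_ee = 0.75}, noise amplitude \code{sigma_ou = 1} with
#' correlation time \code{tau_ou = 10} ms, and initial weights
#' \code{w_init_ee = 0.5 * wmax}, \code{w_init_ie = 0.2}.
#'
#' Two constants are plumbing rather than model constants: the membrane/state
#' time constant \code{tau_m} (ms) of the rate equation and the Euler step
#' \code{dt} (ms). \code{w_init_ei} (static E-to-I weights) defaults to
#' \code{7.2 / n_exc} (0.15 for the 48-neuron network), which places the
#' global inhibitory neuron's summed drive -- and with it the gain of the
#' homeostatic loop -- in a size-invariant range that stabilises the
#' excitatory transient without winding inhibition up to its cap.
#' \code{plasticity_activity} selects the activity variable consumed by the
#' plasticity rules: \code{"linear"} (default) uses the rectified state
#' \code{max(y, 0)}, preserving the full homeostatic error signal;
#' \code{"transfer"} uses the saturating transfer output \code{g(y)}.
#'
#' @param ... named overrides of any default listed above. Unknown names are
#'   an error.
#' @return A list of class \code{"network_config"}.
#' @examples
#' cfg <- network_config()
#' cfg$wmax
#' network_config(sigma_ou = 5)$sigma_ou
#' @export
network_config <- function(...) {
  cfg <- list(
    h_stim     = 8.0,
    r0         = 1.0,
    rmax       = 20.0,
    y0         = 5.0,
    alpha_s    = 2e-6,
    zeta       = 2e-4,
    eta        = 1e-5,
    wmax       = 0.042,
    wmax_inh   = 50,
    w_total_ee = 0.75,
    sigma_ou   = 1.0,
    tau_ou     = 10.0,
    w_init_ee  = NA_real_,   # resolves to 0.5 * wmax
    w_init_ie  = 0.2,
    w_init_ei  = NA_real_,   # resolves to 7.2 / n_exc
    tau_m      = 10.0,
    dt         = 1.0,
    baseline_shift = FALSE,
    plasticity_activity = "linear"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all overrides must be named")
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           "; valid keys are: ", paste(names(cfg), collapse = ", "))
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  }
  if (is.na(cfg$w_init_ee)) cfg$w_init_ee <- 0.5 * cfg$wmax
  validate_config(cfg)
  class(cfg) <- "network_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$rmax > cfg$r0, cfg$r0 >= 0,
    cfg$tau_ou > 0, cfg$sigma_ou >= 0,
    cfg$dt > 0, cfg$tau_m > 0, cfg$dt <= cfg$tau_m / 2,
    cfg$wmax > 0, cfg$wmax_inh > 0, cfg$w_total_ee >= 0,
    cfg$alpha_s >= 0, cfg$zeta >= 0, cfg$eta >= 0,
    cfg$plasticity_activity %in% c("linear", "transfer")
  )
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("Network model configuration\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Plasticity parameters
#'
#' Bundles the parameters consumed by the synaptic update rules. The Hebbian
#' learning rate \code{alpha} is per postsynaptic neuron and may be a vector
#' (one entry per excitatory neuron) -- diversity of \code{alpha} across
#' neurons is the central model ingredient.
#'
#' @param alpha per-neuron Hebbian learning rate(s), Hz. Non-negative.
#' @param zeta synaptic-scaling rate, Hz.
#' @param eta inhibitory learning rate, Hz.
#' @param w_total_ee target summed E-to-E input weight per neuron.
#' @param y0 homeostatic target firing rate, Hz.
#' @param wmax E-to-E (and E-to-I) weight cap.
#' @param wmax_inh cap on the magnitude of I-to-E weights.
#' @return A list of class \code{"plasticity_params"}.
#' @examples
#' plasticity_params(alpha = rep(2e-6, 48))
#' @export
plasticity_params <- function(alpha = 2e-6, zeta = 2e-4, eta = 1e-5,
                              w_total_ee = 0.75, y0 = 5.0,
                              wmax = 0.042, wmax_inh = 50) {
  stopifnot(all(alpha >= 0), zeta >= 0, eta >= 0, w_total_ee >= 0,
            y0 >= 0, wmax > 0, wmax_inh > 0)
  structure(list(alpha = alpha, zeta = zeta, eta = eta,
                 w_total_ee = w_total_ee, y0 = y0,
                 wmax = wmax, wmax_inh = wmax_inh),
            class = "plasticity_params")
}

#' Derive a reproducible stream seed from a master seed
#'
#' Every source of randomness in the package (stimulus schedules, noise
#' processes, receptive-field sampling, decoder initialisation, synthetic
#' calcium data) draws its seed from a master seed through a named stream, so
#' adding a new consumer never perturbs existing streams.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @examples
#' derive_seed(1, "schedule")
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a file of parameter overrides keyed by the canonical parameter names
#' (see \code{\link{network_config}}), validates it, and returns the resolved
#' configuration. An empty file yields all defaults. Unknown keys raise an
#' error that lists the valid keys.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{network_config}.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  } else {
    out <- yaml::yaml.load(txt)
    if (is.null(out)) list() else out
  }
  do.call(network_config, as.list(over))
}

#' Write experiment results to a directory
#'
#' Serializes an experiment result (or any list of data frames, matrices and
#' scalars) as plain-text artifacts: matrices as CSV, data frames as CSV,
#' everything else into a JSON sidecar, plus a manifest with MD5 checksums.
#' Re-running with the same seed reproduces identical checksums for
#' deterministic outputs.
#'
#' @param result named list; elements that are matrices or data frames become
#'   CSV files, the rest is collected into \code{result.json}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
write_results <- function(result, dir) {
  stopifnot(is.list(result), !is.null(names(result)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  scalars <- list()
  for (nm in names(result)) {
    x <- result[[nm]]
    if (is.matrix(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.table(x, f, sep = ",", row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
      files <- c(files, f)
    } else {
      scalars[[nm]] <- x
    }
  }
  if (length(scalars)) {
    f <- file.path(dir, "result.json")
    jsonlite::write_json(scalars, f, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f)
                           as.character(tools::md5sum(f)), ""),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
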