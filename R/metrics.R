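#' Population coupling
#'
#' The population coupling of neuron i is the Pearson correlation of its
#' activity trace with the mean activity of all \emph{other} neurons
#' (leave-self-out mean recomputed per neuron). High coupling marks
#' "choristers", low coupling "soloists". Traces with zero variance yield
#' \code{NA} (flagged, never silently zeroed).
#'
#' @param activity neurons x time matrix (rates or dF/F).
#' @return Numeric vector of couplings in \code{[-1, 1]}, \code{NA} where
#'   undefined, with attribute \code{n_undefined}.
#' @examples
#' x <- matrix(rnorm(40), 4)
#' population_coupling(x)
#' @export
population_coupling <- function(activity) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2, ncol(activity) >= 2)
  n <- nrow(activity)
  tot <- colSums(activity)
  pc <- vapply(seq_len(n), function(i) {
    rest <- (tot - activity[i, ]) / (n - 1)
    if (stats::sd(activity[i, ]) == 0 || stats::sd(rest) == 0) return(NA_real_)
    stats::cor(activity[i, ], rest)
  }, 0)
  attr(pc, "n_undefined") <- sum(is.na(pc))
  pc
}

#' Connection specificity
#'
#' Per-neuron ratio of the mean specific to the mean non-specific excitatory
#' input weight, excluding the diagonal. Inputs from presynaptic neurons in
#' the same stimulus group as the postsynaptic neuron are specific; all
#' others are non-specific. A zero non-specific mean yields \code{NA}
#' (flagged; slow neurons can drive non-specific weights to exactly zero),
#' with the count in attribute \code{n_undefined}.
#'
#' @param W_EE E-to-E weight block (row = postsynaptic).
#' @param prefs integer stimulus-group label per neuron.
#' @return Numeric vector of ratios (>= 0, or \code{NA}).
#' @export
connection_specificity <- function(W_EE, prefs) {
  n <- nrow(W_EE)
  stopifnot(ncol(W_EE) == n, length(prefs) == n)
  ratio <- vapply(seq_len(n), function(i) {
    same <- which(prefs == prefs[i]); same <- setdiff(same, i)
    diff <- which(prefs != prefs[i])
    if (!length(same) || !length(diff)) return(NA_real_)
    ns <- mean(W_EE[i, diff])
    if (ns == 0) return(NA_real_)
    mean(W_EE[i, same]) / ns
  }, 0)
  attr(ratio, "n_undefined") <- sum(is.na(ratio))
  ratio
}

#' Temporal fluctuation of connection specificity
#'
#' Standard deviation over time (population convention, divisor n) of each
#' neuron's connection specificity, over snapshots between \code{t_start}
#' and \code{t_end} seconds (defaults 200--500 s, i.e. after convergence).
#'
#' @param record neurons x snapshots matrix of specificity values (columns in
#'   time order) with snapshot times (s) in attribute or supplied via
#'   \code{times}.
#' @param times snapshot times, s.
#' @param t_start,t_end window, s.
#' @return Per-neuron standard deviation over time.
#' @export
specificity_fluctuations <- function(record, times, t_start = 200, t_end = 500) {
  stopifnot(is.matrix(record), length(times) == ncol(record))
  keep <- times >= t_start & times <= t_end
  if (sum(keep) < 2) stop("fewer than 2 snapshots in [t_start, t_end]")
  sub <- record[, keep, drop = FALSE]
  apply(sub, 1, sd_pop)
}

# population (divisor n) standard deviation, NA-tolerant
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Receptive-field stimulus selectivity
#'
#' Selectivity of each neuron: mean input weight from presynaptic neurons
#' sharing its receptive-field orientation minus the mean input weight from
#' differently tuned neurons (difference form; may be negative). Neurons
#' with no same-orientation partner are flagged \code{NA}.
#'
#' @param W_EE E-to-E weight block.
#' @param orientations per-neuron orientation (group) labels.
#' @return Per-neuron selectivity values.
#' @export
rf_selectivity <- function(W_EE, orientations) {
  n <- nrow(W_EE)
  stopifnot(ncol(W_EE) == n, length(orientations) == n)
  sel <- vapply(seq_len(n), function(i) {
    same <- setdiff(which(orientations == orientations[i]), i)
    diff <- which(orientations != orientations[i])
    if (!length(same) || !length(diff)) return(NA_real_)
    mean(W_EE[i, same]) - mean(W_EE[i, diff])
  }, 0)
  attr(sel, "n_undefined") <- sum(is.na(sel))
  sel
}

#' Temporal variability of stimulus selectivity
#'
#' Standard deviation over time of each neuron's selectivity during ongoing
#' plasticity, using the same post-convergence windowing convention as
#' \code{\link{specificity_fluctuations}}.
#'
#' @inheritParams specificity_fluctuations
#' @return Per-neuron standard deviation.
#' @export
selectivity_variability <- function(record, times, t_start = 200, t_end = 500) {
  specificity_fluctuations(record, times, t_start, t_end)
}

#' Feedforward and associated-stimulus selectivity (ratio forms)
#'
#' Feedforward selectivity: mean specific / mean non-specific input weight
#' minus 1, where specific inputs come from neurons sharing the postsynaptic
#' neuron's feedforward stimulus preference. Associated selectivity: mean
#' weight from neurons preferring the associated stimulus / mean weight from
#' all other neurons, minus 1. Zero denominators are flagged \code{NA}.
#'
#' @param W_EE E-to-E weight block.
#' @param prefs per-neuron preferred-stimulus labels.
#' @param assoc associated stimulus identifier.
#' @return List with per-neuron vectors \code{ff} and \code{assoc}.
#' @export
association_selectivity <- function(W_EE, prefs, assoc) {
  n <- nrow(W_EE)
  stopifnot(ncol(W_EE) == n, length(prefs) == n, assoc %in% prefs)
  ff <- vapply(seq_len(n), function(i) {
    same <- setdiff(which(prefs == prefs[i]), i)
    diff <- which(prefs != prefs[i])
    if (!length(same) || !length(diff)) return(NA_real_)
    ns <- mean(W_EE[i, diff])
    if (ns == 0) return(NA_real_)
    mean(W_EE[i, same]) / ns - 1
  }, 0)
  as_sel <- vapply(seq_len(n), function(i) {
    agrp <- setdiff(which(prefs == assoc), i)
    rest <- setdiff(setdiff(seq_len(n), agrp), i)
    if (!length(agrp) || !length(rest)) return(NA_real_)
    nr <- mean(W_EE[i, rest])
    if (nr == 0) return(NA_real_)
    mean(W_EE[i, agrp]) / nr - 1
  }, 0)
  list(ff = ff, assoc = as_sel)
}

#' Compare the spread of two population-coupling samples
#'
#' Levene test of equality of variances between two samples (e.g. the
#' population-coupling distributions of diverse- and uniform-learning-rate
#' networks). NAs are dropped.
#'
#' @param pc_a,pc_b numeric samples.
#' @param center centering statistic for the Levene test.
#' @return List with \code{statistic}, \code{p.value}, and the two sample
#'   variances.
#' @export
compare_distributions <- function(pc_a, pc_b, center = mean) {
  pc_a <- pc_a[!is.na(pc_a)]; pc_b <- pc_b[!is.na(pc_b)]
  stopifnot(length(pc_a) >= 2, length(pc_b) >= 2)
  vals <- c(pc_a, pc_b)
  grp <- factor(rep(c("a", "b"), c(length(pc_a), length(pc_b))))
  lt <- car::leveneTest(vals ~ grp, center = center)
  list(statistic = lt[1, "F value"], p.value = lt[1, "Pr(>F)"],
       var_a = stats::var(pc_a), var_b = stats::var(pc_b))
}

#' Spearman rank correlation
#'
#' Rank correlation with two-sided p-value; pairs with an undefined entry
#' are removed, constant inputs are flagged.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with \code{r}, \code{p.value}, \code{n}.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p.value = NA_real_, n = length(x),
                flag = "constant input"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Specific / non-specific weight-channel ratio and difference series
#'
#' Convenience accessors turning the group-weight channel of a
#' \code{\link{run_network}} trace into specificity (ratio) and selectivity
#' (difference) time series.
#'
#' @param trace a \code{simulation_trace} recorded with a finite
#'   \code{group_record_ms}.
#' @return List with matrices \code{specificity} (ratio; \code{NA} where the
#'   non-specific mean is 0), \code{selectivity} (difference) and the sample
#'   \code{times} in seconds.
#' @export
trace_specificity <- function(trace) {
  stopifnot(inherits(trace, "simulation_trace"), !is.null(trace$spec_mean))
  s <- trace$spec_mean; ns <- trace$nonspec_mean
  ratio <- s / ns
  ratio[ns == 0] <- NA_real_
  list(specificity = ratio, selectivity = s - ns, times = trace$group_times)
}
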