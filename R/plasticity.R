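#' Hebbian plasticity with homeostatic synaptic scaling (E-to-E)
#'
#' One update of the excitatory recurrent weights:
#' \deqn{W_{ij} \leftarrow W_{ij} + dt\,[\alpha_i y_i y_j -
#'   \zeta(\sum_k W_{ik} - W^{total}_{EE})]}
#' where \eqn{\alpha_i} is the learning rate of the \emph{postsynaptic}
#' neuron, so diversity in \code{alpha} makes some neurons' input weights
#' more plastic than others'. The scaling term pulls each neuron's summed
#' input toward \code{w_total_ee}, inducing competition between presynaptic
#' partners. Rates are the non-negative \code{g(y)} outputs of the transfer
#' function. The diagonal (autapses) is untouched and no clipping is applied
#' here; compose with \code{\link{clip_weights}}.
#'
#' @param W_EE E-to-E weight block (row = postsynaptic).
#' @param rates excitatory rate vector, Hz; non-negative.
#' @param params a \code{\link{plasticity_params}}.
#' @param dt_ms time step, ms (learning rates are in Hz, so the update is
#'   scaled by \code{dt_ms/1000}).
#' @return Updated weight block.
#' @export
hebbian_scaling_update <- function(W_EE, rates, params, dt_ms = 1) {
  n <- nrow(W_EE)
  stopifnot(ncol(W_EE) == n, length(rates) == n)
  if (any(rates < 0)) stop("negative rates: Hebbian update expects g(y) >= 0")
  alpha <- rep_len(params$alpha, n)
  dt <- dt_ms / 1000
  hebb <- (alpha * rates) %o% rates              # alpha_i y_i y_j
  scale_term <- params$zeta * (rowSums(W_EE) - params$w_total_ee)
  dW <- dt * (hebb - scale_term)                 # scale term constant per row
  diag(dW) <- 0
  W_EE + dW
}

#' Homeostatic inhibitory plasticity (I-to-E)
#'
#' Updates the \emph{magnitude} of inhibitory-to-excitatory weights by
#' \code{dt * eta * y_j (y_i - y0)} (presynaptic inhibitory j, postsynaptic
#' excitatory i): inhibition onto a neuron grows while the neuron fires above
#' the homeostatic target \code{y0} and shrinks below it, steering excitatory
#' rates toward \code{y0}. Weights are stored signed (non-positive), so the
#' stored value becomes more negative when \code{y_i > y0}. No clipping here.
#'
#' @param W_IE I-to-E block (rows = excitatory post, columns = inhibitory
#'   pre), entries <= 0.
#' @param rates_E excitatory rates, Hz.
#' @param rates_I inhibitory rates, Hz.
#' @param params a \code{\link{plasticity_params}}.
#' @param dt_ms time step, ms.
#' @return Updated signed I-to-E block.
#' @export
inhibitory_update <- function(W_IE, rates_E, rates_I, params, dt_ms = 1) {
  stopifnot(nrow(W_IE) == length(rates_E), ncol(W_IE) == length(rates_I))
  if (any(rates_E < 0) || any(rates_I < 0)) stop("negative rates")
  dt <- dt_ms / 1000
  dmag <- dt * params$eta * (rates_E - params$y0) %o% rates_I
  W_IE - dmag
}

#' Clip weights to their bounds
#'
#' Clamps E-to-E and E-to-I entries to \code{[0, wmax]}, I-to-E entries to
#' \code{[-wmax_inh, 0]}, zeroes the I-to-I block and the diagonal.
#'
#' @param W full signed weight matrix (excitatory neurons first).
#' @param params a \code{\link{plasticity_params}}.
#' @param n_exc number of excitatory neurons (rows/cols \code{1:n_exc}).
#' @return Clipped weight matrix.
#' @export
clip_weights <- function(W, params, n_exc) {
  n <- nrow(W)
  stopifnot(ncol(W) == n, n_exc >= 1, n_exc <= n)
  e <- seq_len(n_exc)
  i <- setdiff(seq_len(n), e)
  W[, e] <- pmin(pmax(W[, e], 0), params$wmax)        # E->E and E->I columns
  if (length(i)) {
    W[e, i] <- pmin(pmax(W[e, i], -params$wmax_inh), 0)  # I->E
    W[i, i] <- 0                                          # no I->I
  }
  diag(W) <- 0
  W
}

#' Functionally silent plastic-input update (embedded-neuron model)
#'
#' Updates the weight vector from a static presynaptic population onto a
#' single plastic neuron with the Hebbian + scaling rule, where the scaling
#' term acts over the plastic neuron's input weights. These synapses are
#' "functionally silent": they are never fed back into any neuron's
#' activity, so the population coupling of both populations stays where it
#' was set. Weights are clipped to \code{[0, wmax]}.
#'
#' @param w weight vector (one entry per static presynaptic neuron).
#' @param r_static static-population rate vector, Hz.
#' @param r_plastic plastic neuron's rate, Hz (scalar).
#' @param alpha Hebbian learning rate of the plastic neuron, Hz.
#' @param params a \code{\link{plasticity_params}} (uses \code{zeta},
#'   \code{w_total_ee}, \code{wmax}).
#' @param dt_ms time step, ms.
#' @return Updated, clipped weight vector.
#' @export
silent_plastic_update <- function(w, r_static, r_plastic, alpha, params,
                                  dt_ms = 1) {
  stopifnot(length(w) == length(r_static), length(r_plastic) == 1L)
  dt <- dt_ms / 1000
  dw <- dt * (alpha * r_static * r_plastic -
                params$zeta * (sum(w) - params$w_total_ee))
  pmin(pmax(w + dw, 0), params$wmax)
}
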