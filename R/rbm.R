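## Restricted Boltzmann machine with single-step contrastive divergence
## (CD-1). Visible and hidden units are binary/stochastic; training follows
## the update rules
##   dW = eps_w (<v p0'>_data - <p1v p1h'>_recon) - eta W + mom dW_prev
##   da = eps_b (<v>_data - <p1v>_recon)          + mom da_prev
##   dc = eps_b (<p0>_data - <p1h>_recon)         + mom dc_prev
## where p0 = sigma(v W + c) drives sampled hidden states, the visible
## reconstruction p1v = sigma(h W' + a) stays a probability, and
## p1h = sigma(p1v W + c). Momentum is applied uniformly to all three
## parameter groups; the weight cost eta decays weights only.

#' RBM training hyperparameters
#'
#' Defaults: learning rate 0.01 for weights and 0.1 for biases, weight cost
#' 0.0002, momentum 0.5 switching to 0.9 after 5 epochs, 20 epochs, batches
#' of 100.
#'
#' @param eps_w,eps_bias Learning rates for weights / biases.
#' @param eta Weight cost (applied to weights only).
#' @param momentum_initial,momentum_final,momentum_switch Momentum schedule:
#'   \code{momentum_initial} for the first \code{momentum_switch} epochs,
#'   then \code{momentum_final}.
#' @param epochs,batch Training epochs and batch size.
#' @return List of hyperparameters.
#' @export
rbm_hyper <- function(eps_w = 0.01, eps_bias = 0.1, eta = 2e-4,
                      momentum_initial = 0.5, momentum_final = 0.9,
                      momentum_switch = 5L, epochs = 20L, batch = 100L) {
  stopifnot(eps_w > 0, eps_bias > 0, eta >= 0, epochs >= 1, batch >= 1)
  list(eps_w = eps_w, eps_bias = eps_bias, eta = eta,
       momentum_initial = momentum_initial, momentum_final = momentum_final,
       momentum_switch = as.integer(momentum_switch),
       epochs = as.integer(epochs), batch = as.integer(batch))
}

#' Construct an RBM parameter set
#'
#' Weights are initialised from a small zero-mean Gaussian (sd 0.01 by
#' default); biases start at zero.
#'
#' @param n_visible,n_hidden Layer sizes.
#' @param hyper Hyperparameters from \code{\link{rbm_hyper}}.
#' @param init_sd Initial weight standard deviation (0 gives exact zeros).
#' @return Object of class \code{rbm}: weight matrix \code{W}
#'   (n_visible x n_hidden), visible biases \code{a}, hidden biases
#'   \code{c}, and \code{hyper}.
#' @export
rbm_new <- function(n_visible, n_hidden, hyper = rbm_hyper(), init_sd = 0.01) {
  W <- matrix(if (init_sd > 0) rnorm(n_visible * n_hidden, 0, init_sd) else 0,
              n_visible, n_hidden)
  structure(list(W = W, a = numeric(n_visible), c = numeric(n_hidden),
                 hyper = hyper), class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat("<rbm> ", nrow(x$W), " visible x ", ncol(x$W), " hidden\n", sep = "")
  invisible(x)
}

#' Energy of a joint RBM configuration
#'
#' \code{E(v, h) = - sum_i a_i v_i - sum_j c_j h_j - sum_ij h_j v_i w_ij}.
#'
#' @param v Visible vector (binary).
#' @param h Hidden vector (binary).
#' @param rbm An \code{\link{rbm_new}} object.
#' @return Scalar energy.
#' @export
rbm_energy <- function(v, h, rbm) {
  if (length(v) != nrow(rbm$W) || length(h) != ncol(rbm$W))
    stop("dimension mismatch: v ", length(v), ", h ", length(h),
         " vs W ", nrow(rbm$W), "x", ncol(rbm$W))
  -sum(rbm$a * v) - sum(rbm$c * h) - as.numeric(t(v) %*% rbm$W %*% h)
}

#' Exact marginal probability of a visible configuration
#'
#' \code{p(v) = sum_h exp(-E(v,h)) / Z}, computed by marginalising the
#' hidden layer in closed form and summing the partition function over all
#' visible configurations. Only feasible for tiny machines; refuses when
#' \code{n_visible + n_hidden > 20}.
#'
#' @param v Visible configuration (binary vector).
#' @param rbm An \code{rbm} object.
#' @return Probability in \[0,1\].
#' @export
exact_visible_probability <- function(v, rbm) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  if (nv + nh > 20L)
    stop("exact enumeration refused: n_visible + n_hidden = ", nv + nh,
         " > 20")
  if (length(v) != nv) stop("v has length ", length(v), ", expected ", nv)
  unnorm <- function(vv) {
    # sum_h exp(-E) = exp(a'v) prod_j (1 + exp(c_j + v'W_j))
    exp(sum(rbm$a * vv)) * prod(1 + exp(rbm$c + as.numeric(vv %*% rbm$W)))
  }
  configs <- all_binary_vectors(nv)
  Z <- sum(apply(configs, 1, unnorm))
  unnorm(v) / Z
}

# all 2^n binary vectors as rows (n small)
all_binary_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

#' Hidden activation probabilities
#'
#' \code{p0_j = sigma(sum_i v_i w_ij + c_j)}, row-wise for a matrix of
#' visible vectors (or activation probabilities).
#'
#' @param v Visible vector or matrix (rows = examples), values in \[0,1\].
#' @param rbm An \code{rbm} object.
#' @return Matrix/vector of probabilities in (0,1).
#' @export
hidden_probs <- function(v, rbm) {
  v <- as_row_matrix(v, nrow(rbm$W), "visible")
  drop_if_vector(sigmoid(add_bias(v %*% rbm$W, rbm$c)))
}

#' Visible reconstruction probabilities
#'
#' \code{p1_i = sigma(sum_j h_j w_ij + a_i)}.
#'
#' @param h Hidden vector or matrix, values in \[0,1\].
#' @param rbm An \code{rbm} object.
#' @return Matrix/vector of probabilities in (0,1).
#' @export
visible_probs <- function(h, rbm) {
  h <- as_row_matrix(h, ncol(rbm$W), "hidden")
  drop_if_vector(sigmoid(add_bias(h %*% t(rbm$W), rbm$a)))
}

as_row_matrix <- function(x, d, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != d)
    stop(what, " input has ", ncol(x), " columns, expected ", d)
  x
}

drop_if_vector <- function(m) if (nrow(m) == 1L) drop(m) else m

#' Sample binary states from activation probabilities
#'
#' Each unit is set to 1 independently with its activation probability,
#' using the current R random-number stream.
#'
#' @param probs Vector or matrix of probabilities.
#' @return Binary object of the same shape.
#' @export
sample_binary <- function(probs) {
  s <- (runif(length(probs)) < probs) * 1
  if (!is.null(dim(probs))) dim(s) <- dim(probs)
  s
}

#' Momentum state for CD-1 training
#'
#' Zero-initialised previous increments for weights and both bias vectors.
#'
#' @param rbm An \code{rbm} object.
#' @return Object of class \code{cd_state}.
#' @export
cd_state <- function(rbm) {
  structure(list(dW = matrix(0, nrow(rbm$W), ncol(rbm$W)),
                 da = numeric(nrow(rbm$W)),
                 dc = numeric(ncol(rbm$W)),
                 epoch = 0L),
            class = "cd_state")
}

#' One CD-1 parameter update on a batch
#'
#' Positive statistics from the data, negative statistics from a single
#' reconstruction step (sampled hidden states, probabilistic visible
#' reconstruction, probabilistic second hidden pass). Angle-bracket averages
#' are batch means.
#'
#' @param batch Matrix of visible rows, values in \[0,1\].
#' @param rbm An \code{rbm} object.
#' @param state A \code{\link{cd_state}}.
#' @param momentum Momentum coefficient for this update.
#' @return List \code{(rbm, state)} with updated parameters and carried
#'   increments.
#' @export
cd1_update <- function(batch, rbm, state, momentum = 0.5) {
  if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1L)
  if (ncol(batch) != nrow(rbm$W))
    stop("batch has ", ncol(batch), " columns, RBM has ", nrow(rbm$W),
         " visible units")
  hy <- rbm$hyper
  n <- nrow(batch)
  p0 <- sigmoid(add_bias(batch %*% rbm$W, rbm$c))
  h <- sample_binary(p0)
  p1v <- sigmoid(add_bias(h %*% t(rbm$W), rbm$a))
  p1h <- sigmoid(add_bias(p1v %*% rbm$W, rbm$c))
  dW <- hy$eps_w * (crossprod(batch, p0) - crossprod(p1v, p1h)) / n -
    hy$eta * rbm$W + momentum * state$dW
  da <- hy$eps_bias * (colMeans(batch) - colMeans(p1v)) + momentum * state$da
  dc <- hy$eps_bias * (colMeans(p0) - colMeans(p1h)) + momentum * state$dc
  rbm$W <- rbm$W + dW
  rbm$a <- rbm$a + da
  rbm$c <- rbm$c + dc
  state$dW <- dW; state$da <- da; state$dc <- dc
  list(rbm = rbm, state = state)
}

#' Train an RBM with CD-1
#'
#' Shuffled mini-batches (a short final batch is used as-is) for
#' \code{hyper$epochs} epochs; the momentum switches from its initial to its
#' final value after \code{hyper$momentum_switch} epochs.
#'
#' @param data Matrix of visible rows in \[0,1\].
#' @param n_hidden Hidden layer size.
#' @param hyper Hyperparameters (\code{\link{rbm_hyper}}).
#' @param init_sd Initial weight sd.
#' @param init_visible_bias \code{"mean"} (default) starts each visible
#'   bias at the logit of its feature's mean activity, so early
#'   reconstructions match the data brightness and the hidden layer does
#'   not saturate; \code{"zero"} starts at 0.
#' @return Trained \code{rbm}; attribute \code{"recon_mse"} holds the
#'   per-epoch mean squared reconstruction error.
#' @export
train_rbm <- function(data, n_hidden, hyper = rbm_hyper(), init_sd = 0.01,
                      init_visible_bias = c("mean", "zero")) {
  if (is.null(dim(data)) || nrow(data) == 0L)
    stop("training data must be a non-empty matrix")
  init_visible_bias <- match.arg(init_visible_bias)
  rbm <- rbm_new(ncol(data), n_hidden, hyper, init_sd)
  if (init_visible_bias == "mean")
    rbm$a <- stats::qlogis(pmin(pmax(colMeans(data), 1e-3), 1 - 1e-3))
  state <- cd_state(rbm)
  mse <- numeric(hyper$epochs)
  for (epoch in seq_len(hyper$epochs)) {
    mom <- if (epoch <= hyper$momentum_switch) hyper$momentum_initial
           else hyper$momentum_final
    idx <- sample.int(nrow(data))
    starts <- seq(1L, nrow(data), by = hyper$batch)
    err <- 0
    for (s in starts) {
      rows <- idx[s:min(s + hyper$batch - 1L, nrow(data))]
      batch <- data[rows, , drop = FALSE]
      up <- cd1_update(batch, rbm, state, mom)
      rbm <- up$rbm; state <- up$state
      recon <- visible_probs(hidden_probs(batch, rbm), rbm)
      if (is.null(dim(recon))) recon <- matrix(recon, nrow = 1L)
      err <- err + sum((batch - recon)^2)
    }
    mse[epoch] <- err / length(data)
  }
  attr(rbm, "recon_mse") <- mse
  rbm
}
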